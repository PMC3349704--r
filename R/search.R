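# Relaxed seeded local alignment for cross-species snoRNA detection:
# exact short-word seeding (default word size 3, for distant homologies),
# cheap gaps (first gap character costs 1), full affine-gap Smith-Waterman
# extension (compiled) over windows around seed clusters, both strands.
# No E-value statistics: hits above a raw score threshold are reported and
# meant for inspection, mirroring a manual curation workflow.

# positions (0-based) in s that share an exact w-mer with q
.seed_positions <- function(q, s, w) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < w || ns < w) return(integer(0))
  qk <- unique(substring(q, 1:(nq - w + 1L), w:nq))
  sk <- substring(s, 1:(ns - w + 1L), w:ns)
  which(sk %in% qk) - 1L
}

# group sorted seed positions into clusters separated by > gap
.cluster_positions <- function(pos, gap) {
  if (!length(pos)) return(list())
  pos <- sort(unique(pos))
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) pos[(brk[i] + 1L):brk[i + 1L]])
}

.aln_identity <- function(qa, sa) {
  if (!nchar(qa)) return(0)
  a <- seq_chars(qa); b <- seq_chars(sa)
  100 * sum(a == b & a != "-") / length(a)
}

#' Seeded local-alignment search
#'
#' Finds local alignments of `query` in `subject` reachable from an exact
#' `search.word_size` seed: seed positions are clustered, a window around
#' each cluster (padded by the query length plus `search.xdrop`) is aligned
#' with affine-gap Smith-Waterman, and alignments scoring at least
#' `search.min_score` are reported. Both strands are searched when
#' `search.both_strands`; minus-strand coordinates are reported on the
#' forward subject. Overlapping hits on the same strand are merged keeping
#' the higher score. With `search.word_size = 1` and `search.xdrop = Inf`
#' the search degenerates to a full Smith-Waterman of query versus subject.
#'
#' @param query,subject [sno_seq] records.
#' @param params [sno_params()].
#' @return List of `alignment_hit` objects: `query_interval` (0-based
#'   half-open in the query), `subject` ([sno_interval] on the forward
#'   subject), `score`, `identity_pct`, `aligned_query`, `aligned_subject`,
#'   `stage` (filled by [host_guided_search()]). Sorted by decreasing score.
#' @export
seeded_search <- function(query, subject, params = sno_params()) {
  q <- query$seq
  nq <- nchar(q)
  w <- params$search.word_size
  if (nq < w) sno_stop("query shorter than the seed word size")
  slack <- if (is.finite(params$search.xdrop)) nq + ceiling(params$search.xdrop)
           else nchar(subject$seq)
  strands <- if (isTRUE(params$search.both_strands)) c("+", "-") else "+"
  hits <- list()
  for (strand in strands) {
    s <- if (strand == "+") subject$seq else revcomp(subject$seq)
    ns <- nchar(s)
    clusters <- .cluster_positions(.seed_positions(q, s, w), gap = nq + 2L * w)
    for (cl in clusters) {
      s0 <- max(0L, min(cl) - slack)
      s1 <- min(ns, max(cl) + w + slack)
      sub <- substr(s, s0 + 1L, s1)
      # iterate with masking so every non-overlapping local alignment above
      # the score threshold in this window is reported, not just the best
      for (iter in 1:500) {
        aln <- .sw_align_cpp(q, sub,
                             params$search.match, params$search.mismatch,
                             params$search.gap_open, params$search.gap_extend)
        if (aln$score < params$search.min_score) break
        a0 <- s0 + aln$s_start
        a1 <- s0 + aln$s_end
        iv <- if (strand == "+") sno_interval(subject$id, a0, a1, "+")
              else sno_interval(subject$id, ns - a1, ns - a0, "-")
        hits[[length(hits) + 1L]] <- structure(list(
          query_interval = c(aln$q_start, aln$q_end),
          subject = iv,
          score = aln$score,
          identity_pct = .aln_identity(aln$q_aln, aln$s_aln),
          aligned_query = aln$q_aln,
          aligned_subject = aln$s_aln,
          stage = "subject"
        ), class = "alignment_hit")
        substr(sub, aln$s_start + 1L, aln$s_end) <-
          strrep("X", aln$s_end - aln$s_start)
      }
    }
  }
  .merge_hits(hits)
}

# drop hits overlapping a higher-scoring hit on the same contig (and, unless
# ignore_strand, the same strand)
.merge_hits <- function(hits, ignore_strand = FALSE) {
  if (length(hits) < 2L) return(hits)
  ord <- order(-vapply(hits, function(h) h$score, numeric(1)),
               vapply(hits, function(h) h$subject$start, numeric(1)))
  hits <- hits[ord]
  kept <- list()
  for (h in hits) {
    clash <- FALSE
    for (k in kept) {
      if (identical(h$subject$contig, k$subject$contig) &&
          (ignore_strand || identical(h$subject$strand, k$subject$strand)) &&
          h$subject$start < k$subject$end && k$subject$start < h$subject$end) {
        clash <- TRUE; break
      }
    }
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  kept
}

#' Host-gene-guided homolog search
#'
#' Mirrors the curation order for finding homologs of intron-hosted
#' snoRNAs: first the introns of the named host gene are searched; only if
#' that stage finds nothing is the whole genome searched; a final pass
#' re-searches all host introns so extra gene copies in other introns are
#' not missed. Hit coordinates are lifted back to genome coordinates and
#' tagged with the stage that produced them (`"host_introns"` or
#' `"genome"`).
#'
#' @param query A [sno_seq] snoRNA query.
#' @param genome List of [sno_seq] contigs.
#' @param genes List of [gene_model] annotations.
#' @param host_gene_id Host gene to search first; unknown ids produce a
#'   warning and fall through to the genome-wide stage.
#' @param params [sno_params()].
#' @return List of `alignment_hit` objects in genome coordinates.
#' @export
host_guided_search <- function(query, genome, genes, host_gene_id,
                               params = sno_params()) {
  host <- NULL
  for (g in genes) if (g$gene_id == host_gene_id) host <- g
  if (is.null(host)) {
    warning("host gene '", host_gene_id, "' not found in annotation; ",
            "searching genome-wide", call. = FALSE)
  }

  search_introns <- function() {
    out <- list()
    if (is.null(host)) return(out)
    contig <- find_record(genome, host$contig)
    if (is.null(contig)) return(out)
    introns <- enumerate_introns(host)
    for (i in seq_len(nrow(introns))) {
      sub <- sno_seq(contig$id,
                     substr(contig$seq, introns$start[i] + 1L, introns$end[i]))
      for (h in seeded_search(query, sub, params)) {
        h$subject$start <- h$subject$start + introns$start[i]
        h$subject$end <- h$subject$end + introns$start[i]
        h$stage <- "host_introns"
        out[[length(out) + 1L]] <- h
      }
    }
    out
  }

  stage1 <- search_introns()
  stage2 <- list()
  if (!length(stage1)) {
    for (contig in genome) {
      for (h in seeded_search(query, contig, params)) {
        h$stage <- "genome"
        stage2[[length(stage2) + 1L]] <- h
      }
    }
  }
  extra <- search_introns()  # extra-copy pass over the host introns
  .merge_hits(c(stage1, stage2, extra))
}

#' Global per cent identity between two sequences
#'
#' End-gap-free global alignment (match +1, mismatch -1, gap -2, terminal
#' gaps free) via [Biostrings::pairwiseAlignment()]; identity is 100 x
#' matched columns / aligned columns, where terminal-gap columns are
#' excluded from the denominator and internal-gap columns count as
#' non-matches.
#'
#' @param a,b [sno_seq] records (non-empty).
#' @return Per cent identity in `[0, 100]`.
#' @details Several alignments can share the optimal score and differ in
#'   identity; the pair is therefore aligned in a canonical order
#'   (lexicographic by sequence), which makes the result symmetric in its
#'   arguments.
#' @export
global_identity <- function(a, b) {
  if (b$seq < a$seq) { tmp <- a; a <- b; b <- tmp }
  aln <- .overlap_alignment(a$seq, b$seq)
  if (!nchar(aln$a)) return(0)
  x <- seq_chars(aln$a); y <- seq_chars(aln$b)
  100 * sum(x == y & x != "-") / length(x)
}

# local alignment of two DNA strings with homology-detection scoring
# (match +1, mismatch -2, gap of length k costs 2 + 2k, as in BLASTN-style
# schemes): mismatches and gaps are penalized hard enough that chance
# extensions through unrelated sequence do not pay. Used for family
# membership and truncation calls, where a candidate may carry flanking
# genomic sequence that an ends-free (dovetail) alignment could not clip.
.local_alignment <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 2
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln),
       a_range = c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                   Biostrings::end(Biostrings::pattern(aln))),
       b_range = c(Biostrings::start(Biostrings::subject(aln)) - 1L,
                   Biostrings::end(Biostrings::subject(aln))))
}

# ends-free global alignment of two DNA strings; returns the aligned
# (clipped) region as two equal-length strings
.overlap_alignment <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln),
       a_range = c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                   Biostrings::end(Biostrings::pattern(aln))),
       b_range = c(Biostrings::start(Biostrings::subject(aln)) - 1L,
                   Biostrings::end(Biostrings::subject(aln))))
}
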