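# Gene / pseudogene / uncertain classification of snoRNA candidates.
# Only full-length copies with intact boxes, terminal stem and a working
# antisense element, residing sense-strand inside a host-gene intron (or
# belonging to one of the few independent-promoter families), are called
# genes; every failed check contributes a machine-readable reason code.

REASON_CODES <- c("BOX_MUT_C", "BOX_MUT_D", "BOX_MUT_DPRIME", "NO_STEM",
                  "ASE_DISRUPTED", "TRUNC_5", "TRUNC_3", "INTERGENIC",
                  "EXONIC_OVERLAP", "ANTISENSE_STRAND",
                  "NO_TRANSCRIPT_EVIDENCE")

# Relocate boxes with extra mismatch slack when the strict scan found no
# layout, so the broken box can be named. Returns a provisional cd_layout
# (possibly with NULL boxes) plus per-box best mismatch counts (Inf when a
# box cannot be placed at all).
.diagnose_layout <- function(seq, params) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  extra <- params$classify.diag_extra_mismatch
  best_hit <- function(name, tol, window) {
    cons <- box_consensus(name, tol + extra)
    if (window[2] - window[1] < nchar(cons$pattern)) return(NULL)
    hits <- match_box(seq, cons, window = window)
    if (!nrow(hits)) NULL else as.list(hits[1, ])
  }
  c_hit <- best_hit("C", params$boxes.c_max_mismatch,
                    c(0L, min(n, params$layout.c_window + nchar(BOX_PATTERNS[["C"]]) - 1L)))
  d_hit <- best_hit("D", params$boxes.d_max_mismatch,
                    c(max(0L, n - params$layout.d_window), n))
  inner_lo <- if (!is.null(c_hit)) c_hit$start + nchar(BOX_PATTERNS[["C"]]) else 0L
  inner_hi <- if (!is.null(d_hit)) d_hit$start else n
  dp_hit <- NULL
  if (inner_hi > inner_lo) {
    dp_hit <- best_hit("Dprime", params$boxes.dprime_max_mismatch,
                       c(inner_lo, inner_hi))
  }
  cp_hit <- NULL
  if (!is.null(dp_hit) && inner_hi > dp_hit$start + nchar(BOX_PATTERNS[["Dprime"]])) {
    cp_hit <- best_hit("Cprime", params$boxes.cprime_max_mismatch,
                       c(dp_hit$start + nchar(BOX_PATTERNS[["Dprime"]]), inner_hi))
  }
  structure(list(seq = seq,
                 c_box = c_hit, d_box = d_hit,
                 dprime_box = dp_hit, cprime_box = cp_hit,
                 stem = NULL),
            class = "cd_layout")
}

# does any D/D'-anchored duplex against `target` predict `position`?
.ase_reproducible <- function(layout, target, position, params) {
  for (via in c("D", "Dprime")) {
    box <- if (via == "D") layout$d_box else layout$dprime_box
    if (is.null(box)) next
    region <- tryCatch(extract_guide_region(layout, via, params),
                       error = function(e) NULL)
    if (is.null(region)) next
    gseq <- substr(layout$seq, region[1] + 1L, region[2])
    for (dx in find_duplexes(gseq, region[1], list(target), params)) {
      pred <- predict_methylation_site(layout, dx, via, params)
      if (!is.null(pred) && pred$target_id == target$id &&
          pred$position == position) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Classify a snoRNA candidate as gene, pseudogene or uncertain
#'
#' Runs the independent checks — box integrity (within the configured
#' mismatch tolerances), terminal stem, reproducibility of the family's
#' known target site from the antisense element, full length relative to
#' the family reference (`classify.full_length_frac`), and genomic
#' location — and combines them: an empty reason list means `gene`; a
#' sequence-intact candidate stranded in intergenic space without
#' transcript evidence is `uncertain` (with evidence it is upgraded to
#' `gene`, noted in `note`); everything else is `pseudogene`.
#' Independent-promoter families are exempt from the location checks.
#'
#' @param candidate A [sno_seq] candidate sequence.
#' @param layout The candidate's `cd_layout`, or `NULL` (boxes are then
#'   relocated with `classify.diag_extra_mismatch` slack for diagnosis).
#' @param location A `location_call` from [locate_candidate()].
#' @param profile One catalog row (list/data.frame row) with `family`,
#'   `reference_seq`, `target_rna_id`, `target_position`,
#'   `independent_promoter`.
#' @param targets List of [sno_seq] target RNAs (for the antisense check).
#' @param evidence_overlap Logical from [transcript_evidence_overlap()].
#' @param params [sno_params()].
#' @return A `classification_result` list: `candidate_id`, `family`,
#'   `label`, `reasons` (character vector), `note`.
#' @export
classify_candidate <- function(candidate, layout, location, profile, targets,
                               evidence_overlap = FALSE, params = sno_params()) {
  if (is.null(profile) || is.null(profile$family) || !nzchar(profile$family)) {
    sno_stop("candidate has no family assignment; run assign_family() ",
             "against the catalog first")
  }
  reasons <- character(0)
  note <- ""
  ref_seq <- profile$reference_seq
  ref_layouts <- scan_cd_layouts(ref_seq, params)
  ref_layout <- if (length(ref_layouts)) ref_layouts[[1]] else NULL

  work <- layout
  if (is.null(work)) {
    work <- .diagnose_layout(candidate$seq, params)
    if (is.null(work$c_box) || work$c_box$mismatches > params$boxes.c_max_mismatch) {
      reasons <- c(reasons, "BOX_MUT_C")
    }
    if (is.null(work$d_box) || work$d_box$mismatches > params$boxes.d_max_mismatch) {
      reasons <- c(reasons, "BOX_MUT_D")
    }
  }
  ref_has_dprime <- !is.null(ref_layout) && !is.null(ref_layout$dprime_box)
  if (ref_has_dprime && (is.null(work$dprime_box) ||
                         work$dprime_box$mismatches > params$boxes.dprime_max_mismatch)) {
    reasons <- c(reasons, "BOX_MUT_DPRIME")
  }

  if (!is.null(work$c_box) && !is.null(work$d_box)) {
    stem <- if (!is.null(work$stem)) work$stem else find_terminal_stem(work, params)
    if (is.null(stem)) reasons <- c(reasons, "NO_STEM")
  }

  # antisense element: the family's known site must be recoverable
  if (!is.na(profile$target_rna_id) && !is.null(profile$target_rna_id) &&
      !is.na(profile$target_position)) {
    target <- find_record(targets, profile$target_rna_id)
    if (!is.null(target) && !is.null(work$d_box)) {
      if (!.ase_reproducible(work, target, profile$target_position, params)) {
        reasons <- c(reasons, "ASE_DISRUPTED")
      }
    }
  }

  # full length relative to the family reference: judged from how much of
  # the reference the local alignment covers (a candidate padded with
  # flanking genomic sequence is still truncated if a reference end is
  # missing from the alignment)
  aln <- .local_alignment(candidate$seq, ref_seq)
  miss5 <- aln$b_range[1]
  miss3 <- nchar(ref_seq) - aln$b_range[2]
  thresh <- (1 - params$classify.full_length_frac) * nchar(ref_seq)
  if (miss5 + miss3 > thresh) {
    trunc <- c(if (miss5 > thresh) "TRUNC_5", if (miss3 > thresh) "TRUNC_3")
    if (!length(trunc)) trunc <- if (miss5 >= miss3) "TRUNC_5" else "TRUNC_3"
    reasons <- c(reasons, trunc)
  }

  label <- NULL
  if (!isTRUE(profile$independent_promoter)) {
    if (location$status == "exonic_overlap") {
      reasons <- c(reasons, "EXONIC_OVERLAP")
    } else if (location$status == "intronic" && !isTRUE(location$same_strand)) {
      reasons <- c(reasons, "ANTISENSE_STRAND")
    } else if (location$status == "intergenic") {
      if (!length(reasons)) {
        if (evidence_overlap) {
          note <- "intergenic but fully contained in transcript evidence"
        } else {
          reasons <- c(reasons, "INTERGENIC", "NO_TRANSCRIPT_EVIDENCE")
          label <- "uncertain"
        }
      } else {
        reasons <- c(reasons, "INTERGENIC")
      }
    }
  }

  reasons <- intersect(REASON_CODES, reasons)
  if (is.null(label)) label <- if (length(reasons)) "pseudogene" else "gene"
  structure(list(candidate_id = candidate$id,
                 family = profile$family,
                 label = label,
                 reasons = reasons,
                 note = note),
            class = "classification_result")
}

#' Assign a candidate to the most similar catalog family
#'
#' @param candidate A [sno_seq].
#' @param catalog Family catalog data.frame ([read_family_catalog()]).
#' @param details If `TRUE`, return a list with `family`, `identity_pct`
#'   and `aln_len` (columns of the local alignment to that reference);
#'   otherwise just the family name.
#' @return The `family` of the catalog row whose reference gives the
#'   best-scoring local alignment to the candidate under the identity
#'   scoring scheme (a raw identity maximum would let a one-nucleotide
#'   perfect overlap outrank a full-length 95% match). A local alignment
#'   is used because discovered candidates can carry flanking genomic
#'   sequence that an ends-free alignment cannot clip.
#' @export
assign_family <- function(candidate, catalog, details = FALSE) {
  if (!nrow(catalog)) sno_stop("empty family catalog")
  best <- NULL
  for (i in seq_len(nrow(catalog))) {
    aln <- .local_alignment(candidate$seq, catalog$reference_seq[i])
    x <- seq_chars(aln$a)
    ident <- if (length(x)) 100 * sum(x == seq_chars(aln$b) & x != "-") / length(x) else 0
    if (is.null(best) || aln$score > best$score) {
      best <- list(family = catalog$family[i], identity_pct = ident,
                   aln_len = length(x), score = aln$score)
    }
  }
  best <- best[c("family", "identity_pct", "aln_len")]
  if (details) best else best$family
}

#' Per-family census of classification results
#'
#' @param results data.frame of classification results (needs `family` and
#'   `label` columns), e.g. from [classify_genome()].
#' @param species_label Species tag for the census rows.
#' @return data.frame with `family`, `species`, `n_genes`,
#'   `n_pseudogenes`, `n_uncertain`, one row per family, sorted by family.
#' @export
summarize_census <- function(results, species_label) {
  results <- as.data.frame(results)
  if (!nrow(results)) {
    return(data.frame(family = character(0), species = character(0),
                      n_genes = integer(0), n_pseudogenes = integer(0),
                      n_uncertain = integer(0), stringsAsFactors = FALSE))
  }
  fams <- sort(unique(results$family))
  out <- data.frame(
    family = fams,
    species = species_label,
    n_genes = vapply(fams, function(f) sum(results$family == f & results$label == "gene"), integer(1)),
    n_pseudogenes = vapply(fams, function(f) sum(results$family == f & results$label == "pseudogene"), integer(1)),
    n_uncertain = vapply(fams, function(f) sum(results$family == f & results$label == "uncertain"), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' End-to-end candidate discovery and classification
#'
#' For every catalog family, searches every genome contig with
#' [seeded_search()], merges overlapping hits across families into
#' candidate loci (best score wins), then scans each locus for a C/D
#' layout, locates it against the gene models, and classifies it.
#'
#' @param genome List of [sno_seq] contigs.
#' @param genes List of [gene_model] annotations.
#' @param catalog Family catalog data.frame.
#' @param targets List of [sno_seq] target RNAs.
#' @param evidence Optional `GRanges` of transcript evidence.
#' @param species_label Species tag used in reports.
#' @param params [sno_params()].
#' @return data.frame with one row per candidate locus: `candidate_id`,
#'   `family`, `contig`, `start`, `end`, `strand` (0-based half-open),
#'   `label`, `reasons` (list column), `status`, `host_gene`, `note`.
#' @export
classify_genome <- function(genome, genes, catalog, targets, evidence = NULL,
                            species_label = "unknown", params = sno_params()) {
  index <- build_intron_index(genes)
  hits <- list()
  for (i in seq_len(nrow(catalog))) {
    ref <- sno_seq(catalog$family[i], catalog$reference_seq[i])
    for (contig in genome) {
      hits <- c(hits, seeded_search(ref, contig, params))
    }
  }
  loci <- .merge_hits(hits, ignore_strand = TRUE)
  rows <- list()
  for (h in loci) {
    iv <- h$subject
    contig <- find_record(genome, iv$contig)
    seq <- substr(contig$seq, iv$start + 1L, iv$end)
    if (iv$strand == "-") seq <- revcomp(seq)
    cand_id <- sprintf("cand_%s_%d_%d_%s", iv$contig, iv$start, iv$end, iv$strand)
    cand <- sno_seq(cand_id, seq)
    asg <- assign_family(cand, catalog, details = TRUE)
    # below the membership thresholds the locus is background, not a family copy
    if (asg$identity_pct < params$classify.min_identity_pct ||
        asg$aln_len < params$classify.min_aln_len) next
    fam <- asg$family
    profile <- as.list(catalog[catalog$family == fam, ][1, ])
    layouts <- scan_cd_layouts(cand$seq, params)
    layout <- if (length(layouts)) layouts[[1]] else NULL
    loc <- locate_candidate(iv, index)
    ev <- transcript_evidence_overlap(iv, evidence)
    res <- classify_candidate(cand, layout, loc, profile, targets, ev, params)
    rows[[length(rows) + 1L]] <- data.frame(
      candidate_id = cand_id, family = fam,
      contig = iv$contig, start = iv$start, end = iv$end, strand = iv$strand,
      label = res$label,
      reasons = I(list(res$reasons)),
      status = loc$status,
      host_gene = if (is.null(loc$host_gene)) NA_character_ else loc$host_gene,
      note = res$note,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) {
    out <- data.frame(candidate_id = character(0), family = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      label = character(0), reasons = I(list()),
                      status = character(0), host_gene = character(0),
                      note = character(0), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$contig, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "species") <- species_label
  out
}
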