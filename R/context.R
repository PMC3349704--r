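# Genomic context of candidate loci: intron enumeration, an interval index
# over introns and exons, intronic/exonic/intergenic calls, and
# transcript-evidence containment. Interval arithmetic goes through
# IRanges/GenomicRanges; candidate intervals are converted from the internal
# 0-based convention at this boundary.

#' Enumerate the introns of a gene model
#'
#' Introns are the gaps between consecutive exons. Rows are returned in
#' ascending genomic order; `intron_index` is 0-based in gene orientation
#' (for a `-` strand gene the last genomic gap is intron 0).
#'
#' @param gene A [gene_model].
#' @return data.frame with `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `gene_id`, `intron_index`; zero rows for single-exon genes.
#' @examples
#' g <- gene_model("g", "chr1", "+", data.frame(start = c(100, 300), end = c(200, 400)))
#' enumerate_introns(g)  # one intron (200, 300)
#' @export
enumerate_introns <- function(gene) {
  ex <- gene$exons
  k <- nrow(ex)
  if (k < 2L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0),
                      intron_index = integer(0), stringsAsFactors = FALSE))
  }
  starts <- ex$end[-k]
  ends <- ex$start[-1]
  idx <- if (gene$strand == "+") seq_len(k - 1L) - 1L else rev(seq_len(k - 1L) - 1L)
  data.frame(contig = gene$contig, start = starts, end = ends,
             strand = gene$strand, gene_id = gene$gene_id,
             intron_index = idx, stringsAsFactors = FALSE)
}

#' Build an interval index over introns and exons
#'
#' @param genes List of [gene_model] objects.
#' @return A list of class `intron_index` holding `introns` and `exons`
#'   `GRanges` (1-based internally, as GRanges requires) plus the gene list.
#' @export
build_intron_index <- function(genes) {
  intron_rows <- do.call(rbind, c(lapply(genes, enumerate_introns),
                                  make.row.names = FALSE))
  if (is.null(intron_rows) || !nrow(intron_rows)) {
    introns <- GenomicRanges::GRanges()
  } else {
    introns <- GenomicRanges::GRanges(
      seqnames = intron_rows$contig,
      ranges = IRanges::IRanges(start = intron_rows$start + 1L, end = intron_rows$end),
      strand = intron_rows$strand,
      gene_id = intron_rows$gene_id,
      intron_index = intron_rows$intron_index
    )
  }
  exon_list <- lapply(genes, function(g) {
    GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(start = g$exons$start + 1L, end = g$exons$end),
      strand = g$strand,
      gene_id = g$gene_id
    )
  })
  exons <- if (length(exon_list)) suppressWarnings(do.call(c, unname(exon_list)))
           else GenomicRanges::GRanges()
  structure(list(introns = introns, exons = exons, genes = genes),
            class = "intron_index")
}

#' Locate a candidate relative to gene models
#'
#' A candidate is `intronic` when fully contained in a single intron and
#' overlapping no exon; `exonic_overlap` when it overlaps any exon by at
#' least one nucleotide; `intergenic` otherwise. When several overlapping
#' genes contain the candidate in an intron, the host is the gene with the
#' shortest containing intron (ties: lexicographically smallest gene id).
#' `same_strand` compares the candidate strand with the host gene strand.
#' The verdict does not depend on gene input order.
#'
#' @param candidate A [sno_interval].
#' @param index An `intron_index` from [build_intron_index()].
#' @return A `location_call` list: `status`, `host_gene`, `intron_index`,
#'   `same_strand` (the last three `NA`/`NULL` unless intronic).
#' @export
locate_candidate <- function(candidate, index) {
  gr <- interval_to_granges(candidate)
  known <- as.character(GenomicRanges::seqnames(c(index$introns, index$exons)))
  if (!candidate$contig %in% known) {
    warning("contig '", candidate$contig, "' has no annotated genes", call. = FALSE)
    return(structure(list(status = "intergenic", host_gene = NULL,
                          intron_index = NULL, same_strand = NULL),
                     class = "location_call"))
  }
  exon_ov <- GenomicRanges::findOverlaps(gr, index$exons, minoverlap = 1L,
                                         ignore.strand = TRUE)
  within <- GenomicRanges::findOverlaps(gr, index$introns, type = "within",
                                        ignore.strand = TRUE)
  if (length(within) && !length(exon_ov)) {
    hits <- S4Vectors::subjectHits(within)
    w <- BiocGenerics::width(index$introns)[hits]
    ids <- index$introns$gene_id[hits]
    pick <- hits[order(w, ids)][1]
    host_strand <- as.character(BiocGenerics::strand(index$introns))[pick]
    return(structure(list(
      status = "intronic",
      host_gene = index$introns$gene_id[pick],
      intron_index = index$introns$intron_index[pick],
      same_strand = identical(candidate$strand, host_strand)
    ), class = "location_call"))
  }
  if (length(exon_ov)) {
    return(structure(list(status = "exonic_overlap", host_gene = NULL,
                          intron_index = NULL, same_strand = NULL),
                     class = "location_call"))
  }
  structure(list(status = "intergenic", host_gene = NULL,
                 intron_index = NULL, same_strand = NULL),
            class = "location_call")
}

#' Check transcript-evidence containment
#'
#' `TRUE` iff the candidate is fully contained within at least one evidence
#' feature (mRNA/EST-style intervals). Half overlaps do not count: a snoRNA
#' processed from a transcript must lie inside it.
#'
#' @param candidate A [sno_interval].
#' @param evidence_features A `GRanges` of evidence intervals (as read by
#'   [read_evidence_features()]), or `NULL`/empty.
#' @return Logical scalar.
#' @export
transcript_evidence_overlap <- function(candidate, evidence_features) {
  if (is.null(evidence_features) || !length(evidence_features)) return(FALSE)
  gr <- interval_to_granges(candidate)
  ov <- GenomicRanges::findOverlaps(gr, evidence_features, type = "within",
                                    ignore.strand = TRUE)
  length(ov) > 0L
}

#' Read evidence features (GFF3 or BED) as plain intervals
#'
#' @param path Path to a GFF3 or BED file.
#' @return A `GRanges` of the features.
#' @export
read_evidence_features <- function(path) {
  if (!file.exists(path)) sno_stop("evidence file not found: ", path)
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  rtracklayer::import(path, format = fmt)
}
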