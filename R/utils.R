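# Internal sequence helpers. All sequences are uppercase DNA character
# scalars; U is folded to T at the I/O boundary (see read_fasta).

# error helper used for user-input problems (maps to CLI exit code 1)
sno_stop <- function(..., class = "sno_input_error") {
  stop(structure(
    class = c(class, "sno_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

normalize_seq <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

validate_alphabet <- function(x, id = "<sequence>") {
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  if (length(bad) && nchar(bad)) {
    sno_stop("illegal character '", bad, "' in sequence '", id, "'")
  }
  invisible(TRUE)
}

#' Construct a sequence record
#'
#' A lightweight container for a named nucleotide sequence. The sequence is
#' normalized to the DNA alphabet (uppercase, U read as T) and validated
#' against `{A,C,G,T,N}`.
#'
#' @param id Non-empty record identifier.
#' @param seq Non-empty nucleotide string over `{A,C,G,T,U,N}` (case
#'   insensitive).
#' @param description Free-text description (rest of the FASTA header).
#' @return An object of class `sno_seq`: a list with elements `id`,
#'   `description` and `seq`.
#' @examples
#' sno_seq("x", "acgu")$seq  # "ACGT"
#' @export
sno_seq <- function(id, seq, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    sno_stop("sequence id must be a non-empty string")
  }
  seq <- normalize_seq(seq)
  if (!nzchar(seq)) sno_stop("sequence '", id, "' is empty")
  validate_alphabet(seq, id)
  structure(list(id = id, description = description, seq = seq),
            class = "sno_seq")
}

#' @export
print.sno_seq <- function(x, ...) {
  cat(sprintf("<sno_seq> %s (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Convert a sequence record to RNA lettering
#'
#' Output convenience: snoRNA sequences are stored as DNA internally but can
#' be reported with U in place of T.
#'
#' @param record A [sno_seq] record.
#' @return The sequence string with T replaced by U.
#' @export
as_rna <- function(record) chartr("T", "U", record$seq)

# find a record by id in a list of sno_seq
find_record <- function(records, id) {
  for (r in records) if (r$id == id) return(r)
  NULL
}

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open (`start` inclusive, `end` exclusive),
#' the single internal convention of the package.
#'
#' @param contig Contig/chromosome name.
#' @param start,end Integer bounds with `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `sno_interval`.
#' @export
sno_interval <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    sno_stop("invalid interval [", start, ",", end, ") on ", contig)
  }
  if (!strand %in% c("+", "-")) sno_stop("strand must be '+' or '-'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "sno_interval")
}

# 0-based half-open interval -> GRanges (1-based inclusive)
interval_to_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$contig,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = iv$strand
  )
}

# uniform ACGT random sequence using the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
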