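.sno_defaults <- function() {
  list(
    # Box tolerances. "Intact" boxes are quantified as maximum Hamming
    # distance to the degenerate consensus: D (CUGA) is the shortest and most
    # constrained box (0 mismatches); C tolerates the known RUGAUGA
    # variation (1); the internal C'/D' copies are often imperfect (2/1).
    boxes.c_max_mismatch      = 1L,
    boxes.d_max_mismatch      = 0L,
    boxes.cprime_max_mismatch = 2L,
    boxes.dprime_max_mismatch = 1L,
    boxes.h_max_mismatch      = 0L,
    boxes.aca_max_mismatch    = 0L,
    # Candidate layout geometry (typical vertebrate C/D sizes).
    layout.min_len  = 50L,
    layout.max_len  = 120L,
    layout.c_window = 12L,   # C box must start within this many nt of the 5' end
    layout.d_window = 12L,   # D box must end within this many nt of the 3' end
    # Terminal stem ("short inverted repeats" flanking the boxes).
    stem.min_pairs     = 4L,
    stem.max_gu        = 1L,
    stem.search_window = 8L,
    # H/ACA layout.
    haca.min_len    = 100L,
    haca.max_len    = 160L,
    haca.aca_offset = 3L,    # nt between ACA box end and the 3' end
    # Antisense element / guide duplex ("usually from 9 to 20 nt").
    element.min_len          = 9L,
    element.max_len          = 20L,
    element.max_gu           = 3L,
    element.allow_gu_at_site = TRUE,
    # Target RNAs that cannot carry 2'-O-methyl marks in eukaryotes
    # (comma-separated id patterns, case-insensitive).
    targets.disallowed = "5S",
    # Relaxed seeded homolog search (word size 3, first gap character cost 1).
    search.word_size    = 3L,
    search.match        = 1,
    search.mismatch     = -1,
    search.gap_open     = 1,
    search.gap_extend   = 1,
    search.xdrop        = 10,
    search.min_score    = 16,
    search.both_strands = TRUE,
    # Classifier. min_identity_pct gates family membership in the
    # discovery pipeline: below ~75% nucleotide identity (the alignment
    # twilight zone) an assignment of a locus to a specific family is not
    # trustworthy and the locus is dropped as background.
    # Identity is only meaningful over a substantial alignment: membership
    # additionally needs at least min_aln_len aligned columns, about the
    # shortest credible C/D fragment (C box + 9-nt element + D box + stems).
    classify.full_length_frac    = 0.9,
    classify.diag_extra_mismatch = 2L,
    classify.min_identity_pct    = 75,
    classify.min_aln_len         = 30L
  )
}

#' Analysis parameters
#'
#' Returns the package's flat, namespaced parameter set, optionally
#' overridden. Unknown keys are rejected with the list of valid keys, so a
#' typo cannot silently fall back to a default.
#'
#' @param ... Named overrides, e.g. `sno_params(layout.max_len = 200L)`.
#' @return A named list of class `sno_params`.
#' @seealso [read_params()] for loading overrides from a `key = value` file.
#' @examples
#' p <- sno_params(boxes.d_max_mismatch = 1L)
#' p$boxes.d_max_mismatch
#' @export
sno_params <- function(...) {
  p <- .sno_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      sno_stop("all parameter overrides must be named")
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      sno_stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
               "\nvalid keys: ", paste(names(p), collapse = ", "))
    }
    p <- modifyList(p, dots)
  }
  structure(p, class = c("sno_params", "list"))
}

#' Read parameters from a flat key=value file
#'
#' The file format is TOML-style flat assignments, one `key = value` per
#' line; `#` starts a comment. Values are coerced to the type of the
#' corresponding default. Unknown keys are rejected.
#'
#' @param path Path to the parameter file.
#' @param base Parameter set to override (default [sno_params()]).
#' @return A `sno_params` object.
#' @export
read_params <- function(path, base = sno_params()) {
  if (!file.exists(path)) sno_stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      sno_stop("malformed parameter line (expected key = value): '", ln, "'")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (!key %in% names(base)) {
      sno_stop("unknown parameter '", key, "'\nvalid keys: ",
               paste(names(base), collapse = ", "))
    }
    proto <- base[[key]]
    overrides[[key]] <- if (is.logical(proto)) {
      toupper(val) %in% c("TRUE", "T", "YES", "1")
    } else if (is.integer(proto)) {
      as.integer(val)
    } else if (is.numeric(proto)) {
      as.numeric(val)
    } else {
      val
    }
  }
  p <- modifyList(base, overrides)
  structure(p, class = c("sno_params", "list"))
}
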