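# Degenerate-consensus box detection and C/D candidate layout assembly.
# Box consensus sequences (DNA lettering): C = TGATGA, D = CTGA, H = ANANNA,
# ACA = ACA; the internal C'/D' copies reuse the C/D patterns with relaxed
# mismatch tolerance.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

BOX_PATTERNS <- c(C = "TGATGA", D = "CTGA", Cprime = "TGATGA",
                  Dprime = "CTGA", H = "ANANNA", ACA = "ACA")

#' Box consensus definition
#'
#' @param name One of `C`, `D`, `Cprime`, `Dprime`, `H`, `ACA`.
#' @param max_mismatch Maximum Hamming distance tolerated; defaults come
#'   from [sno_params()].
#' @param pattern IUPAC pattern; defaults to the canonical consensus for
#'   `name`.
#' @return A list of class `box_consensus`.
#' @export
box_consensus <- function(name, max_mismatch = NULL, pattern = NULL) {
  name <- match.arg(name, names(BOX_PATTERNS))
  if (is.null(pattern)) pattern <- BOX_PATTERNS[[name]]
  pattern <- normalize_seq(pattern)
  if (!nzchar(pattern)) sno_stop("box pattern must be non-empty")
  if (any(!seq_chars(pattern) %in% names(IUPAC_SETS))) {
    sno_stop("box pattern contains a non-IUPAC character: ", pattern)
  }
  if (is.null(max_mismatch)) {
    p <- sno_params()
    key <- paste0("boxes.", tolower(sub("prime", "prime", name)), "_max_mismatch")
    key <- switch(name,
                  C = "boxes.c_max_mismatch", D = "boxes.d_max_mismatch",
                  Cprime = "boxes.cprime_max_mismatch",
                  Dprime = "boxes.dprime_max_mismatch",
                  H = "boxes.h_max_mismatch", ACA = "boxes.aca_max_mismatch")
    max_mismatch <- p[[key]]
  }
  if (max_mismatch < 0L) sno_stop("max_mismatch must be >= 0")
  structure(list(name = name, pattern = pattern,
                 max_mismatch = as.integer(max_mismatch)),
            class = "box_consensus")
}

#' Scan a sequence window for a degenerate box consensus
#'
#' Returns every start position in the window where the Hamming distance to
#' the IUPAC pattern (degenerate positions match their allowed set, `N`
#' matches anything) is at most `consensus$max_mismatch`. An `N` in the
#' *sequence* matches nothing except pattern `N`.
#'
#' @param seq Nucleotide string (DNA lettering; U accepted and folded to T).
#' @param consensus A [box_consensus].
#' @param window 0-based half-open `(start, end)` within `seq`; the whole
#'   match must lie inside the window. Default: the full sequence.
#' @return data.frame with columns `box`, `start` (0-based), `mismatches`,
#'   sorted by (`mismatches`, `start`).
#' @examples
#' match_box("AATGATGAAA", box_consensus("C", 0L))  # start 2
#' @export
match_box <- function(seq, consensus, window = NULL) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  plen <- nchar(consensus$pattern)
  if (is.null(window)) window <- c(0L, n)
  if (window[1] < 0L || window[2] > n || window[1] > window[2]) {
    sno_stop("window [", window[1], ",", window[2], ") out of range for length ", n)
  }
  empty <- data.frame(box = character(0), start = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  last <- window[2] - plen
  if (last < window[1]) return(empty)
  starts <- window[1]:last
  sc <- seq_chars(seq)
  pc <- seq_chars(consensus$pattern)
  mism <- integer(length(starts))
  for (k in seq_len(plen)) {
    allowed <- IUPAC_SETS[[pc[k]]]
    obs <- sc[starts + k]           # starts are 0-based; +k gives 1-based index
    bad <- !(obs %in% allowed)
    if (identical(allowed, c("A", "C", "G", "T"))) bad[] <- FALSE  # pattern N
    mism <- mism + as.integer(bad)
  }
  keep <- mism <= consensus$max_mismatch
  out <- data.frame(box = rep(consensus$name, sum(keep)), start = starts[keep],
                    mismatches = mism[keep], stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

# best internal hit strictly inside (from, to), or NULL
.best_internal_box <- function(seq, consensus, from, to) {
  if (to - from < nchar(consensus$pattern)) return(NULL)
  hits <- match_box(seq, consensus, window = c(from, to))
  if (!nrow(hits)) return(NULL)
  as.list(hits[1, ])
}

#' Scan a candidate-scale sequence for C/D box layouts
#'
#' Pairs every C-box hit starting within `layout.c_window` nt of the 5' end
#' with every D-box hit ending within `layout.d_window` nt of the 3' end,
#' provided the sequence length lies in `[layout.min_len, layout.max_len]`.
#' For each pair the best internal D' (and then C', downstream of D') hit
#' between the boxes is attached when present, and the terminal stem is
#' searched. No two layouts share the same `(c_box$start, d_box$start)`.
#'
#' @param seq Nucleotide string.
#' @param params [sno_params()].
#' @return List of `cd_layout` objects (possibly empty), ordered by
#'   total box mismatches then position. Each layout carries `seq`, `c_box`,
#'   `d_box`, `dprime_box`, `cprime_box` (each a list with `start`,
#'   `mismatches`, or NULL) and `stem` (see [find_terminal_stem()]).
#' @export
scan_cd_layouts <- function(seq, params = sno_params()) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < params$layout.min_len || n > params$layout.max_len) return(list())
  cb <- box_consensus("C", params$boxes.c_max_mismatch)
  db <- box_consensus("D", params$boxes.d_max_mismatch)
  c_hits <- match_box(seq, cb, window = c(0L, min(n, params$layout.c_window + nchar(cb$pattern) - 1L)))
  c_hits <- c_hits[c_hits$start < params$layout.c_window, , drop = FALSE]
  d_lo <- max(0L, n - params$layout.d_window)
  d_hits <- match_box(seq, db, window = c(d_lo, n))
  d_hits <- d_hits[d_hits$start + nchar(db$pattern) > n - params$layout.d_window, , drop = FALSE]
  if (!nrow(c_hits) || !nrow(d_hits)) return(list())

  dpb <- box_consensus("Dprime", params$boxes.dprime_max_mismatch)
  cpb <- box_consensus("Cprime", params$boxes.cprime_max_mismatch)
  layouts <- list()
  for (i in seq_len(nrow(c_hits))) {
    for (j in seq_len(nrow(d_hits))) {
      c_start <- c_hits$start[i]
      d_start <- d_hits$start[j]
      c_end <- c_start + nchar(cb$pattern)
      if (d_start <= c_end) next
      dprime <- .best_internal_box(seq, dpb, c_end, d_start)
      cprime <- NULL
      if (!is.null(dprime)) {
        cprime <- .best_internal_box(seq, cpb, dprime$start + nchar(dpb$pattern), d_start)
      } else {
        cprime <- .best_internal_box(seq, cpb, c_end, d_start)
      }
      layout <- structure(list(
        seq = seq,
        c_box = list(box = "C", start = c_start, mismatches = c_hits$mismatches[i]),
        d_box = list(box = "D", start = d_start, mismatches = d_hits$mismatches[j]),
        dprime_box = dprime, cprime_box = cprime, stem = NULL
      ), class = "cd_layout")
      layout$stem <- find_terminal_stem(layout, params)
      layouts[[length(layouts) + 1L]] <- layout
    }
  }
  ord <- order(vapply(layouts, function(l) l$c_box$mismatches + l$d_box$mismatches, numeric(1)),
               vapply(layouts, function(l) l$c_box$start, numeric(1)),
               vapply(layouts, function(l) l$d_box$start, numeric(1)))
  layouts[ord]
}

#' @export
print.cd_layout <- function(x, ...) {
  cat(sprintf("<cd_layout> %d nt; C@%d(%dmm) D@%d(%dmm)%s%s%s\n",
              nchar(x$seq), x$c_box$start, x$c_box$mismatches,
              x$d_box$start, x$d_box$mismatches,
              if (!is.null(x$dprime_box)) sprintf(" D'@%d", x$dprime_box$start) else "",
              if (!is.null(x$cprime_box)) sprintf(" C'@%d", x$cprime_box$start) else "",
              if (!is.null(x$stem)) sprintf(" stem %dbp", x$stem$paired_len) else " no-stem"))
  invisible(x)
}

# pair classification for a putative stem/duplex pair of DNA letters:
# returns "WC", "GU" or NA
.pair_class <- function(a, b) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  out <- rep(NA_character_, length(a))
  out[gu] <- "GU"
  out[wc] <- "WC"
  out
}

#' Find the terminal stem of a C/D layout
#'
#' Searches for the longest ungapped complementary pairing (Watson-Crick
#' plus G-U wobble) between a window of `stem.search_window` nt ending at
#' the C box start and a window of the same size starting at the D box end;
#' this is the short inverted repeat that folds the two boxes together.
#' Reported only if at least `stem.min_pairs` long with at most
#' `stem.max_gu` G-U pairs. Length ties are broken toward the outermost
#' (most terminal) pairing: smallest 5' start, then largest 3' end.
#'
#' @param layout A `cd_layout` (needs `c_box` and `d_box`).
#' @param params [sno_params()].
#' @return A list with `five_prime` and `three_prime` 0-based half-open
#'   intervals, `paired_len`, `gu_pairs`; or `NULL` when no qualifying stem
#'   exists.
#' @export
find_terminal_stem <- function(layout, params = sno_params()) {
  if (is.null(layout$c_box) || is.null(layout$d_box)) {
    sno_stop("layout must carry C and D boxes")
  }
  s <- seq_chars(layout$seq)
  n <- length(s)
  sw <- params$stem.search_window
  w5 <- c(max(0L, layout$c_box$start - sw), layout$c_box$start)
  d_end <- layout$d_box$start + nchar(BOX_PATTERNS[["D"]])
  w3 <- c(d_end, min(n, d_end + sw))
  if (w5[2] - w5[1] < params$stem.min_pairs || w3[2] - w3[1] < params$stem.min_pairs) {
    return(NULL)
  }
  best <- NULL
  for (a in w5[1]:(w5[2] - 1L)) {
    for (b in w3[1]:(w3[2] - 1L)) {
      maxL <- min(w5[2] - a, w3[2] - b)
      if (maxL < params$stem.min_pairs) next
      for (L in maxL:params$stem.min_pairs) {
        # 5' segment [a, a+L) pairs antiparallel with 3' segment [b, b+L)
        cls <- .pair_class(s[(a + 1L):(a + L)], s[(b + L):(b + 1L)])
        if (anyNA(cls)) next
        gu <- sum(cls == "GU")
        if (gu > params$stem.max_gu) next
        cand <- list(five_prime = c(a, a + L), three_prime = c(b, b + L),
                     paired_len = L, gu_pairs = gu)
        if (is.null(best) ||
            L > best$paired_len ||
            (L == best$paired_len &&
             (a < best$five_prime[1] ||
              (a == best$five_prime[1] && b + L > best$three_prime[2])))) {
          best <- cand
        }
        break  # longer L already tried; shorter sub-pairings are not maximal
      }
    }
  }
  best
}

#' Scan for H/ACA box layouts
#'
#' Pairs H-box (ANANNA) hits in the interior third of the sequence with an
#' ACA-box hit at exactly `haca.aca_offset` nt from the 3' end. Hairpin
#' structure is not verified.
#'
#' @param seq Nucleotide string of length at least `haca.min_len`.
#' @param params [sno_params()].
#' @return List of layouts, each a list with `h_box` and `aca_box` hits.
#' @export
scan_haca_layouts <- function(seq, params = sno_params()) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n < params$haca.min_len || n > params$haca.max_len) return(list())
  hb <- box_consensus("H", params$boxes.h_max_mismatch)
  ab <- box_consensus("ACA", params$boxes.aca_max_mismatch)
  h_hits <- match_box(seq, hb)
  lo <- floor(n / 3); hi <- floor(2 * n / 3)
  h_hits <- h_hits[h_hits$start >= lo & h_hits$start < hi, , drop = FALSE]
  aca_start <- n - nchar(ab$pattern) - params$haca.aca_offset
  if (aca_start < 0L) return(list())
  a_hits <- match_box(seq, ab, window = c(aca_start, aca_start + nchar(ab$pattern)))
  if (!nrow(h_hits) || !nrow(a_hits)) return(list())
  out <- list()
  for (i in seq_len(nrow(h_hits))) {
    out[[length(out) + 1L]] <- list(
      h_box = as.list(h_hits[i, ]),
      aca_box = as.list(a_hits[1, ])
    )
  }
  out
}
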