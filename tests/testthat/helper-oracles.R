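# Independent brute-force oracles. These deliberately re-derive results from
# the stated rules with naive loops (no code shared with the package
# internals) so implementation and oracle can disagree.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive degenerate Hamming scan
oracle_match_positions <- function(seq, pattern, max_mm,
                                   window = c(0, nchar(seq))) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  out <- data.frame(start = integer(0), mismatches = integer(0))
  if (window[2] - window[1] < length(p)) return(out)
  for (st in window[1]:(window[2] - length(p))) {
    mm <- 0L
    for (k in seq_along(p)) {
      if (!s[st + k] %in% ORACLE_IUPAC[[p[k]]]) mm <- mm + 1L
    }
    if (mm <= max_mm) out <- rbind(out, data.frame(start = st, mismatches = mm))
  }
  out[order(out$mismatches, out$start), , drop = FALSE]
}

# WC/GU pair test on DNA letters (a 5'->3' strand base vs its partner)
oracle_pairs <- function(a, b) {
  wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  gu <- (a == "G" && b == "T") || (a == "T" && b == "G")
  if (wc) "WC" else if (gu) "GU" else NA_character_
}

# exhaustive C/D layout enumeration following the same stated rules as
# scan_cd_layouts: C hit starting within c_window of the 5' end, D hit
# ending within d_window of the 3' end, sequence length within
# [min_len, max_len]; best D' then C' strictly between; returns a data
# frame of box start positions (one row per (C, D) pair), unordered.
oracle_scan_cd <- function(seq, params) {
  n <- nchar(seq)
  out <- data.frame(c_start = integer(0), d_start = integer(0),
                    dprime_start = integer(0), cprime_start = integer(0))
  if (n < params$layout.min_len || n > params$layout.max_len) return(out)
  c_hits <- oracle_match_positions(seq, "TGATGA", params$boxes.c_max_mismatch)
  c_hits <- c_hits[c_hits$start < params$layout.c_window, , drop = FALSE]
  d_hits <- oracle_match_positions(seq, "CTGA", params$boxes.d_max_mismatch)
  d_hits <- d_hits[d_hits$start >= n - params$layout.d_window &
                     d_hits$start + 4L <= n, , drop = FALSE]
  for (ci in seq_len(nrow(c_hits))) {
    for (di in seq_len(nrow(d_hits))) {
      cs <- c_hits$start[ci]; ds <- d_hits$start[di]
      if (ds <= cs + 6L) next
      dp <- oracle_match_positions(seq, "CTGA", params$boxes.dprime_max_mismatch,
                                   window = c(cs + 6L, ds))
      dps <- if (nrow(dp)) dp$start[1] else NA_integer_
      cp_lo <- if (!is.na(dps)) dps + 4L else cs + 6L
      cp <- oracle_match_positions(seq, "TGATGA", params$boxes.cprime_max_mismatch,
                                   window = c(cp_lo, ds))
      cps <- if (nrow(cp)) cp$start[1] else NA_integer_
      out <- rbind(out, data.frame(c_start = cs, d_start = ds,
                                   dprime_start = dps, cprime_start = cps))
    }
  }
  out
}

# brute-force ungapped antiparallel duplex enumeration: every maximal run
# of paired (WC or GU) positions between guide i and target j where
# consecutive guide positions pair consecutive *decreasing* target
# positions; returns guide start, length, target start (0-based) and GU
# count for runs passing the length/GU filters.
oracle_duplexes <- function(guide, target, params) {
  g <- strsplit(guide, "")[[1]]
  t <- strsplit(target, "")[[1]]
  ng <- length(g); nt <- length(t)
  runs <- data.frame(g_start = integer(0), len = integer(0),
                     t_start = integer(0), gu = integer(0))
  for (i0 in seq_len(ng)) {
    for (j0 in seq_len(nt)) {
      # start of a run: previous antidiagonal cell unpaired or out of range
      prev_ok <- i0 > 1L && j0 < nt && !is.na(oracle_pairs(g[i0 - 1L], t[j0 + 1L]))
      if (prev_ok) next
      if (is.na(oracle_pairs(g[i0], t[j0]))) next
      L <- 0L; gu <- 0L
      while (i0 + L <= ng && j0 - L >= 1L) {
        cls <- oracle_pairs(g[i0 + L], t[j0 - L])
        if (is.na(cls)) break
        if (cls == "GU") gu <- gu + 1L
        L <- L + 1L
      }
      if (L >= params$element.min_len && L <= params$element.max_len &&
          gu <= params$element.max_gu) {
        runs <- rbind(runs, data.frame(g_start = i0 - 1L, len = L,
                                       t_start = j0 - L, gu = gu))
      }
    }
  }
  runs
}

# Smith-Waterman oracle with the package's WU-BLAST-style gap costs
# (first gap char = go, extension = ge), via Biostrings
oracle_sw_score <- function(q, s, match = 1, mismatch = -1, go = 1, ge = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = go - ge, gapExtension = ge))
}

# exhaustive ends-free global alignment of two short strings: returns the
# identities (matches / columns, terminal-gap columns excluded) of all
# score-optimal alignments
oracle_overlap_identities <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- new.env(); best$score <- -Inf; best$idents <- numeric(0)
  recurse <- function(i, j, cols) {
    if (i > length(A) && j > length(B)) {
      # score / identity over the alignment, terminal gaps free/excluded
      if (nrow(cols)) {
        lead <- cumprod(cols$gap) == 1
        trail <- rev(cumprod(rev(cols$gap)) == 1)
        core <- cols[!(lead | trail), , drop = FALSE]
      } else core <- cols
      sc <- if (nrow(core)) sum(core$score) else 0
      id <- if (nrow(core)) 100 * sum(core$match) / nrow(core) else 0
      if (sc > best$score) { best$score <- sc; best$idents <- id }
      else if (sc == best$score) best$idents <- c(best$idents, id)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      m <- A[i] == B[j]
      recurse(i + 1L, j + 1L,
              rbind(cols, data.frame(score = if (m) match else mismatch,
                                     match = m, gap = FALSE)))
    }
    if (i <= length(A)) {
      recurse(i + 1L, j, rbind(cols, data.frame(score = -gap, match = FALSE,
                                                gap = TRUE)))
    }
    if (j <= length(B)) {
      recurse(i, j + 1L, rbind(cols, data.frame(score = -gap, match = FALSE,
                                                gap = TRUE)))
    }
  }
  recurse(1L, 1L, data.frame(score = numeric(0), match = logical(0),
                             gap = logical(0)))
  list(score = best$score, identities = unique(best$idents))
}
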