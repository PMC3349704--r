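# Antisense-element detection against target RNAs, methylation-site
# prediction by the four-nucleotide D/D'-box offset rule, and validation of
# claimed guide/target assignments.
#
# Offset convention (stated once, used everywhere): the 2'-O-methylated
# target nucleotide is the one paired with the guide position that has
# exactly 4 candidate nucleotides strictly between it and the first
# nucleotide of the D or D' box, i.e. guide partner index = box start - 5
# (0-based).

#' Guide-region window upstream of a D or D' box
#'
#' The antisense element lies immediately 5' of the D (or D') box. The
#' returned window spans up to `element.max_len` nt ending at the
#' nucleotide immediately 5' of the box start, clipped at the end of the
#' preceding box (C' or D' for the D box; C for the D' box).
#'
#' @param layout A `cd_layout` from [scan_cd_layouts()].
#' @param via_box `"D"` or `"Dprime"`.
#' @param params [sno_params()].
#' @return 0-based half-open `c(start, end)` within the candidate sequence.
#' @export
extract_guide_region <- function(layout, via_box = c("D", "Dprime"),
                                 params = sno_params()) {
  via_box <- match.arg(via_box)
  box_len <- function(name) nchar(BOX_PATTERNS[[name]])
  if (via_box == "D") {
    bs <- layout$d_box$start
    preceding <- layout$c_box$start + box_len("C")
    if (!is.null(layout$dprime_box)) {
      preceding <- max(preceding, layout$dprime_box$start + box_len("Dprime"))
    }
    if (!is.null(layout$cprime_box)) {
      preceding <- max(preceding, layout$cprime_box$start + box_len("Cprime"))
    }
  } else {
    if (is.null(layout$dprime_box)) sno_stop("layout has no D' box")
    bs <- layout$dprime_box$start
    preceding <- layout$c_box$start + box_len("C")
  }
  start <- max(bs - params$element.max_len, preceding)
  if (start >= bs) sno_stop("no room for a guide region 5' of the ", via_box, " box")
  c(start, bs)
}

#' Find ungapped guide:target duplexes
#'
#' Enumerates all maximal ungapped antiparallel pairings between the guide
#' region and each target RNA in which every position is Watson-Crick or
#' G-U paired. A pairing is maximal when it cannot be extended by another
#' paired position on either side. Pairings are then filtered to length in
#' `[element.min_len, element.max_len]` and at most `element.max_gu` G-U
#' pairs, and sorted by (length desc, G-U count asc, target id, target
#' start). G-U pairs count toward the element length.
#'
#' @param guide_seq Guide-region nucleotide string (5'->3').
#' @param candidate_offset 0-based offset of `guide_seq` within the
#'   candidate sequence (used to report guide intervals in candidate
#'   coordinates).
#' @param targets List of [sno_seq] target RNAs.
#' @param params [sno_params()].
#' @return List of `duplex_hit` objects: `guide_interval` and
#'   `target_interval` (0-based half-open; target interval in target
#'   coordinates), `target_id`, `pairs` (vector of `"WC"`/`"GU"`, ordered
#'   5'->3' along the guide), `gu_count`.
#' @export
find_duplexes <- function(guide_seq, candidate_offset, targets,
                          params = sno_params()) {
  if (params$element.min_len < 1L) sno_stop("element.min_len must be >= 1")
  guide_seq <- normalize_seq(guide_seq)
  g <- seq_chars(guide_seq)
  ng <- length(g)
  hits <- list()
  for (tr in targets) {
    rc <- seq_chars(revcomp(tr$seq))
    nt <- length(rc)
    # align guide index i (0-based) with revcomp(target) index n = i + d;
    # a WC pair is an exact letter match, wobble G:U appears as guide G vs
    # rc A, or guide T vs rc C.
    for (d in (-(ng - 1L)):(nt - 1L)) {
      i0 <- max(0L, -d)
      i1 <- min(ng - 1L, nt - 1L - d)
      if (i1 - i0 + 1L < params$element.min_len) next
      gi <- g[(i0 + 1L):(i1 + 1L)]
      ri <- rc[(i0 + d + 1L):(i1 + d + 1L)]
      wc <- gi == ri & gi %in% c("A", "C", "G", "T")
      gu <- (gi == "G" & ri == "A") | (gi == "T" & ri == "C")
      paired <- wc | gu
      # maximal runs of paired positions
      r <- rle(paired)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        L <- r$lengths[k]
        if (L < params$element.min_len || L > params$element.max_len) next
        sel <- starts[k]:ends[k]
        gu_n <- sum(gu[sel])
        if (gu_n > params$element.max_gu) next
        gs <- i0 + starts[k] - 1L          # 0-based guide start
        ns <- gs + d                        # 0-based start in revcomp(target)
        hits[[length(hits) + 1L]] <- structure(list(
          guide_interval = c(candidate_offset + gs, candidate_offset + gs + L),
          target_id = tr$id,
          target_interval = c(nt - (ns + L), nt - ns),
          pairs = ifelse(gu[sel], "GU", "WC"),
          gu_count = gu_n
        ), class = "duplex_hit")
      }
    }
  }
  if (!length(hits)) return(hits)
  ord <- order(-vapply(hits, function(h) length(h$pairs), numeric(1)),
               vapply(hits, function(h) h$gu_count, numeric(1)),
               vapply(hits, function(h) h$target_id, character(1)),
               vapply(hits, function(h) h$target_interval[1], numeric(1)))
  hits[ord]
}

#' Predict the 2'-O-methylation site implied by a duplex
#'
#' Applies the four-nucleotide rule: with `b` the 0-based start of the D or
#' D' box, the guide partner of the methylated target nucleotide is index
#' `b - 5`, leaving exactly 4 candidate nucleotides strictly between it and
#' the box. A prediction is returned only when that index falls inside the
#' duplex guide interval (and, if `element.allow_gu_at_site` is `FALSE`,
#' is not a G-U pair).
#'
#' @param layout A `cd_layout`.
#' @param duplex A `duplex_hit` supported by the guide region of `via_box`.
#' @param via_box `"D"` or `"Dprime"`.
#' @param params [sno_params()].
#' @return A `target_site_prediction` list (`target_id`, `position`
#'   1-based, `modification`, `via_box`, `guide_partner_index` 0-based), or
#'   `NULL` when the rule places the partner outside the duplex.
#' @export
predict_methylation_site <- function(layout, duplex, via_box = c("D", "Dprime"),
                                     params = sno_params()) {
  via_box <- match.arg(via_box)
  b <- if (via_box == "D") layout$d_box$start else {
    if (is.null(layout$dprime_box)) sno_stop("layout has no D' box")
    layout$dprime_box$start
  }
  p <- b - 5L
  gi <- duplex$guide_interval
  if (p < gi[1] || p >= gi[2]) return(NULL)
  k <- p - gi[1]
  if (!params$element.allow_gu_at_site && duplex$pairs[k + 1L] == "GU") return(NULL)
  structure(list(
    target_id = duplex$target_id,
    position = duplex$target_interval[2] - k,  # 0-based partner + 1
    modification = "2primeOmethyl",
    via_box = via_box,
    guide_partner_index = p
  ), class = "target_site_prediction")
}

VIOLATION_CODES <- c("OFFSET_GT4", "ELEMENT_NOT_ADJACENT", "ELEMENT_IS_INTERBOX_SPAN",
                     "TARGET_DISALLOWED", "SITE_UNPAIRED", "DUPLEX_TOO_SHORT")

.disallowed_target <- function(target_id, params) {
  pats <- trimws(strsplit(params$targets.disallowed, ",", fixed = TRUE)[[1]])
  pats <- pats[nzchar(pats)]
  any(vapply(pats, function(p) grepl(p, target_id, ignore.case = TRUE), logical(1)))
}

#' Validate a claimed antisense element / target assignment
#'
#' Checks a claimed guide element and target against the C/D guide rules
#' and returns a verdict with machine-readable violation codes:
#' `TARGET_DISALLOWED` (target id matches the disallowed list, by default
#' 5S rRNA, which carries no 2'-O-methyl marks in eukaryotes);
#' `ELEMENT_IS_INTERBOX_SPAN` (the claimed element is just the full C-D' or
#' C'-D inter-box fragment rather than a specific guide);
#' `DUPLEX_TOO_SHORT` (no qualifying duplex of at least `element.min_len`
#' supports the claim); `SITE_UNPAIRED` (the claimed site has no pairing
#' partner in any duplex); `OFFSET_GT4` (the claimed site's guide partner
#' lies more than four nucleotides from the nearest downstream D/D' box).
#'
#' @param layout A `cd_layout` for the candidate.
#' @param claimed_element 0-based half-open `c(start, end)` within the
#'   candidate sequence.
#' @param claimed_target A [sno_seq] target RNA.
#' @param claimed_site 1-based position in the target RNA, or `NULL`.
#' @param params [sno_params()].
#' @return A `target_validation` list: `verdict`
#'   (`"consistent"`/`"inconsistent"`), `violations` (character vector),
#'   `duplexes` (supporting duplex hits).
#' @export
validate_claimed_target <- function(layout, claimed_element, claimed_target,
                                    claimed_site = NULL, params = sno_params()) {
  n <- nchar(layout$seq)
  if (claimed_element[1] < 0L || claimed_element[2] > n ||
      claimed_element[1] >= claimed_element[2]) {
    sno_stop("claimed element outside the candidate sequence")
  }
  if (!is.null(claimed_site) && is.na(claimed_site)) claimed_site <- NULL
  if (!is.null(claimed_site) &&
      (claimed_site < 1L || claimed_site > nchar(claimed_target$seq))) {
    sno_stop("claimed site ", claimed_site, " outside target '",
             claimed_target$id, "'")
  }
  violations <- character(0)

  if (.disallowed_target(claimed_target$id, params)) {
    violations <- c(violations, "TARGET_DISALLOWED")
  }

  box_len <- function(name) nchar(BOX_PATTERNS[[name]])
  spans <- list()
  if (!is.null(layout$dprime_box)) {
    spans$c_dprime <- c(layout$c_box$start + box_len("C"), layout$dprime_box$start)
  }
  if (!is.null(layout$cprime_box)) {
    spans$cprime_d <- c(layout$cprime_box$start + box_len("Cprime"), layout$d_box$start)
  }
  for (sp in spans) {
    if (identical(as.integer(claimed_element), as.integer(sp))) {
      violations <- c(violations, "ELEMENT_IS_INTERBOX_SPAN")
      break
    }
  }

  guide_seq <- substr(layout$seq, claimed_element[1] + 1L, claimed_element[2])
  duplexes <- find_duplexes(guide_seq, claimed_element[1], list(claimed_target), params)
  if (!length(duplexes)) {
    violations <- c(violations, "DUPLEX_TOO_SHORT")
  }

  if (!is.null(claimed_site)) {
    site0 <- claimed_site - 1L
    covering <- Filter(function(h) site0 >= h$target_interval[1] &&
                         site0 < h$target_interval[2], duplexes)
    if (!length(covering)) {
      violations <- c(violations, "SITE_UNPAIRED")
    } else {
      best <- covering[[1]]
      k <- best$target_interval[2] - 1L - site0
      p <- best$guide_interval[1] + k
      box_starts <- c(layout$d_box$start,
                      if (!is.null(layout$dprime_box)) layout$dprime_box$start)
      downstream <- box_starts[box_starts > p]
      nt_between <- if (length(downstream)) min(downstream) - 1L - p else Inf
      if (nt_between > 4L) violations <- c(violations, "OFFSET_GT4")
    }
  }

  violations <- intersect(VIOLATION_CODES, violations)  # canonical order
  structure(list(
    verdict = if (length(violations)) "inconsistent" else "consistent",
    violations = violations,
    duplexes = duplexes
  ), class = "target_validation")
}
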