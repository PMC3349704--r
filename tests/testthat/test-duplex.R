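test_that("extract_guide_region clips at the preceding box", {
  s <- strrep("A", 80)
  # D box at 70, C' ending at 45: window limited by max_element_len (20)
  lay <- bare_layout(s, c_start = 4L, d_start = 70L, cprime_start = 39L)
  expect_equal(extract_guide_region(lay, "D"), c(50L, 70L))
  # D' box at 30, C box ending at 16: clipped at the C box
  lay <- bare_layout(s, c_start = 10L, d_start = 70L, dprime_start = 30L)
  expect_equal(extract_guide_region(lay, "Dprime"), c(16L, 30L))
  # no internal boxes, C ends at 16 but window is only 20 nt
  lay <- bare_layout(s, c_start = 10L, d_start = 70L)
  expect_equal(extract_guide_region(lay, "D"), c(50L, 70L))
  expect_error(extract_guide_region(lay, "Dprime"), "no D' box")
})

test_that("find_duplexes reports perfect and wobble pairings with the G-U budget", {
  set.seed(201)
  target <- fixture_target()
  guide <- oracle_revcomp(substr(target$seq, 101, 112))  # 12-nt perfect guide
  hits <- find_duplexes(guide, 0L, list(target))
  expect_true(length(hits) >= 1L)
  top <- hits[[1]]
  expect_equal(top$target_interval, c(100L, 112L))
  expect_equal(top$guide_interval, c(0L, 12L))
  expect_true(all(top$pairs == "WC"))
  expect_equal(top$gu_count, 0L)

  # turn one pair into G-U: target A (guide T) -> target G keeps a T:G wobble
  tchars <- strsplit(target$seq, "")[[1]]
  a_pos <- which(tchars[101:112] == "A")[1]
  skip_if(is.na(a_pos))  # fixed seed provides one
  tchars[100 + a_pos] <- "G"
  t2 <- sno_seq("t2", paste(tchars, collapse = ""))
  hits_gu <- find_duplexes(guide, 0L, list(t2))
  with_site <- Filter(function(h) h$target_interval[1] <= 100 &&
                        h$target_interval[2] >= 112, hits_gu)
  expect_length(with_site, 1L)
  expect_equal(with_site[[1]]$gu_count, 1L)
  strict <- find_duplexes(guide, 0L, list(t2), sno_params(element.max_gu = 0L))
  expect_length(Filter(function(h) h$target_interval[1] <= 100 &&
                         h$target_interval[2] >= 112, strict), 0L)

  # 8-nt complementarity is below the 9-nt element minimum
  short_guide <- oracle_revcomp(substr(target$seq, 101, 108))
  hits8 <- find_duplexes(short_guide, 0L, list(target))
  expect_length(Filter(function(h) h$target_interval[1] == 100, hits8), 0L)
})

test_that("find_duplexes equals the brute-force all-pairs scan", {
  set.seed(202)
  params <- sno_params()
  for (rep in 1:8) {
    guide <- random_seq(sample(12:20, 1))
    target <- sno_seq("t", random_seq(60))
    # implant a complement so non-empty cases occur
    if (rep %% 2 == 0) {
      at <- sample(5:40, 1)
      tch <- strsplit(target$seq, "")[[1]]
      tch[at:(at + 11)] <- strsplit(oracle_revcomp(substr(guide, 1, 12)), "")[[1]]
      target <- sno_seq("t", paste(tch, collapse = ""))
    }
    got <- find_duplexes(guide, 0L, list(target), params)
    want <- oracle_duplexes(guide, target$seq, params)
    expect_equal(length(got), nrow(want))
    if (length(got)) {
      key <- function(g, L, t) paste(g, L, t)
      got_keys <- sort(vapply(got, function(h)
        key(h$guide_interval[1], diff(h$guide_interval), h$target_interval[1]),
        character(1)))
      want_keys <- sort(key(want$g_start, want$len, want$t_start))
      expect_equal(got_keys, want_keys)
    }
  }
})

test_that("predict_methylation_site applies the four-nucleotide rule", {
  # D box at 60, duplex over guide (48,60) and target (100,112):
  # the partner of guide index 55 read off the antiparallel map is
  # target index 100 + (112 - 100 - 1) - (55 - 48) = 104, reported 105
  lay <- bare_layout(strrep("A", 70), c_start = 2L, d_start = 60L)
  dup <- structure(list(guide_interval = c(48L, 60L), target_id = "t",
                        target_interval = c(100L, 112L),
                        pairs = rep("WC", 12L), gu_count = 0L),
                   class = "duplex_hit")
  pred <- predict_methylation_site(lay, dup, "D")
  expect_equal(pred$guide_partner_index, 55L)
  expect_equal(pred$position, 105L)
  expect_equal(pred$via_box, "D")
  expect_equal(pred$modification, "2primeOmethyl")
  # element not adjacent: partner index outside the duplex
  dup2 <- dup; dup2$guide_interval <- c(40L, 52L)
  expect_null(predict_methylation_site(lay, dup2, "D"))
})

test_that("every prediction has exactly four nucleotides between partner and box", {
  set.seed(203)
  for (rep in 1:20) {
    fx <- fixture_gene(position = sample(30:250, 1),
                       element_len = sample(9:20, 1))
    region <- extract_guide_region(fx$layout, "D")
    gseq <- substr(fx$gene$seq, region[1] + 1, region[2])
    hits <- find_duplexes(gseq, region[1], list(fx$target))
    preds <- Filter(Negate(is.null),
                    lapply(hits, function(h)
                      predict_methylation_site(fx$layout, h, "D")))
    expect_true(length(preds) >= 1L)
    for (p in preds) {
      expect_equal(fx$layout$d_box$start - 1L - p$guide_partner_index, 4L)
    }
    expect_true(any(vapply(preds, function(p) p$position, numeric(1)) ==
                      fx$profile$target_position))
  }
})

test_that("homologous candidates from one profile hit the same target site", {
  set.seed(204)
  target <- fixture_target()
  profile <- fixture_profile(target, 150L)
  pos_of <- function(gene) {
    lay <- scan_cd_layouts(gene$seq)[[1]]
    region <- extract_guide_region(lay, "D")
    hits <- find_duplexes(substr(gene$seq, region[1] + 1, region[2]),
                          region[1], list(target))
    preds <- Filter(Negate(is.null),
                    lapply(hits, function(h) predict_methylation_site(lay, h, "D")))
    vapply(preds, function(p) p$position, numeric(1))
  }
  g1 <- make_snorna_gene(profile, target, sim_config())
  g2 <- make_snorna_gene(profile, target, sim_config())
  expect_false(g1$seq == g2$seq)  # different spacers/stems, same element
  expect_true(150 %in% pos_of(g1))
  expect_true(150 %in% pos_of(g2))
})

test_that("validate_claimed_target reproduces the known error classes", {
  set.seed(205)
  fx <- fixture_gene()
  lay <- fx$layout
  region <- extract_guide_region(lay, "D")

  # a 5S rRNA target is disallowed outright
  five_s <- sno_seq("5S_rRNA", random_seq(120))
  v <- validate_claimed_target(lay, region, five_s, NULL)
  expect_true("TARGET_DISALLOWED" %in% v$violations)
  expect_equal(v$verdict, "inconsistent")

  # claiming the whole C-to-D' fragment is not an antisense element
  span <- c(lay$c_box$start + 6L, lay$dprime_box$start)
  v2 <- validate_claimed_target(lay, span, fx$target, NULL)
  expect_true("ELEMENT_IS_INTERBOX_SPAN" %in% v2$violations)
  # ... as is the C'-to-D fragment
  span2 <- c(lay$cprime_box$start + 6L, lay$d_box$start)
  v2b <- validate_claimed_target(lay, span2, fx$target, NULL)
  expect_true("ELEMENT_IS_INTERBOX_SPAN" %in% v2b$violations)

  # the true 12-nt element abutting the D box with the true site is consistent
  elem <- c(lay$d_box$start - 12L, lay$d_box$start)
  v3 <- validate_claimed_target(lay, elem, fx$target,
                                fx$profile$target_position)
  expect_equal(v3$verdict, "consistent")
  expect_length(v3$violations, 0L)

  # a site outside any duplex is unpaired
  far <- if (fx$profile$target_position > 150) 10L else 290L
  v4 <- validate_claimed_target(lay, region, fx$target, far)
  expect_true("SITE_UNPAIRED" %in% v4$violations)

  # an element with no >= 9 nt complementarity to the target
  v5 <- validate_claimed_target(lay, c(lay$c_box$start + 6L,
                                       lay$c_box$start + 18L),
                                sno_seq("other", strrep("A", 100)), NULL)
  expect_true("DUPLEX_TOO_SHORT" %in% v5$violations)

  expect_error(validate_claimed_target(lay, region, fx$target, 9999L),
               "outside target")
})

test_that("a guide partner more than four nucleotides from the box is flagged", {
  set.seed(206)
  # hand-built candidate: C box, a decoy element far from any D box, then
  # the true element abutting the D box; the decoy is poly-T against a
  # poly-A target stretch so no chance internal box can sit next to it
  target_seq <- paste0(random_seq(192), strrep("A", 12), random_seq(96))
  true_el <- oracle_revcomp(substr(target_seq, 93, 104))
  decoy_el <- strrep("T", 12)
  s <- paste0("GGCAGT", "TGATGA", decoy_el, strrep("A", 10), true_el,
              "CTGA", "ACTGCC")
  target <- sno_seq("t28S", target_seq)
  lay <- scan_cd_layouts(s)[[1]]
  # decoy element spans candidate positions [12, 24); its duplex partner for
  # claimed site 197 sits ~26 nt upstream of the D box
  v <- validate_claimed_target(lay, c(12L, 24L), target, 197L)
  expect_true("OFFSET_GT4" %in% v$violations)
  expect_equal(v$verdict, "inconsistent")
})
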