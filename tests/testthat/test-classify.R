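# classify_candidate is exercised against locations built from a small
# two-gene annotation; sequence lesions come from pseudogenize().

classify_setup <- function(seed = 601) {
  set.seed(seed)
  fx <- fixture_gene()
  host <- gene_model("host1", "chr1", "+",
                     data.frame(start = c(100, 600), end = c(200, 700)))
  idx <- build_intron_index(list(host))
  list(fx = fx, idx = idx,
       intronic = locate_candidate(sno_interval("chr1", 300, 362), idx),
       intergenic = locate_candidate(sno_interval("chr1", 900, 962), idx),
       antisense = locate_candidate(sno_interval("chr1", 300, 362, "-"), idx))
}

test_that("an intact intronic candidate is a gene with no reasons", {
  s <- classify_setup()
  res <- classify_candidate(s$fx$gene, s$fx$layout, s$intronic, s$fx$profile,
                            list(s$fx$target))
  expect_equal(res$label, "gene")
  expect_length(res$reasons, 0L)
})

test_that("truncation is labeled pseudogene with the missing end named", {
  s <- classify_setup()
  for (mode in c("truncate5", "truncate3")) {
    ps <- pseudogenize(s$fx$gene, mode)
    layouts <- scan_cd_layouts(ps$record$seq)
    res <- classify_candidate(ps$record,
                              if (length(layouts)) layouts[[1]] else NULL,
                              s$intronic, s$fx$profile, list(s$fx$target))
    expect_equal(res$label, "pseudogene")
    expect_true((if (mode == "truncate5") "TRUNC_5" else "TRUNC_3") %in% res$reasons)
  }
})

test_that("an intact but intergenic candidate without evidence is uncertain", {
  s <- classify_setup()
  res <- classify_candidate(s$fx$gene, s$fx$layout, s$intergenic, s$fx$profile,
                            list(s$fx$target), evidence_overlap = FALSE)
  expect_equal(res$label, "uncertain")
  expect_setequal(res$reasons, c("INTERGENIC", "NO_TRANSCRIPT_EVIDENCE"))
  # transcript evidence upgrades it to gene, with a provenance note
  res2 <- classify_candidate(s$fx$gene, s$fx$layout, s$intergenic, s$fx$profile,
                             list(s$fx$target), evidence_overlap = TRUE)
  expect_equal(res2$label, "gene")
  expect_match(res2$note, "evidence")
})

test_that("box substitutions plus intergenic location give a reason-coded pseudogene", {
  s <- classify_setup()
  ps <- pseudogenize(s$fx$gene, "box_mut", box = "C")
  layouts <- scan_cd_layouts(ps$record$seq)
  res <- classify_candidate(ps$record,
                            if (length(layouts)) layouts[[1]] else NULL,
                            s$intergenic, s$fx$profile, list(s$fx$target))
  expect_equal(res$label, "pseudogene")
  expect_true("BOX_MUT_C" %in% res$reasons)
  expect_true("INTERGENIC" %in% res$reasons)
  ps_d <- pseudogenize(s$fx$gene, "box_mut", box = "D")
  res_d <- classify_candidate(ps_d$record, NULL, s$intronic, s$fx$profile,
                              list(s$fx$target))
  expect_equal(res_d$label, "pseudogene")
  expect_true("BOX_MUT_D" %in% res_d$reasons)
})

test_that("a shuffled antisense element is caught as ASE_DISRUPTED", {
  s <- classify_setup()
  ps <- pseudogenize(s$fx$gene, "shuffle_element", profile = s$fx$profile,
                     target = s$fx$target)
  layouts <- scan_cd_layouts(ps$record$seq)
  res <- classify_candidate(ps$record, layouts[[1]], s$intronic, s$fx$profile,
                            list(s$fx$target))
  expect_equal(res$label, "pseudogene")
  expect_true("ASE_DISRUPTED" %in% res$reasons)
})

test_that("antisense-strand intronic candidates are pseudogenes unless promoter-exempt", {
  s <- classify_setup()
  res <- classify_candidate(s$fx$gene, s$fx$layout, s$antisense, s$fx$profile,
                            list(s$fx$target))
  expect_equal(res$label, "pseudogene")
  expect_true("ANTISENSE_STRAND" %in% res$reasons)
})

test_that("independent-promoter families never collect location reasons", {
  s <- classify_setup()
  prof <- s$fx$profile
  prof$independent_promoter <- TRUE
  for (loc in list(s$intergenic, s$antisense)) {
    res <- classify_candidate(s$fx$gene, s$fx$layout, loc, prof,
                              list(s$fx$target))
    expect_equal(res$label, "gene")
    expect_false(any(c("INTERGENIC", "ANTISENSE_STRAND",
                       "NO_TRANSCRIPT_EVIDENCE") %in% res$reasons))
  }
})

test_that("any disruptive edit removes the gene label (reason monotonicity)", {
  s <- classify_setup(602)
  for (mode in c("box_mut", "truncate5", "truncate3", "shuffle_element")) {
    ps <- pseudogenize(s$fx$gene, mode, profile = s$fx$profile,
                       target = s$fx$target)
    layouts <- scan_cd_layouts(ps$record$seq)
    res <- classify_candidate(ps$record,
                              if (length(layouts)) layouts[[1]] else NULL,
                              s$intronic, s$fx$profile, list(s$fx$target))
    expect_false(res$label == "gene")
    expect_true(length(res$reasons) >= 1L)
  }
  # relocation of an intact copy out of its intron also cannot stay a gene
  res <- classify_candidate(s$fx$gene, s$fx$layout, s$intergenic, s$fx$profile,
                            list(s$fx$target))
  expect_false(res$label == "gene")
})

test_that("classification requires a family assignment", {
  s <- classify_setup()
  expect_error(classify_candidate(s$fx$gene, s$fx$layout, s$intronic,
                                  list(family = ""), list(s$fx$target)),
               "family assignment")
})

test_that("the census counts labels per family", {
  res <- data.frame(
    family = c("F", "F", "F", "F", "G"),
    label = c("gene", "pseudogene", "pseudogene", "pseudogene", "uncertain"),
    stringsAsFactors = FALSE)
  cen <- summarize_census(res, "toy")
  expect_equal(cen$family, c("F", "G"))
  expect_equal(cen$n_genes, c(1L, 0L))
  expect_equal(cen$n_pseudogenes, c(3L, 0L))
  expect_equal(cen$n_uncertain, c(0L, 1L))
  expect_equal(cen$n_genes + cen$n_pseudogenes + cen$n_uncertain,
               as.integer(table(res$family)[cen$family]), ignore_attr = TRUE)
  expect_equal(nrow(summarize_census(res[0, ], "toy")), 0L)
})

test_that("family assignment picks the closest reference", {
  set.seed(603)
  target <- fixture_target()
  cat_rows <- list()
  genes <- list()
  for (i in 1:3) {
    prof <- fixture_profile(target, 50 + 40 * i, family = sprintf("FAM%d", i))
    g <- make_snorna_gene(prof, target, sim_config())
    genes[[i]] <- g
    cat_rows[[i]] <- data.frame(family = prof$family, class = "CD",
                                reference_seq = g$seq,
                                target_rna_id = target$id,
                                target_position = prof$target_position,
                                independent_promoter = FALSE)
  }
  catalog <- do.call(rbind, cat_rows)
  for (i in 1:3) {
    expect_equal(assign_family(genes[[i]], catalog), sprintf("FAM%d", i))
  }
})
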