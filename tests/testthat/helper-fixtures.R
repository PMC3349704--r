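# Shared fixture builders (all seeded by the caller).

fixture_target <- function(len = 300L) {
  sno_seq("toy28S", paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = ""), "synthetic rRNA target")
}

fixture_profile <- function(target, position = 120L, family = "SNORD901",
                            independent_promoter = FALSE) {
  list(family = family, class = "CD", target_rna_id = target$id,
       target_position = position, independent_promoter = independent_promoter)
}

# one generated gene plus its layout and profile
fixture_gene <- function(position = 120L, element_len = 12L) {
  target <- fixture_target()
  profile <- fixture_profile(target, position)
  cfg <- sim_config(element_len = element_len)
  gene <- make_snorna_gene(profile, target, cfg)
  profile$reference_seq <- gene$seq
  layout <- scan_cd_layouts(gene$seq)[[1]]
  list(gene = gene, layout = layout, profile = profile, target = target,
       cfg = cfg)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a bare layout object for unit tests that only need box positions
bare_layout <- function(seq, c_start = NULL, d_start = NULL,
                        dprime_start = NULL, cprime_start = NULL) {
  mk <- function(name, start) if (is.null(start)) NULL else
    list(box = name, start = start, mismatches = 0L)
  structure(list(seq = seq,
                 c_box = mk("C", c_start), d_box = mk("D", d_start),
                 dprime_box = mk("Dprime", dprime_start),
                 cprime_box = mk("Cprime", cprime_start), stem = NULL),
            class = "cd_layout")
}
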