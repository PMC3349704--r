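# Seeded generator of snoRNA genes, pseudogenes, host genes, toy genomes,
# target RNAs and truth tables. Every other module is testable against
# these fixtures without downloads, and the generator doubles as a
# self-oracle: at noise-free settings the end-to-end pipeline must
# reproduce the truth table exactly.

PSEUDO_MODES <- c("box_mut", "truncate5", "truncate3", "shuffle_element",
                  "intergenic_retro")

#' Simulation configuration
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_host_genes,introns_per_gene Host-gene layout counts.
#' @param exon_len,intron_len,intergenic_len Segment sizes (nt).
#' @param n_gene_copies Intact gene copies implanted per family.
#' @param pseudo_modes Pseudogene modes applied (one copy each) per family;
#'   subset of `box_mut`, `truncate5`, `truncate3`, `shuffle_element`,
#'   `intergenic_retro`.
#' @param element_len Antisense element length, in `[9, 20]`.
#' @param target_len Target RNA length (nt).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_host_genes = 3L, introns_per_gene = 4L,
                       exon_len = 120L, intron_len = 400L,
                       intergenic_len = 600L, n_gene_copies = 1L,
                       pseudo_modes = PSEUDO_MODES[c(1, 2, 4, 5)],
                       element_len = 12L, target_len = 300L) {
  if (element_len < 9L || element_len > 20L) {
    sno_stop("element_len must be in [9, 20]")
  }
  bad <- setdiff(pseudo_modes, PSEUDO_MODES)
  if (length(bad)) sno_stop("unknown pseudo mode(s): ", paste(bad, collapse = ", "))
  if (n_host_genes < 0L || introns_per_gene < 0L || n_gene_copies < 0L) {
    sno_stop("counts must be >= 0")
  }
  structure(list(seed = as.integer(seed), n_host_genes = as.integer(n_host_genes),
                 introns_per_gene = as.integer(introns_per_gene),
                 exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
                 intergenic_len = as.integer(intergenic_len),
                 n_gene_copies = as.integer(n_gene_copies),
                 pseudo_modes = pseudo_modes,
                 element_len = as.integer(element_len),
                 target_len = as.integer(target_len)),
            class = "sim_config")
}

#' Generate a snoRNA gene sequence for a family profile
#'
#' Assembles 5' stem arm + C box + spacer + D' box + spacer + C' box +
#' antisense element + D box + 3' stem arm (the reverse complement of the
#' 5' arm). The element is the reverse complement of the target window
#' placed so that the four-nucleotide rule points exactly at
#' `profile$target_position`. Random spacers are rejection-sampled until
#' the sequence yields exactly one C/D layout with a stem whose predicted
#' site equals the profile position. Consumes the caller's RNG stream, so
#' results are reproducible under `set.seed()`.
#'
#' @param profile Catalog row (needs `family`, `target_rna_id`,
#'   `target_position`).
#' @param target [sno_seq] target RNA containing the profile position.
#' @param cfg [sim_config()].
#' @param params [sno_params()].
#' @return A [sno_seq] snoRNA gene sequence.
#' @export
make_snorna_gene <- function(profile, target, cfg = sim_config(),
                             params = sno_params()) {
  if (is.na(profile$target_position) || is.null(profile$target_position)) {
    sno_stop("profile must define a target position")
  }
  el <- cfg$element_len
  p0 <- profile$target_position - 1L
  t0 <- p0 - 4L
  if (t0 < 0L || t0 + el > nchar(target$seq)) {
    sno_stop("target window for position ", profile$target_position,
             " (element ", el, " nt) out of range in '", target$id, "'")
  }
  element <- revcomp(substr(target$seq, t0 + 1L, t0 + el))
  for (try in 1:200) {
    stem5 <- random_dna(6L)
    spacer1 <- random_dna(8L)
    spacer2 <- random_dna(6L)
    spacer3 <- random_dna(4L)
    seq <- paste0(stem5, "TGATGA", spacer1, "CTGA", spacer2, "TGATGA",
                  spacer3, element, "CTGA", revcomp(stem5))
    layouts <- scan_cd_layouts(seq, params)
    if (length(layouts) != 1L) next
    lay <- layouts[[1]]
    if (is.null(lay$stem) || is.null(lay$dprime_box) || is.null(lay$cprime_box)) next
    region <- extract_guide_region(lay, "D", params)
    ok <- FALSE
    for (dx in find_duplexes(substr(seq, region[1] + 1L, region[2]),
                             region[1], list(target), params)) {
      pred <- predict_methylation_site(lay, dx, "D", params)
      if (!is.null(pred) && pred$position == profile$target_position) ok <- TRUE
    }
    if (ok) {
      return(sno_seq(paste0(profile$family, "_ref"), seq,
                     paste0("synthetic ", profile$family)))
    }
  }
  sno_stop("could not assemble a valid snoRNA gene for ", profile$family)
}

#' Derive a pseudogene copy from a gene sequence
#'
#' Modes: `box_mut` substitutes bases in the C or D box beyond the
#' classifier tolerance; `truncate5`/`truncate3` removes 40% of the
#' sequence from the respective end (well past the full-length fraction);
#' `shuffle_element` permutes the antisense element until the target site
#' is no longer recoverable; `intergenic_retro` leaves the sequence intact
#' (its pseudogenicity comes from placement, handled by
#' [build_toy_genome()]). Consumes the caller's RNG stream.
#'
#' @param gene [sno_seq] gene sequence (as from [make_snorna_gene()]).
#' @param mode One of the modes above.
#' @param profile,target Family profile row and its target RNA (needed for
#'   `shuffle_element` verification).
#' @param box For `box_mut`: `"C"` or `"D"` (default `"D"`).
#' @param params [sno_params()].
#' @return List with `record` ([sno_seq]), `truth_label`
#'   (`pseudogene`/`uncertain`) and `applied_mode`.
#' @export
pseudogenize <- function(gene, mode, profile = NULL, target = NULL,
                         box = "D", params = sno_params()) {
  if (!mode %in% PSEUDO_MODES) sno_stop("unknown pseudogene mode '", mode, "'")
  seq <- gene$seq
  n <- nchar(seq)
  label <- "pseudogene"
  if (mode == "box_mut") {
    layouts <- scan_cd_layouts(seq, params)
    if (!length(layouts)) sno_stop("input is not a scannable gene")
    lay <- layouts[[1]]
    tol <- if (box == "C") params$boxes.c_max_mismatch else params$boxes.d_max_mismatch
    start <- if (box == "C") lay$c_box$start else lay$d_box$start
    blen <- nchar(BOX_PATTERNS[[box]])
    for (try in 1:100) {
      pos <- sample(seq_len(blen), tol + 1L)
      chars <- seq_chars(seq)
      for (p in pos) {
        old <- chars[start + p]
        chars[start + p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      mutated <- paste(chars, collapse = "")
      if (!length(scan_cd_layouts(mutated, params))) { seq <- mutated; break }
    }
  } else if (mode == "truncate5") {
    seq <- substr(seq, floor(0.4 * n) + 1L, n)
  } else if (mode == "truncate3") {
    seq <- substr(seq, 1L, n - floor(0.4 * n))
  } else if (mode == "shuffle_element") {
    if (is.null(profile) || is.null(target)) {
      sno_stop("shuffle_element needs the family profile and target")
    }
    layouts <- scan_cd_layouts(seq, params)
    if (!length(layouts)) sno_stop("input is not a scannable gene")
    lay <- layouts[[1]]
    region <- extract_guide_region(lay, "D", params)
    for (try in 1:100) {
      chars <- seq_chars(seq)
      el_idx <- (region[1] + 1L):region[2]
      chars[el_idx] <- sample(chars[el_idx])
      shuffled <- paste(chars, collapse = "")
      lay2 <- scan_cd_layouts(shuffled, params)
      if (length(lay2) != 1L) next
      if (!.ase_reproducible(lay2[[1]], target, profile$target_position, params)) {
        seq <- shuffled; break
      }
    }
  } else if (mode == "intergenic_retro") {
    label <- "uncertain"
  }
  list(record = sno_seq(paste0(gene$id, "_", mode), seq),
       truth_label = label,
       applied_mode = mode)
}

#' Build a seeded toy genome with implanted copies and a truth table
#'
#' Lays out `n_host_genes` plus-strand host genes (alternating exons and
#' introns) separated by intergenic gaps on a uniform-ACGT background, and
#' implants, for every catalog family, `n_gene_copies` intact copies into
#' introns (sense strand) plus one pseudogene copy per configured mode —
#' intronically for the sequence-level modes, intergenically for
#' `intergenic_retro`. Implants sit at least 50 nt from any intron or gene
#' boundary. Fully reproducible from `cfg$seed`.
#'
#' @param catalog Family catalog data.frame (see [read_family_catalog()];
#'   [sim_family_catalog()] builds one).
#' @param targets List of [sno_seq] target RNAs referenced by the catalog.
#' @param cfg [sim_config()].
#' @param out_dir Optional directory; when given, `genome.fa`,
#'   `genes.gff3`, `truth.tsv`, `targets.fa` and `catalog.tsv` are written
#'   there.
#' @param params [sno_params()].
#' @return List with `genome` (list of [sno_seq]), `genes` (list of
#'   [gene_model]), `truth` (data.frame: `copy_id`, `family`, `contig`,
#'   `start`, `end`, `strand`, `truth_label`, `applied_mode`), `catalog`,
#'   `targets`.
#' @export
build_toy_genome <- function(catalog, targets, cfg = sim_config(),
                             out_dir = NULL, params = sno_params()) {
  if (!nrow(catalog)) sno_stop("catalog must be non-empty")
  set.seed(cfg$seed)

  # copies to implant
  implants <- list()
  for (i in seq_len(nrow(catalog))) {
    profile <- as.list(catalog[i, ])
    target <- find_record(targets, profile$target_rna_id)
    if (is.null(target)) sno_stop("target '", profile$target_rna_id, "' missing")
    ref <- sno_seq(paste0(profile$family, "_ref"), profile$reference_seq)
    for (k in seq_len(cfg$n_gene_copies)) {
      implants[[length(implants) + 1L]] <- list(
        copy_id = sprintf("%s_gene_%d", profile$family, k),
        family = profile$family, seq = ref$seq,
        truth_label = "gene", applied_mode = NA_character_,
        where = "intron")
    }
    for (mode in cfg$pseudo_modes) {
      ps <- pseudogenize(ref, mode, profile = profile, target = target,
                         params = params)
      implants[[length(implants) + 1L]] <- list(
        copy_id = sprintf("%s_%s", profile$family, mode),
        family = profile$family, seq = ps$record$seq,
        truth_label = ps$truth_label, applied_mode = mode,
        where = if (mode == "intergenic_retro") "intergenic" else "intron")
    }
  }
  n_intronic <- sum(vapply(implants, function(x) x$where == "intron", logical(1)))
  n_intergenic <- length(implants) - n_intronic
  slots_intron <- cfg$n_host_genes * cfg$introns_per_gene
  slots_inter <- cfg$n_host_genes + 1L
  if (n_intronic > slots_intron || n_intergenic > slots_inter) {
    sno_stop("genome too small to place all copies: need ", n_intronic,
             " intron slots (have ", slots_intron, ") and ", n_intergenic,
             " intergenic slots (have ", slots_inter, ")")
  }
  max_copy <- max(c(0L, vapply(implants, function(x) nchar(x$seq), integer(1))))
  if (cfg$intron_len < max_copy + 100L || cfg$intergenic_len < max_copy + 100L) {
    sno_stop("introns/intergenic gaps too short for the copies plus 50 nt margins")
  }

  # genome layout: gap, then per gene exon (intron exon)*, then gap ...
  pieces <- character(0)
  genes <- list()
  intron_spans <- list()   # (start,end) per intron slot, genomic
  gap_spans <- list()
  pos <- 0L
  add_piece <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  for (g in seq_len(cfg$n_host_genes + 1L)) {
    gap_spans[[g]] <- c(pos, pos + cfg$intergenic_len)
    add_piece(random_dna(cfg$intergenic_len))
    if (g > cfg$n_host_genes) break
    exons <- data.frame(start = integer(0), end = integer(0))
    for (e in seq_len(cfg$introns_per_gene + 1L)) {
      exons <- rbind(exons, data.frame(start = pos, end = pos + cfg$exon_len))
      add_piece(random_dna(cfg$exon_len))
      if (e <= cfg$introns_per_gene) {
        intron_spans[[length(intron_spans) + 1L]] <- c(pos, pos + cfg$intron_len)
        add_piece(random_dna(cfg$intron_len))
      }
    }
    genes[[g]] <- gene_model(sprintf("host%d", g), "toychr1", "+", exons)
  }
  genome_seq <- paste(pieces, collapse = "")

  # implant copies by substring replacement (segment lengths preserved)
  truth <- list()
  i_intron <- 0L
  i_gap <- 0L
  for (im in implants) {
    if (im$where == "intron") {
      i_intron <- i_intron + 1L
      span <- intron_spans[[i_intron]]
    } else {
      i_gap <- i_gap + 1L
      span <- gap_spans[[i_gap]]
    }
    width <- span[2] - span[1]
    offset <- 50L + sample.int(width - nchar(im$seq) - 100L + 1L, 1L) - 1L
    at <- span[1] + offset
    genome_seq <- paste0(substr(genome_seq, 1L, at), im$seq,
                         substr(genome_seq, at + nchar(im$seq) + 1L, nchar(genome_seq)))
    truth[[length(truth) + 1L]] <- data.frame(
      copy_id = im$copy_id, family = im$family, contig = "toychr1",
      start = at, end = at + nchar(im$seq), strand = "+",
      truth_label = im$truth_label, applied_mode = im$applied_mode,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  out <- list(genome = list(sno_seq("toychr1", genome_seq)),
              genes = genes, truth = truth,
              catalog = catalog, targets = targets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$genome, file.path(out_dir, "genome.fa"))
    write_gff3(out$genes, file.path(out_dir, "genes.gff3"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(targets, file.path(out_dir, "targets.fa"))
    write_family_catalog(catalog, file.path(out_dir, "catalog.tsv"))
  }
  out
}

#' Build a synthetic family catalog with target RNAs
#'
#' Convenience wrapper: draws one random target RNA, picks `n` distinct
#' target positions, and generates one reference gene per family with
#' [make_snorna_gene()]. Consumes the caller's RNG stream.
#'
#' @param n Number of families.
#' @param cfg [sim_config()].
#' @param params [sno_params()].
#' @return List with `catalog` (data.frame) and `targets` (list of
#'   [sno_seq]).
#' @export
sim_family_catalog <- function(n = 3L, cfg = sim_config(), params = sno_params()) {
  target <- sno_seq("toy28S", random_dna(cfg$target_len), "synthetic rRNA target")
  lo <- 5L + cfg$element_len
  positions <- sort(sample(lo:(cfg$target_len - cfg$element_len - 5L), n))
  rows <- list()
  for (i in seq_len(n)) {
    profile <- list(family = sprintf("SNORD9%02d", i), class = "CD",
                    target_rna_id = target$id, target_position = positions[i],
                    independent_promoter = FALSE)
    ref <- make_snorna_gene(profile, target, cfg, params)
    rows[[i]] <- data.frame(family = profile$family, class = "CD",
                            reference_seq = ref$seq,
                            target_rna_id = target$id,
                            target_position = positions[i],
                            independent_promoter = FALSE,
                            stringsAsFactors = FALSE)
  }
  list(catalog = do.call(rbind, rows), targets = list(target))
}
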