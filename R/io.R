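# Readers and writers: FASTA, GFF3/BED12 gene models, family catalog and
# claimed-target TSVs, result reports. GFF3 is 1-based inclusive on disk and
# 0-based half-open in memory; conversion happens here and nowhere else.

#' Read a multi-record FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; records are then
#' normalized to the DNA alphabet (uppercase, U to T) and validated. Record
#' ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A list of [sno_seq] records, in file order. An empty file yields
#'   an empty list.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) sno_stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) sno_stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    ln <- .fasta_header_line(path, which(!nzchar(ids))[1])
    sno_stop("malformed FASTA header (empty id) at line ", ln, " of ", path)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    sno_stop("duplicate sequence id '", dup, "' in ", path)
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- normalize_seq(as.character(set[[i]]))
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    if (length(bad) && nchar(bad)) {
      ln <- .fasta_bad_char_line(path, bad)
      sno_stop("illegal character '", bad, "' in record '", ids[i],
               "' (line ", ln, ") of ", path)
    }
    out[[i]] <- sno_seq(ids[i], s, descs[i])
  }
  out
}

# locate the n-th header line (for error messages)
.fasta_header_line <- function(path, n) {
  which(startsWith(readLines(path, warn = FALSE), ">"))[n]
}

# locate the first line containing an offending character
.fasta_bad_char_line <- function(path, ch) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, ">")
  hit <- body & grepl(ch, toupper(chartr("U", "T", lines)), fixed = TRUE)
  if (any(hit)) which(hit)[1] else NA_integer_
}

#' Write sequence records to FASTA
#'
#' @param records List of [sno_seq] records.
#' @param path Output path.
#' @param rna If `TRUE`, write the RNA lettering (T as U).
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, rna = FALSE, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    s <- if (rna) as_rna(r) else r$seq
    writeLines(paste0(">", header), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with 0-based half-open `start`, `end` columns;
#'   exons must be non-overlapping. Stored sorted by ascending genomic start
#'   regardless of strand.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons) {
  if (!nzchar(gene_id)) sno_stop("gene_id must be non-empty")
  if (!strand %in% c("+", "-")) sno_stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) < 1L) sno_stop("gene '", gene_id, "' has no exons")
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start) || any(exons$start < 0L)) {
    sno_stop("gene '", gene_id, "' has an invalid exon interval")
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    sno_stop("gene '", gene_id, "' has overlapping exons")
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 files must carry `gene`, `mRNA`/`transcript` and `exon` features
#' linked by `Parent` attributes (exons parented directly on a gene are also
#' accepted). Multi-transcript genes collapse to the transcript with the
#' greatest summed exon length (ties broken by lexicographically smallest
#' transcript id). BED12 rows are taken as one gene each, blocks as exons.
#' Coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A list of [gene_model] objects.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) sno_stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") .read_bed12_models(path) else .read_gff3_models(path)
}

.read_gff3_models <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) sno_stop("malformed GFF3 '", path, "': ", conditionMessage(e))
  )
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  gene_ids <- ids[is_gene]
  tx2gene <- setNames(parents[is_tx], ids[is_tx])

  # resolve each exon to a (gene, transcript) pair
  ex_parent <- parents[is_exon]
  ex_start0 <- BiocGenerics::start(gr)[is_exon] - 1L
  ex_end <- BiocGenerics::end(gr)[is_exon]
  ex_gene <- character(length(ex_parent))
  ex_tx <- character(length(ex_parent))
  keep <- logical(length(ex_parent))
  for (i in seq_along(ex_parent)) {
    p <- ex_parent[i]
    if (!is.na(p) && p %in% names(tx2gene)) {
      ex_tx[i] <- p; ex_gene[i] <- tx2gene[[p]]; keep[i] <- TRUE
    } else if (!is.na(p) && p %in% gene_ids) {
      ex_tx[i] <- paste0(p, ".direct"); ex_gene[i] <- p; keep[i] <- TRUE
    } else {
      warning("exon without resolvable gene parent skipped (Parent=",
              ifelse(is.na(p), "<none>", p), ")", call. = FALSE)
    }
  }

  models <- list()
  for (g in gene_ids) {
    sel <- keep & ex_gene == g
    if (!any(sel)) next
    txs <- unique(ex_tx[sel])
    lens <- vapply(txs, function(t) sum(ex_end[sel & ex_tx == t] -
                                          ex_start0[sel & ex_tx == t]), numeric(1))
    best <- txs[order(-lens, txs)][1]
    sel2 <- sel & ex_tx == best
    gidx <- which(is_gene & ids == g)[1]
    models[[g]] <- gene_model(
      gene_id = g,
      contig = as.character(GenomicRanges::seqnames(gr))[gidx],
      strand = as.character(BiocGenerics::strand(gr))[gidx],
      exons = data.frame(start = ex_start0[sel2], end = ex_end[sel2])
    )
  }
  unname(models)
}

.read_bed12_models <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) sno_stop("malformed BED '", path, "': ", conditionMessage(e))
  )
  models <- vector("list", length(gr))
  has_blocks <- "blocks" %in% names(S4Vectors::mcols(gr))
  for (i in seq_along(gr)) {
    g0 <- BiocGenerics::start(gr)[i] - 1L
    if (has_blocks && length(gr$blocks[[i]])) {
      b <- gr$blocks[[i]]  # 1-based, relative to the range start
      exons <- data.frame(start = g0 + BiocGenerics::start(b) - 1L,
                          end = g0 + BiocGenerics::end(b))
    } else {
      exons <- data.frame(start = g0, end = BiocGenerics::end(gr)[i])
    }
    nm <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name[i] else paste0("bed_", i)
    st <- as.character(BiocGenerics::strand(gr))[i]
    models[[i]] <- gene_model(nm, as.character(GenomicRanges::seqnames(gr))[i],
                              if (st %in% c("+", "-")) st else "+", exons)
  }
  models
}

#' Write gene models as GFF3
#'
#' Emits a three-level gene/mRNA/exon hierarchy per model; internal 0-based
#' half-open coordinates are converted back to 1-based inclusive.
#'
#' @param models List of [gene_model] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- c(min(m$exons$start), max(m$exons$end))
    tx <- paste0(m$gene_id, ".t1")
    writeLines(sprintf("%s\tsnoverify\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$contig, span[1] + 1L, span[2], m$strand, m$gene_id), con)
    writeLines(sprintf("%s\tsnoverify\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       m$contig, span[1] + 1L, span[2], m$strand, tx, m$gene_id), con)
    for (i in seq_len(nrow(m$exons))) {
      writeLines(sprintf("%s\tsnoverify\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         m$contig, m$exons$start[i] + 1L, m$exons$end[i],
                         m$strand, tx, i, tx), con)
    }
  }
  invisible(path)
}

#' Read a family catalog TSV
#'
#' Columns: `family`, `class` (CD / HACA / scaRNA), `reference_seq`,
#' `target_rna_id`, `target_position` (1-based in the target RNA, empty if
#' unknown), `independent_promoter` (true/false). A set `target_position`
#' requires a set `target_rna_id`.
#'
#' @param path Path to the TSV.
#' @return data.frame with one row per family profile.
#' @export
read_family_catalog <- function(path) {
  if (!file.exists(path)) sno_stop("catalog file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("family", "class", "reference_seq", "target_rna_id",
            "target_position", "independent_promoter")
  miss <- setdiff(need, names(df))
  if (length(miss)) sno_stop("catalog missing column(s): ", paste(miss, collapse = ", "))
  df$reference_seq <- vapply(df$reference_seq, normalize_seq, character(1))
  df$target_rna_id[!nzchar(df$target_rna_id)] <- NA_character_
  df$target_position <- suppressWarnings(as.integer(df$target_position))
  df$independent_promoter <- toupper(df$independent_promoter) %in% c("TRUE", "T", "YES", "1")
  bad <- !is.na(df$target_position) & is.na(df$target_rna_id)
  if (any(bad)) {
    sno_stop("catalog family '", df$family[which(bad)[1]],
             "' has target_position without target_rna_id")
  }
  if (!all(df$class %in% c("CD", "HACA", "scaRNA"))) {
    sno_stop("catalog class must be one of CD, HACA, scaRNA")
  }
  df
}

#' Write a family catalog TSV
#' @param catalog data.frame as returned by [read_family_catalog()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_family_catalog <- function(catalog, path) {
  out <- catalog
  out$independent_promoter <- ifelse(out$independent_promoter, "true", "false")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a claimed-target TSV
#'
#' Columns: `candidate_id`, `element_start`, `element_end` (1-based
#' inclusive within the candidate sequence; converted to 0-based half-open),
#' `target_id`, and optional `claimed_site` (1-based in the target RNA).
#'
#' @param path Path to the TSV.
#' @return data.frame with 0-based half-open `element_start`, `element_end`.
#' @export
read_claimed_targets <- function(path) {
  if (!file.exists(path)) sno_stop("claimed-target file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("candidate_id", "element_start", "element_end", "target_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) sno_stop("claimed-target table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (!"claimed_site" %in% names(df)) df$claimed_site <- NA_integer_
  df$claimed_site <- suppressWarnings(as.integer(df$claimed_site))
  df$element_start <- as.integer(df$element_start) - 1L  # to 0-based
  df$element_end <- as.integer(df$element_end)           # inclusive -> exclusive
  if (any(df$element_start < 0L | df$element_end <= df$element_start)) {
    sno_stop("claimed element interval invalid (expect 1-based inclusive bounds)")
  }
  df
}

# flatten list-columns (reason vectors etc.) for tabular output
.flatten_report <- function(records) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ";"), character(1))
    }
  }
  df
}

#' Write a result report
#'
#' TSV output flattens list columns (e.g. reason codes) with `;`; JSON
#' output preserves them and round-trips losslessly through
#' [read_report_json()]. Column order is the input order (deterministic).
#'
#' @param records A data.frame (possibly with list columns).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (format == "tsv") {
    ok <- tryCatch({
      write.table(.flatten_report(df), path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) sno_stop("cannot write report to '", path, "'")
  } else {
    ok <- tryCatch({
      jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) sno_stop("cannot write report to '", path, "'")
  }
  invisible(path)
}

#' Read back a JSON report
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return data.frame.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
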