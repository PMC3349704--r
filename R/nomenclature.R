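# Uniform species-prefixed names for homologs of human snoRNAs: the human
# gene name (SNORD/SNORA/SCARNA scheme) prefixed with a short lowercase
# species code, e.g. mmusSNORD87 for the mouse homolog of human SNORD87.

.parse_species <- function(name) {
  if (is.list(name) && !is.null(name$genus)) {
    genus <- name$genus; epithet <- name$epithet
  } else {
    parts <- strsplit(trimws(name), "\\s+")[[1]]
    if (length(parts) != 2L) {
      sno_stop("species must be 'Genus epithet' (got '", name, "')")
    }
    genus <- parts[1]; epithet <- parts[2]
  }
  if (!grepl("^[A-Za-z]+$", genus) || !grepl("^[A-Za-z]+$", epithet)) {
    sno_stop("genus and epithet must be alphabetic")
  }
  list(genus = tolower(genus), epithet = tolower(epithet))
}

#' Species prefix for snoRNA homolog names
#'
#' The prefix is the first letter of the genus plus the first three letters
#' of the species epithet, lowercase (Mus musculus -> `mmus`, Microcebus
#' murinus -> `mmur`). On collision with a reserved prefix, successive
#' epithet letters are appended (5-letter, 6-letter, ...) until unique;
#' once the epithet is exhausted, genus letters (from the second) are
#' appended. Epithets shorter than three letters are padded with genus
#' letters, with a warning. The caller is responsible for adding the
#' returned prefix to its reserved set.
#'
#' @param name Species as `"Genus epithet"` or `list(genus=, epithet=)`.
#' @param reserved Character vector of already-assigned prefixes.
#' @return The prefix string (length 4 when no collision occurs).
#' @examples
#' species_prefix("Mus musculus")                       # "mmus"
#' species_prefix("Microcebus murinus", reserved = "mmus")  # "mmur"
#' @export
species_prefix <- function(name, reserved = character(0)) {
  sp <- .parse_species(name)
  g <- seq_chars(sp$genus)
  e <- seq_chars(sp$epithet)
  if (length(e) < 3L) {
    warning("species epithet '", sp$epithet, "' shorter than 3 letters; ",
            "padding the prefix from the genus", call. = FALSE)
    pad <- g[-1][seq_len(3L - length(e))]
    e <- c(e, pad)
  }
  k <- 3L
  repeat {
    prefix <- paste0(g[1], paste(e[seq_len(min(k, length(e)))], collapse = ""))
    if (k > length(e)) {
      extra <- k - length(e)
      pool <- g[-1]
      if (extra > length(pool)) {
        sno_stop("cannot derive a unique prefix for ", sp$genus, " ", sp$epithet)
      }
      prefix <- paste0(prefix, paste(pool[seq_len(extra)], collapse = ""))
    }
    if (!prefix %in% reserved) return(prefix)
    k <- k + 1L
  }
}

#' Species-prefixed name for a homolog of a human snoRNA
#'
#' @param name Species as `"Genus epithet"` or `list(genus=, epithet=)`.
#' @param human_gene Human snoRNA gene name (SNORD/SNORA/SCARNA scheme);
#'   other names are accepted with a warning.
#' @param reserved Reserved prefixes passed to [species_prefix()].
#' @return The concatenated name, e.g. `"mmusSNORD87"`.
#' @examples
#' homolog_name("Mus musculus", "SNORD87")  # "mmusSNORD87"
#' @export
homolog_name <- function(name, human_gene, reserved = character(0)) {
  if (!is.character(human_gene) || length(human_gene) != 1L || !nzchar(human_gene)) {
    sno_stop("human gene name must be a non-empty string")
  }
  if (!grepl("^(SNORD|SNORA|SCARNA)", human_gene)) {
    warning("'", human_gene, "' does not follow the SNORD/SNORA/SCARNA ",
            "naming scheme", call. = FALSE)
  }
  paste0(species_prefix(name, reserved), human_gene)
}
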