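#' Read an aligned allotype panel from FASTA
#'
#' Headers are taken as allele names (first whitespace-delimited token);
#' the locus is inferred from the text before `*` when recognizable.
#' Sequences must be pre-aligned to a common length; gaps are mapped to `*`.
#'
#' @param path FASTA file of aligned amino-acid sequences.
#' @return an [allele_panel()].
#' @export
read_allele_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- sub("\\s.*$", "", names(aa))
  allele_panel(nm, as.character(aa))
}

#' Write a panel to FASTA
#' @param panel an [allele_panel()].
#' @param path output file.
#' @export
write_allele_fasta <- function(panel, path) {
  aa <- Biostrings::AAStringSet(gsub("\\*", "-", panel$sequence))
  names(aa) <- panel$name
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read an aligned panel from TSV
#'
#' Expects columns `allele` (or `name`) and `sequence`; an optional `locus`
#' column overrides locus inference.
#'
#' @param path TSV file.
#' @return an [allele_panel()].
#' @export
read_allele_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm_col <- intersect(c("allele", "name"), names(d))[1]
  if (is.na(nm_col) || !"sequence" %in% names(d))
    stopf("expected columns allele/name and sequence in %s", path)
  allele_panel(d[[nm_col]], d$sequence,
               locus = if ("locus" %in% names(d)) d$locus else NULL)
}

#' Write an encoded panel as TSV
#'
#' One row per allotype, one column per (position, residue) feature, with
#' feature labels (`R1`-style) as header.
#'
#' @param enc an [one_hot_encode()] result.
#' @param path output file.
#' @export
write_encoded_tsv <- function(enc, path) {
  d <- data.frame(allele = enc$allele_names, enc$matrix,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide binding matrix
#'
#' Rows are KIR allotypes (first column holds their names), remaining
#' columns are HLA allotypes.
#'
#' @param path TSV/CSV file.
#' @param sep field separator (default tab).
#' @param stage stage label for the resulting [binding_matrix()].
#' @return a [binding_matrix()].
#' @export
read_binding_matrix <- function(path, sep = "\t", stage = "raw") {
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  binding_matrix(m, stage = stage)
}

#' Write a binding matrix
#' @param m a [binding_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_binding_matrix <- function(m, path, sep = "\t") {
  d <- data.frame(kir = rownames(m$values), m$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read replicate binding runs in long format
#'
#' Expects columns `kir`, `hla`, `run`, `value`; returns one matrix per run
#' with congruent axes (pairs absent from a run become `NA`).
#'
#' @param path TSV file.
#' @return list of kir x hla matrices.
#' @export
read_binding_runs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("kir", "hla", "run", "value")
  if (!all(need %in% names(d)))
    stopf("expected columns %s in %s", paste(need, collapse = ", "), path)
  kir <- unique(d$kir); hla <- unique(d$hla)
  lapply(split(d, d$run), function(r) {
    m <- matrix(NA_real_, length(kir), length(hla),
                dimnames = list(kir, hla))
    m[cbind(match(r$kir, kir), match(r$hla, hla))] <- r$value
    m
  })
}

#' Read allele-frequency tables
#'
#' Expects columns `population`, `locus`, `allele`, `frequency`; returns one
#' `frequency_table` per (population, locus).
#'
#' @param path TSV file.
#' @return list of [frequency_table()] objects named `population.locus`.
#' @export
read_frequency_tables <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "locus", "allele", "frequency")
  if (!all(need %in% names(d)))
    stopf("expected columns %s in %s", paste(need, collapse = ", "), path)
  lapply(split(d, list(d$population, d$locus), drop = TRUE), function(g)
    frequency_table(stats::setNames(g$frequency, g$allele),
                    population = g$population[1], locus = g$locus[1]))
}
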