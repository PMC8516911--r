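#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Write sequences to FASTA
#' @param genome named character vector / DNAStringSet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read / write 6-column BED
#'
#' BED is 0-based half-open, matching the package's internal convention.
#'
#' @param path file path.
#' @return tibble with `contig`, `start`, `end`, `name`, `score`, `strand`
#'   (missing columns filled with defaults).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("contig", "start", "end", "name", "score", "strand")[
      seq_len(min(6, ncol(df)))]
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "+"
  as_tibble(df)
}

#' @param df tibble with at least `contig`, `start`, `end`; `name`, `score`
#'   and `strand` are taken from matching columns when present.
#' @param name_col column used for the BED name field.
#' @rdname read_bed
#' @export
write_bed <- function(df, path, name_col = NULL) {
  nm <- if (!is.null(name_col) && name_col %in% names(df)) {
    df[[name_col]]
  } else if ("name" %in% names(df)) df$name
    else if ("family" %in% names(df)) df$family
    else rep(".", nrow(df))
  score <- if ("score" %in% names(df)) df$score
    else if ("n_low" %in% names(df)) df$n_low else rep(0L, nrow(df))
  strand <- if ("strand" %in% names(df)) df$strand else rep("+", nrow(df))
  out <- data.frame(df$contig, df$start, df$end, nm, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refGene-like gene table
#'
#' Expects a tab-separated file with a header naming at least `name`,
#' `contig`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#' `exon_starts`, `exon_ends` (exon columns comma-separated, 0-based
#' half-open as in UCSC tables).
#'
#' @param path file path.
#' @return tibble ready for [build_region_models()].
#' @export
read_gene_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, package version and seed next to a
#' subcommand's outputs so any run can be reproduced.
#'
#' @param path output JSON path.
#' @param subcommand name of the pipeline step.
#' @param inputs,outputs named lists of file paths.
#' @param params named list of parameters (coerced to simple values).
#' @param seed integer seed or `NA`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, inputs = list(),
                           outputs = list(), params = list(), seed = NA) {
  manifest <- list(
    tool = "quadmine",
    version = as.character(utils::packageVersion("quadmine")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    params = params,
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
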