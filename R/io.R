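# Plain-text readers/writers for the pipeline's tabular and sequence formats.

#' Read a FASTA file as a named character vector
#'
#' Headers are parsed up to the first whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_vector <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  toupper(out)
}

#' Write named sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_vector <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Read a tab-separated table as a tibble
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE))
}

#' Write a tibble as a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
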