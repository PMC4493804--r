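#' Read sequence reads from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a tibble of reads, in file order,
#' with sequences uppercased. This is the entry point for LTR-junction
#' sequencing reads, reference genomes and vector sequences alike.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `read_id` (the first whitespace-delimited
#'   token of each header) and `sequence` (uppercase nucleotides).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt", ">r2", "GGGTTT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- which(nchar(ids) == 0L | nchar(seqs) == 0L)
  if (length(bad)) {
    abort(sprintf("FASTA record %d in %s has an empty header or sequence",
                  bad[1], path))
  }
  tibble(read_id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param reads A data frame with columns `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  set <- Biostrings::BStringSet(reads$sequence)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
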