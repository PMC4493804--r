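#' Read alignments in 12-column BLAST tabular ("blast8") format
#'
#' blast8 is the tab-separated interchange format the pipeline uses for
#' alignments (the output dialect of `blat -out=blast8` and
#' `blastn -outfmt 6`): query id, target id, percent identity, alignment
#' length, mismatches, gap openings, query start/end, target start/end,
#' e-value, score. Coordinates are 1-based inclusive; a target start greater
#' than the target end encodes a minus-strand alignment and is preserved,
#' not normalised.
#'
#' @param path Path to a blast8 file.
#' @return A tibble with the twelve columns `query_id`, `target_id`,
#'   `percent_identity`, `aln_length`, `mismatches`, `gap_openings`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `e_value`, `score`.
#' @export
read_blast8 <- function(path) {
  if (!file.exists(path)) abort(sprintf("blast8 file not found: %s", path))
  lines <- readr::read_lines(path)
  lines_keep <- which(nzchar(lines))
  if (!length(lines_keep)) return(empty_alignments())
  fields <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- lines_keep[which(nf != 12L)[1]]
    abort(sprintf("line %d of %s has %d columns; blast8 requires 12",
                  bad, path, nf[which(nf != 12L)[1]]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- tibble(
    query_id = m[, 1], target_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_openings = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    t_start = as.integer(m[, 9]), t_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), score = as.numeric(m[, 12])
  )
  num_cols <- setdiff(names(out), c("query_id", "target_id"))
  if (anyNA(out[num_cols])) {
    abort(sprintf("non-numeric value in a numeric blast8 column of %s", path))
  }
  out
}

#' Write alignments in blast8 format
#'
#' Inverse of [read_blast8()]; the read -> write -> read round trip is
#' field-identical.
#'
#' @param alignments A tibble as returned by [read_blast8()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast8 <- function(alignments, path) {
  fmt_num <- function(x) {
    vapply(x, function(v) format(v, scientific = v != 0 && abs(v) < 1e-3, trim = TRUE),
           character(1))
  }
  lines <- paste(
    alignments$query_id, alignments$target_id,
    fmt_num(alignments$percent_identity), alignments$aln_length,
    alignments$mismatches, alignments$gap_openings,
    alignments$q_start, alignments$q_end,
    alignments$t_start, alignments$t_end,
    fmt_num(alignments$e_value), fmt_num(alignments$score),
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Alignment strand from target coordinates
#'
#' blast8 encodes minus-strand alignments by a target start greater than the
#' target end.
#'
#' @param t_start,t_end Target coordinate vectors.
#' @return A character vector of `"+"` / `"-"`.
#' @export
alignment_strand <- function(t_start, t_end) {
  ifelse(t_start <= t_end, "+", "-")
}
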