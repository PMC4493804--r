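#' Locate the LTR-chromosome junction in a read
#'
#' Performs an exact, case-insensitive substring search for the vector LTR
#' in a read. The genomic portion of an LTR-primed read begins immediately
#' after the LTR, so the junction offset is the 0-based position of the
#' first base downstream of the first LTR occurrence.
#'
#' @param sequence Read sequence (character scalar).
#' @param ltr LTR sequence to search for.
#' @return Integer 0-based offset of the first genomic base, or `NA_integer_`
#'   when the LTR is absent.
#' @examples
#' find_ltr("TTGACGTAACCGG", "TTGACGT")  # 7
#' @export
find_ltr <- function(sequence, ltr) {
  assert_dna(toupper(ltr), "ltr")
  hit <- stringr::str_locate(toupper(sequence), stringr::fixed(toupper(ltr)))
  if (is.na(hit[1, "end"])) NA_integer_ else as.integer(hit[1, "end"])
}

# Trim one read; returns a one-row tibble in the trim_reads() schema.
trim_one <- function(read_id, sequence, ltr, lc, config) {
  seq_up <- toupper(sequence)
  row <- tibble(
    read_id = read_id, query = NA_character_,
    ltr_end_in_read = NA_integer_, lc_found = FALSE,
    truncated_at_n_run = FALSE, reason = NA_character_
  )
  off <- find_ltr(seq_up, ltr)
  if (is.na(off) || off >= nchar(seq_up)) {
    row$reason <- "no_ltr"
    if (!is.na(off)) row$ltr_end_in_read <- off
    if (is.na(off)) return(row)
    # LTR found flush at the read end: no genomic sequence remains, which is
    # a zero-length query -> eliminated as too short, not as missing LTR.
    row$reason <- "too_short"
    return(row)
  }
  query <- substr(seq_up, off + 1L, nchar(seq_up))
  row$ltr_end_in_read <- off
  if (!is.null(lc) && !is.na(lc) && nzchar(lc)) {
    lc_hit <- stringr::str_locate(query, stringr::fixed(toupper(lc)))
    if (!is.na(lc_hit[1, "start"])) {
      row$lc_found <- TRUE
      query <- substr(query, 1L, lc_hit[1, "start"] - 1L)
    }
  }
  n_run <- stringr::str_locate(query, sprintf("N{%d,}", config$n_run_limit))
  if (!is.na(n_run[1, "start"])) {
    row$truncated_at_n_run <- TRUE
    query <- substr(query, 1L, n_run[1, "start"] - 1L)
  }
  if (nchar(query) < config$min_query_len) {
    row$reason <- "too_short"
  } else {
    row$query <- query
  }
  row
}

#' Trim a single read to its genomic query
#'
#' Applies the junction-trimming cascade to one read, in the fixed order:
#' (1) locate the LTR -- reads without an LTR-chromosome junction are
#' eliminated (`no_ltr`); (2) optionally locate the linker cassette (LC)
#' within the query and truncate immediately before it; (3) truncate before
#' the first run of `n_run_limit` (default 3) or more consecutive `N`
#' bases; (4) eliminate queries shorter than `min_query_len` (default
#' 30 bp, the length below which an alignment cannot reach the score
#' cutoff) as `too_short`.
#'
#' @param read A one-row data frame with `read_id` and `sequence`, or a
#'   character sequence (then `read_id` defaults to `"read"`).
#' @param ltr LTR sequence (exact match, case-insensitive).
#' @param lc Optional linker-cassette sequence; `NULL` to skip step (2).
#' @param config A [ris_config()].
#' @return A one-row tibble with columns `read_id`, `query` (`NA` when
#'   eliminated), `ltr_end_in_read`, `lc_found`, `truncated_at_n_run`,
#'   `reason` (`NA` for surviving queries, else `"no_ltr"`/`"too_short"`).
#' @export
trim_read <- function(read, ltr, lc = NULL, config = ris_config()) {
  config <- as_ris_config(config)
  if (is.character(read)) read <- tibble(read_id = "read", sequence = read)
  trim_one(read$read_id[1], read$sequence[1], ltr, lc, config)
}

#' Trim a batch of reads to alignment queries
#'
#' Vectorised [trim_read()] over a reads tibble: every read yields exactly
#' one row, either a surviving query or a filter reason, in input order.
#'
#' @param reads A data frame with columns `read_id` and `sequence`.
#' @inheritParams trim_read
#' @return A tibble, one row per read, with the [trim_read()] schema.
#'   Surviving queries have `reason = NA`; use [trim_queries()] /
#'   [trim_eliminated()] to split the partition.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("a", "b"),
#'   sequence = c(paste0("TTGACGT", strrep("ACGTT", 8)), "CCCCCCCC")
#' )
#' trim_reads(reads, ltr = "TTGACGT")
#' @export
trim_reads <- function(reads, ltr, lc = NULL, config = ris_config()) {
  config <- as_ris_config(config)
  if (anyDuplicated(reads$read_id)) {
    abort(sprintf("duplicate read_id: %s",
                  reads$read_id[duplicated(reads$read_id)][1]))
  }
  if (!nrow(reads)) {
    return(tibble(read_id = character(), query = character(),
                  ltr_end_in_read = integer(), lc_found = logical(),
                  truncated_at_n_run = logical(), reason = character()))
  }
  purrr::map2(reads$read_id, reads$sequence,
              function(id, s) trim_one(id, s, ltr, lc, config)) |>
    bind_rows()
}

#' Surviving queries of a trim partition
#' @param trimmed Output of [trim_reads()].
#' @return Rows with a query, i.e. `reason` is `NA`.
#' @export
trim_queries <- function(trimmed) {
  filter(trimmed, is.na(.data$reason))
}

#' Eliminated reads of a trim partition
#' @param trimmed Output of [trim_reads()].
#' @return A tibble of `read_id`, `reason` for eliminated reads.
#' @export
trim_eliminated <- function(trimmed) {
  trimmed |>
    filter(!is.na(.data$reason)) |>
    select("read_id", "reason")
}
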