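#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across bind_rows left_join row_number n slice_head first
#' @importFrom tibble tibble as_tibble
NULL

# Reverse complement of an uppercase DNA string; N maps to N.
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Hamming mismatch count between two equal-length uppercase strings.
# N counts as a mismatch against anything (including N) except when both
# positions are identical non-N bases -- i.e. only exact A/C/G/T matches count.
hamming_matches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  eq <- ra == rb
  n_raw <- charToRaw("N")
  sum(eq & ra != n_raw)
}

# Validate a single uppercase nucleotide string over {A,C,G,T,N}.
assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  if (grepl("[^ACGTN]", x)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", what))
  }
  invisible(x)
}

# Empty tibble constructors keep column schemas stable for edge cases.
empty_alignments <- function() {
  tibble(
    query_id = character(), target_id = character(),
    percent_identity = double(), aln_length = integer(),
    mismatches = integer(), gap_openings = integer(),
    q_start = integer(), q_end = integer(),
    t_start = integer(), t_end = integer(),
    e_value = double(), score = double()
  )
}

empty_candidates <- function() {
  tibble(
    read_id = character(), chrom = character(), strand = character(),
    position = integer(), far_end = integer(),
    score = double(), percent_identity = double()
  )
}

empty_filter_reasons <- function() {
  tibble(read_id = character(), reason = character())
}

filter_reason_levels <- c(
  "no_ltr", "too_short", "vector_best",
  "ambiguous_second_best", "low_best_identity", "no_passing_alignment"
)
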