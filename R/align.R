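#' Bundle reference sequences for alignment
#'
#' Combines the genome chromosomes with the vector sequence into one
#' reference set. Queries are aligned against both so that reads arising
#' from vector-internal priming (rather than an LTR-chromosome junction)
#' can be recognised and filtered out when their best alignment is to the
#' vector.
#'
#' @param genome A tibble with `read_id`/`sequence` columns (as returned by
#'   [read_fasta()]) or a named character vector of chromosome sequences.
#' @param vector Optional vector sequence in the same forms; `NULL` when
#'   only a genome is used.
#' @param vector_name Name identifying the vector target; defaults to the
#'   vector's FASTA id or `"vector"`. Must not collide with a chromosome
#'   name.
#' @return An object of class `ris_refs`: a named character vector of
#'   uppercase sequences with attribute `vector_name` (`NA` if no vector).
#' @export
reference_set <- function(genome, vector = NULL, vector_name = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(toupper(x$sequence), x$read_id)
    else stats::setNames(toupper(unname(x)), names(x))
  }
  seqs <- as_named(genome)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("every reference sequence must be named")
  }
  vname <- NA_character_
  if (!is.null(vector)) {
    v <- as_named(if (is.character(vector) && is.null(names(vector)))
      stats::setNames(vector, vector_name %||% "vector") else vector)
    vname <- vector_name %||% names(v)[1]
    if (vname %in% names(seqs)) {
      abort(sprintf("vector name '%s' collides with a chromosome name", vname))
    }
    seqs <- c(seqs, stats::setNames(unname(v[1]), vname))
  }
  structure(seqs, vector_name = vname, class = "ris_refs")
}

# All full-length ungapped placements of `sequence` on one target strand.
# Non-overlapping exact seeds of length min_seed tile the query; every
# placement with fewer than floor(len/min_seed) mismatches carries at least
# one exact seed (pigeonhole), so the scan is exhaustive down to that depth.
seed_placements <- function(sequence, subject, min_seed) {
  len <- nchar(sequence)
  n_seeds <- len %/% min_seed
  starts <- integer(0)
  for (k in seq_len(n_seeds)) {
    off <- (k - 1L) * min_seed
    seed <- substr(sequence, off + 1L, off + min_seed)
    if (grepl("N", seed, fixed = TRUE)) next
    hits <- Biostrings::start(Biostrings::matchPattern(seed, subject, fixed = TRUE))
    starts <- c(starts, hits - off)
  }
  starts <- sort(unique(starts))
  starts[starts >= 1L & starts + len - 1L <= length(subject)]
}

#' Built-in deterministic aligner
#'
#' An exhaustive seed-and-extend search for ungapped, full-query placements
#' of each query on both strands of every reference sequence. It serves as
#' a reproducible in-package alignment backend for validation: on the small
#' genomes it is meant for, its hit set is provably identical to a
#' brute-force all-positions Hamming scan for any placement with fewer than
#' `floor(length / min_seed)` mismatches (every such placement contains an
#' exact seed of length `min_seed`).
#'
#' Scoring is `2 * matches - 6 * mismatches` (no gaps are produced), so a
#' perfect 30 bp alignment scores exactly 60 -- the score cutoff below
#' which queries shorter than 30 bp cannot pass. Percent identity is
#' `100 * matches / length`; an `N` never counts as a match. The e-value
#' column is reported as 0 (it has no meaning for an exhaustive scan).
#'
#' @param queries A tibble with columns `read_id` and `query` (or
#'   `sequence`).
#' @param refs A [reference_set()].
#' @param config A [ris_config()]; uses `min_seed`.
#' @param min_report_identity Placements below this percent identity are
#'   not reported (default 90).
#' @return A blast8-schema tibble (see [read_blast8()]), ordered by query,
#'   target and position. Minus-strand placements have `t_start > t_end`;
#'   `q_start`/`q_end` always span the full query.
#' @export
builtin_align <- function(queries, refs, config = ris_config(),
                          min_report_identity = 90) {
  config <- as_ris_config(config)
  stopifnot(inherits(refs, "ris_refs"))
  qcol <- if ("query" %in% names(queries)) "query" else "sequence"
  subjects <- lapply(unclass(refs)[seq_along(refs)], Biostrings::DNAString)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(queries))) {
    qid <- queries$read_id[i]
    qseq <- toupper(queries[[qcol]][i])
    len <- nchar(qseq)
    if (len < config$min_seed) next
    qrc <- revcomp(qseq)
    for (tgt in names(subjects)) {
      subj <- subjects[[tgt]]
      tseq <- refs[[tgt]]
      for (strand in c("+", "-")) {
        s <- if (strand == "+") qseq else qrc
        for (st in seed_placements(s, subj, config$min_seed)) {
          frag <- substr(tseq, st, st + len - 1L)
          matches <- hamming_matches(s, frag)
          identity <- 100 * matches / len
          if (identity < min_report_identity) next
          mism <- len - matches
          rows[[length(rows) + 1L]] <- tibble(
            query_id = qid, target_id = tgt,
            percent_identity = identity, aln_length = len,
            mismatches = as.integer(mism), gap_openings = 0L,
            q_start = 1L, q_end = len,
            t_start = if (strand == "+") st else st + len - 1L,
            t_end = if (strand == "+") st + len - 1L else st,
            e_value = 0, score = 2 * matches - 6 * mism
          )
        }
      }
    }
  }
  if (!length(rows)) return(empty_alignments())
  bind_rows(rows) |>
    arrange(.data$query_id, .data$target_id,
            pmin(.data$t_start, .data$t_end), .data$t_start)
}

#' Align queries against the reference set
#'
#' Dispatches to one of three backends: the deterministic built-in aligner
#' (`"builtin"`), a pre-computed blast8 file (`"blast8"`, e.g. produced by
#' an external BLAT run), or an arbitrary external aligner command
#' (`"command"`) that must write blast8. The command template may contain
#' the placeholders `{queries}`, `{reference}` and `{output}`, which are
#' substituted with temporary FASTA paths and the expected output path.
#'
#' @param queries Tibble with `read_id` and `query`/`sequence` columns.
#' @param refs A [reference_set()] (required for `builtin` and `command`).
#' @param backend `"builtin"`, `"blast8"` or `"command"`.
#' @param blast8_path Path to an existing blast8 file (backend `"blast8"`).
#' @param command Command template (backend `"command"`).
#' @param config A [ris_config()].
#' @return A blast8-schema tibble. For the `blast8` backend, records naming
#'   unknown query ids are kept with a warning.
#' @export
align_queries <- function(queries, refs = NULL,
                          backend = c("builtin", "blast8", "command"),
                          blast8_path = NULL, command = NULL,
                          config = ris_config()) {
  backend <- match.arg(backend)
  config <- as_ris_config(config)
  if (backend == "builtin") {
    if (is.null(refs)) abort("the builtin backend needs a reference_set")
    return(builtin_align(queries, refs, config))
  }
  if (backend == "blast8") {
    if (is.null(blast8_path)) abort("backend 'blast8' needs `blast8_path`")
    aln <- read_blast8(blast8_path)
    unknown <- setdiff(unique(aln$query_id), queries$read_id)
    if (length(unknown)) {
      warn(sprintf("blast8 file references %d query id(s) not in the query set (e.g. %s); records kept",
                   length(unknown), unknown[1]))
    }
    return(aln)
  }
  if (is.null(command)) abort("backend 'command' needs `command`")
  if (is.null(refs)) abort("backend 'command' needs a reference_set")
  qf <- tempfile(fileext = ".fa")
  rf <- tempfile(fileext = ".fa")
  of <- tempfile(fileext = ".blast8")
  qcol <- if ("query" %in% names(queries)) "query" else "sequence"
  write_fasta(tibble(read_id = queries$read_id, sequence = queries[[qcol]]), qf)
  write_fasta(tibble(read_id = names(refs), sequence = unname(unclass(refs))), rf)
  cmd <- command
  cmd <- gsub("{queries}", qf, cmd, fixed = TRUE)
  cmd <- gsub("{reference}", rf, cmd, fixed = TRUE)
  cmd <- gsub("{output}", of, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) {
    abort(sprintf("external aligner failed with exit status %d: %s", status, cmd))
  }
  read_blast8(of)
}
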