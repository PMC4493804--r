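#' Run the full integration-site pipeline
#'
#' Orchestrates the stages in order: (1) trim LTR-chromosome junctions to
#' genomic queries, (2) align queries to the genome plus vector, (3) keep
#' the top alignments per query and remove queries that cannot be placed
#' unequivocally, (4) cluster candidate sites into unique RISs, (5)
#' annotate gene / TSS / feature proximity, (6) optionally process a
#' random control set through the identical alignment-onward path and test
#' the observed proximity profile against it, and (7) write concise and
#' complete CSV reports when `out_dir` is given.
#'
#' All tabular arguments also accept file paths: reads / genome / vector
#' as FASTA, genes as refFlat, features as BED.
#'
#' @param reads Reads tibble (`read_id`, `sequence`) or FASTA path.
#' @param ltr LTR sequence (string or single-record FASTA path).
#' @param genome Genome tibble or FASTA path.
#' @param vector Vector sequence tibble / FASTA path, or `NULL`.
#' @param lc Optional linker-cassette sequence (string or FASTA path).
#' @param genes Optional gene tibble ([read_genes()]) or refFlat path.
#' @param features Optional feature tibble ([read_features_bed()]) or BED
#'   path.
#' @param config A [ris_config()] or list of overrides.
#' @param backend,blast8_path,align_command Passed to [align_queries()].
#' @param random_n Number of random control sites; `NULL` (default)
#'   disables the control stage, `NA` uses `config$random_n_default`.
#' @param random_length Control site length in bp (default 40).
#' @param out_dir Optional output directory for [write_reports()].
#' @return An object of class `ris_run`: a list with `config`, `trimmed`,
#'   `alignments`, `passing`, `candidates`, `filter_reasons`,
#'   `unique_ris`, `annotated`, `random` (a `ris_random_control` or
#'   `NULL`), `results` (a `ris_summary`), and `manifest` (per-stage
#'   counts).
#' @examples
#' sim <- simulate_dataset(genome_length = 20000, n_integrations = 6,
#'                         error_rate = 0, seed = 7)
#' run <- run_pipeline(sim$reads, ltr = sim$ltr, genome = sim$genome,
#'                     vector = sim$vector, lc = sim$lc, genes = sim$genes)
#' run$unique_ris
#' @export
run_pipeline <- function(reads, ltr, genome, vector = NULL, lc = NULL,
                         genes = NULL, features = NULL,
                         config = ris_config(),
                         backend = c("builtin", "blast8", "command"),
                         blast8_path = NULL, align_command = NULL,
                         random_n = NULL, random_length = 40L,
                         out_dir = NULL) {
  config <- as_ris_config(config)
  backend <- match.arg(backend)
  as_seq_table <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x)) return(read_fasta(x))
    if (is.data.frame(x)) return(x)
    abort(sprintf("`%s` must be a tibble or an existing FASTA path", what))
  }
  as_short_seq <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      return(read_fasta(x)$sequence[1])
    }
    toupper(x)
  }
  reads <- as_seq_table(reads, "reads")
  genome <- as_seq_table(genome, "genome")
  vector <- as_seq_table(vector, "vector")
  ltr <- as_short_seq(ltr)
  lc <- as_short_seq(lc)
  if (is.character(genes) && length(genes) == 1L) genes <- read_genes(genes)
  if (is.character(features) && length(features) == 1L) {
    features <- read_features_bed(features)
  }

  trimmed <- trim_reads(reads, ltr, lc, config)
  queries <- trim_queries(trimmed)

  refs <- reference_set(genome, vector)
  alignments <- align_queries(queries, refs, backend = backend,
                              blast8_path = blast8_path,
                              command = align_command, config = config)
  passing <- initial_filter(alignments, config)
  top <- top_alignments(passing, config)
  cls <- classify_queries(top, config,
                          vector_name = attr(refs, "vector_name"),
                          query_ids = queries$read_id)
  filter_reasons <- bind_rows(trim_eliminated(trimmed), cls$rejected)

  unique_ris <- call_unique_ris(cls$candidates, config)
  annotated <- unique_ris
  if (!is.null(genes) && nrow(unique_ris)) {
    annotated <- annotate_genes(annotated, genes, config) |>
      annotate_tss(genes)
  }
  if (!is.null(features) && nrow(unique_ris)) {
    annotated <- annotate_features(annotated, features)
  }

  random <- NULL
  if (!is.null(random_n)) {
    rn <- if (is.na(random_n)) config$random_n_default else as.integer(random_n)
    random <- random_control_run(genome, genes, features,
                                 n = rn, site_length = random_length,
                                 seed = config$seed, refs = refs,
                                 config = config)
  }
  results <- if (!is.null(genes) && nrow(unique_ris)) {
    summarize_integration(annotated, random$annotated, config)
  } else NULL

  reason_counts <- table(factor(filter_reasons$reason,
                                levels = filter_reason_levels))
  manifest <- list(
    config = unclass(config),
    counts = tibble(
      stage = c("reads", "queries", "alignments", "passing_alignments",
                "candidates", "unique_ris",
                paste0("eliminated_", names(reason_counts))),
      n = c(nrow(reads), nrow(queries), nrow(alignments), nrow(passing),
            nrow(cls$candidates), nrow(unique_ris),
            as.integer(reason_counts))
    ),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  run <- structure(list(
    config = config, trimmed = trimmed, alignments = alignments,
    passing = passing, candidates = cls$candidates,
    filter_reasons = filter_reasons, unique_ris = unique_ris,
    annotated = annotated, random = random, results = results,
    manifest = manifest
  ), class = "ris_run")
  if (!is.null(out_dir)) write_reports(run, out_dir)
  run
}

#' @export
print.ris_run <- function(x, ...) {
  cat("<ris_run>\n")
  print(x$manifest$counts, n = Inf)
  if (!is.null(x$results)) {
    cat("\n")
    print(x$results)
  }
  invisible(x)
}

#' Concise per-site report table
#'
#' One row per unique integration site with position, support and (when
#' annotated) gene, TSS and feature proximity columns.
#'
#' @param run A `ris_run`.
#' @return A tibble without the nested `members` column.
#' @export
concise_report <- function(run) {
  select(run$annotated, -dplyr::any_of("members"))
}

#' Write concise and complete CSV reports
#'
#' Writes `unique_ris.csv` (the concise per-site table), the complete
#' outputs (`candidates.csv`, `members.csv`, one
#' `filtered_<reason>.csv` per elimination reason, `alignments.csv`),
#' `summary.csv` and `chisq.csv` when tests were run, and a
#' `manifest.json` snapshot of configuration and stage counts.
#'
#' @param run A `ris_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(run, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    abort(sprintf("cannot write to output directory: %s", out_dir))
  }
  readr::write_csv(concise_report(run), file.path(out_dir, "unique_ris.csv"),
                   na = "")
  readr::write_csv(run$candidates, file.path(out_dir, "candidates.csv"))
  if (nrow(run$unique_ris)) {
    readr::write_csv(ris_members(run$unique_ris),
                     file.path(out_dir, "members.csv"))
  }
  readr::write_csv(run$alignments, file.path(out_dir, "alignments.csv"))
  for (r in unique(run$filter_reasons$reason)) {
    readr::write_csv(filter(run$filter_reasons, .data$reason == r),
                     file.path(out_dir, sprintf("filtered_%s.csv", r)))
  }
  if (!is.null(run$results)) {
    readr::write_csv(run$results$summary, file.path(out_dir, "summary.csv"))
    tests <- list(gene = run$results$gene_test,
                  feature = run$results$feature_test)
    rows <- purrr::imap(tests, function(t, nm) {
      if (is.null(t)) return(NULL)
      mutate(t$table, test = nm, statistic = t$statistic, df = t$df,
             p_value = t$p_value)
    })
    rows <- purrr::compact(rows)
    if (length(rows)) {
      readr::write_csv(bind_rows(rows), file.path(out_dir, "chisq.csv"))
    }
  }
  jsonlite::write_json(
    list(config = run$manifest$config,
         counts = run$manifest$counts,
         timestamp = run$manifest$timestamp),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
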