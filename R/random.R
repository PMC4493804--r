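#' Generate random integration-site control sequences
#'
#' Draws `n` sites of `site_length` bp uniformly from the genome: a
#' chromosome is chosen with probability proportional to its number of
#' valid start positions (`length - site_length + 1`), the start is
#' uniform over those positions, and the strand is uniform; minus-strand
#' sites are reverse-complemented, mimicking junction fragments recovered
#' in either orientation. Sites containing any `N` are redrawn (bounded at
#' `100 * n` attempts) so the control set is not length-distorted by
#' ambiguity truncation downstream.
#'
#' @param genome A genome tibble (`read_id`, `sequence`) or named character
#'   vector.
#' @param n Number of sites; must lie in `config$random_n_bounds`
#'   (1..100,000).
#' @param site_length Site length in bp; must lie in
#'   `config$random_len_bounds` (30..1000).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param config A [ris_config()].
#' @return A tibble with `read_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand` and `sequence` -- the truth table and FASTA
#'   content in one; write with [write_fasta()].
#' @export
generate_random_sites <- function(genome, n, site_length, seed = NULL,
                                  config = ris_config()) {
  config <- as_ris_config(config)
  seed <- seed %||% config$seed
  nb <- config$random_n_bounds
  lb <- config$random_len_bounds
  if (n < nb[1] || n > nb[2]) {
    abort(sprintf("n must be between %d and %d sites", nb[1], nb[2]))
  }
  if (site_length < lb[1] || site_length > lb[2]) {
    abort(sprintf("site_length must be between %d and %d bp", lb[1], lb[2]))
  }
  seqs <- if (is.data.frame(genome)) {
    stats::setNames(toupper(genome$sequence), genome$read_id)
  } else stats::setNames(toupper(unname(genome)), names(genome))
  lens <- nchar(seqs)
  if (any(lens < site_length)) {
    abort(sprintf("chromosome %s is shorter than site_length",
                  names(seqs)[lens < site_length][1]))
  }
  weights <- lens - site_length + 1
  withr::with_seed(seed, {
    rows <- vector("list", n)
    accepted <- 0L
    attempts <- 0L
    while (accepted < n) {
      attempts <- attempts + 1L
      if (attempts > 100L * n) {
        abort("exhausted redraw attempts: too many ambiguous bases in the genome")
      }
      ci <- sample.int(length(seqs), 1L, prob = weights)
      start <- sample.int(weights[ci], 1L)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      s <- substr(seqs[[ci]], start, start + site_length - 1L)
      if (grepl("N", s, fixed = TRUE)) next
      accepted <- accepted + 1L
      rows[[accepted]] <- tibble(
        read_id = sprintf("random_%06d", accepted),
        chrom = names(seqs)[ci],
        start = as.integer(start),
        end = as.integer(start + site_length - 1L),
        strand = strand,
        sequence = if (strand == "+") s else revcomp(s)
      )
    }
    bind_rows(rows)
  })
}

#' Process random control sites through the alignment pipeline
#'
#' Random sites carry no LTR, so they enter the pipeline at alignment and
#' are then filtered, classified and annotated with exactly the same
#' functions as real queries -- imparting the same mapping biases
#' (repetitive-region ambiguity, identity filtering) that affect observed
#' sites. The surviving sites' proximity proportions are the expected
#' values for the chi-squared goodness-of-fit tests.
#'
#' @param genome Genome tibble or named character vector.
#' @param genes Gene tibble ([read_genes()]), or `NULL`.
#' @param features Feature tibble ([read_features_bed()]), or `NULL`.
#' @param n,site_length,seed Passed to [generate_random_sites()];
#'   `n` defaults to `config$random_n_default`.
#' @param refs Optional [reference_set()]; built from `genome` (plus
#'   `vector`) when omitted.
#' @param vector Optional vector sequence included in the reference so the
#'   vector-best filter applies to controls too.
#' @param config A [ris_config()].
#' @return A list of class `ris_random_control`: `sites` (truth table),
#'   `candidates`, `annotated` (surviving candidates with annotations),
#'   `rejected`, `survival` (surviving fraction), and `proportions`
#'   (list with `gene` and optionally `feature` proportion vectors).
#' @export
random_control_run <- function(genome, genes = NULL, features = NULL,
                               n = NULL, site_length = 40L, seed = NULL,
                               refs = NULL, vector = NULL,
                               config = ris_config()) {
  config <- as_ris_config(config)
  n <- n %||% config$random_n_default
  sites <- generate_random_sites(genome, n, site_length, seed, config)
  refs <- refs %||% reference_set(genome, vector)
  aln <- align_queries(sites, refs, backend = "builtin", config = config)
  passing <- initial_filter(aln, config)
  top <- top_alignments(passing, config)
  cls <- classify_queries(top, config,
                          vector_name = attr(refs, "vector_name"),
                          query_ids = sites$read_id)
  if (!nrow(cls$candidates)) {
    abort("all random control sites were filtered out")
  }
  annotated <- cls$candidates
  if (!is.null(genes)) {
    annotated <- annotate_genes(annotated, genes, config) |>
      annotate_tss(genes)
  }
  if (!is.null(features)) {
    annotated <- annotate_features(annotated, features)
  }
  proportions <- list()
  if (!is.null(genes)) {
    proportions$gene <- as.numeric(prop.table(table(gene_category(annotated))))
    names(proportions$gene) <- levels(gene_category(annotated))
  }
  if (!is.null(features)) {
    proportions$feature <- as.numeric(prop.table(table(feature_category(annotated))))
    names(proportions$feature) <- levels(feature_category(annotated))
  }
  structure(list(sites = sites, candidates = cls$candidates,
                 annotated = annotated, rejected = cls$rejected,
                 survival = nrow(cls$candidates) / nrow(sites),
                 proportions = proportions),
            class = "ris_random_control")
}
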