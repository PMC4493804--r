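#' Pipeline configuration
#'
#' Collects every numeric threshold of the integration-site pipeline as a
#' named, overridable parameter. The defaults are the published, recommended
#' settings for LTR-junction data: queries shorter than 30 bp are eliminated
#' (they cannot reach the alignment-score cutoff of 60), alignments below
#' 92 % identity or starting more than 3 bp into the query are dropped, the
#' 5 best-scoring alignments per query are kept, a query is called ambiguous
#' when its second-best score exceeds 95 % of the best (90 % for best scores
#' below 100), the best alignment must reach 95 % identity, candidate sites
#' within +/- 5 bp on the same chromosome and strand are merged, genes are
#' reported up to 5 kb away, and random controls default to 100,000 sites.
#'
#' @param min_query_len Minimum trimmed query length in bp (default 30).
#' @param n_run_limit Queries are truncated before a run of this many
#'   consecutive ambiguous bases, `N` (default 3).
#' @param min_score Minimum alignment score, blast8 column 12 (default 60).
#' @param min_identity_initial Minimum percent identity for any alignment to
#'   be considered (default 92).
#' @param max_qstart_offset Maximum distance in bp between the alignment
#'   start and the query start, `q_start - 1` (default 3).
#' @param top_k Number of best-scoring alignments retained per query
#'   (default 5).
#' @param ratio_hi,ratio_lo Second-best/best score percentage above which a
#'   query is rejected as ambiguous; `ratio_hi` (95) applies when the best
#'   score is at least `ratio_score_boundary`, `ratio_lo` (90) below it.
#' @param ratio_score_boundary Score boundary between the two ratio tiers
#'   (default 100).
#' @param min_best_identity Minimum percent identity of the best alignment
#'   for a candidate call (default 95).
#' @param cluster_halfwidth Half-width in bp of the site-merging window;
#'   candidates within this distance of a unique site join its cluster
#'   (default 5, i.e. a 10 bp window).
#' @param gene_max_dist Maximum distance in bp at which a nearby gene is
#'   reported for a site not inside any gene (default 5000).
#' @param random_n_default Default number of random control sites
#'   (default 100000).
#' @param random_len_bounds,random_n_bounds Allowed (min, max) for random
#'   site length and count (defaults c(30, 1000) and c(1, 100000)).
#' @param min_seed Exact-seed length used by the built-in aligner
#'   (default 7).
#' @param seed Integer seed controlling all randomness (default 1).
#'
#' @return A named list of class `ris_config`.
#' @examples
#' cfg <- ris_config(min_score = 50)
#' cfg$min_score
#' @export
ris_config <- function(min_query_len = 30L,
                       n_run_limit = 3L,
                       min_score = 60,
                       min_identity_initial = 92,
                       max_qstart_offset = 3L,
                       top_k = 5L,
                       ratio_hi = 95,
                       ratio_lo = 90,
                       ratio_score_boundary = 100,
                       min_best_identity = 95,
                       cluster_halfwidth = 5L,
                       gene_max_dist = 5000L,
                       random_n_default = 100000L,
                       random_len_bounds = c(30L, 1000L),
                       random_n_bounds = c(1L, 100000L),
                       min_seed = 7L,
                       seed = 1L) {
  cfg <- list(
    min_query_len = as.integer(min_query_len),
    n_run_limit = as.integer(n_run_limit),
    min_score = as.numeric(min_score),
    min_identity_initial = as.numeric(min_identity_initial),
    max_qstart_offset = as.integer(max_qstart_offset),
    top_k = as.integer(top_k),
    ratio_hi = as.numeric(ratio_hi),
    ratio_lo = as.numeric(ratio_lo),
    ratio_score_boundary = as.numeric(ratio_score_boundary),
    min_best_identity = as.numeric(min_best_identity),
    cluster_halfwidth = as.integer(cluster_halfwidth),
    gene_max_dist = as.integer(gene_max_dist),
    random_n_default = as.integer(random_n_default),
    random_len_bounds = as.integer(random_len_bounds),
    random_n_bounds = as.integer(random_n_bounds),
    min_seed = as.integer(min_seed),
    seed = as.integer(seed)
  )
  scalars <- setdiff(names(cfg), c("random_len_bounds", "random_n_bounds"))
  bad <- scalars[!vapply(cfg[scalars], function(v) length(v) == 1L && !is.na(v) && v > 0 ||
                           identical(v, cfg$seed), logical(1))]
  if (any(vapply(cfg[scalars], function(v) length(v) != 1L || is.na(v), logical(1)))) {
    abort("all configuration thresholds must be single non-missing values")
  }
  pos <- setdiff(scalars, "seed")
  if (any(vapply(cfg[pos], function(v) v <= 0, logical(1)))) {
    abort("all configuration thresholds must be positive")
  }
  for (b in c("random_len_bounds", "random_n_bounds")) {
    if (length(cfg[[b]]) != 2L || cfg[[b]][1] > cfg[[b]][2]) {
      abort(sprintf("%s must be an ordered (min, max) pair", b))
    }
  }
  structure(cfg, class = "ris_config")
}

#' @export
print.ris_config <- function(x, ...) {
  cat("<ris_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = "..")))
  }
  invisible(x)
}

as_ris_config <- function(config) {
  if (inherits(config, "ris_config")) return(config)
  if (is.list(config)) return(do.call(ris_config, config))
  abort("`config` must be a ris_config or a named list of overrides")
}
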