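#' Annotate sites with gene proximity
#'
#' Phase one of gene annotation: each site is first tested for containment
#' within a gene's transcription bounds (ties between containing genes are
#' broken by smallest transcript span, then name). A site not inside any
#' gene is assigned the nearest gene whose 5' or 3' end lies within
#' `gene_max_dist` (default 5 kb); farther sites get no gene. The distance
#' is unsigned (to the nearer gene end); the side relative to the gene --
#' `upstream` or `downstream` in gene orientation -- is reported
#' separately, since an upstream provirus can dysregulate a gene by
#' enhancer activation while an intragenic one can cause premature
#' polyadenylation.
#'
#' @param sites A tibble with at least `chrom` and `position` columns.
#' @param genes A gene tibble from [read_genes()].
#' @param config A [ris_config()].
#' @return `sites` with added columns `in_gene` (logical), `gene_name`
#'   (`NA` when no gene within range), `gene_distance` (0 when inside,
#'   else bp to the nearer end), `gene_side` (`"within"`, `"upstream"`,
#'   `"downstream"` or `NA`).
#' @export
annotate_genes <- function(sites, genes, config = ris_config()) {
  config <- as_ris_config(config)
  ann <- purrr::pmap(list(sites$chrom, sites$position), function(chrom, pos) {
    g <- genes[genes$chrom == chrom, ]
    none <- tibble(in_gene = FALSE, gene_name = NA_character_,
                   gene_distance = NA_integer_, gene_side = NA_character_)
    if (!nrow(g)) return(none)
    inside <- g$tx_start <= pos & pos <= g$tx_end
    if (any(inside)) {
      gi <- g[inside, ]
      gi <- gi[order(gi$tx_end - gi$tx_start, gi$gene_name), ]
      return(tibble(in_gene = TRUE, gene_name = gi$gene_name[1],
                    gene_distance = 0L, gene_side = "within"))
    }
    d <- ifelse(pos < g$tx_start, g$tx_start - pos, pos - g$tx_end)
    g <- g[order(d, g$gene_name), ]
    d <- sort(d)
    if (d[1] > config$gene_max_dist) return(none)
    side <- if (pos < g$tx_start[1]) {
      if (g$strand[1] == "+") "upstream" else "downstream"
    } else {
      if (g$strand[1] == "+") "downstream" else "upstream"
    }
    tibble(in_gene = FALSE, gene_name = g$gene_name[1],
           gene_distance = as.integer(d[1]), gene_side = side)
  }) |> bind_rows()
  dplyr::bind_cols(sites, ann)
}

#' Annotate sites with nearest transcription start site
#'
#' Phase two of gene annotation: independently of containment, each site is
#' assigned the gene (on its chromosome, at any distance) whose TSS is
#' closest. A provirus can sit inside one gene yet be closer to the TSS of
#' another; both facts are reported. The distance is signed in gene
#' orientation: negative when the site lies upstream of the TSS, positive
#' downstream, 0 at the TSS.
#'
#' @inheritParams annotate_genes
#' @return `sites` with added columns `tss_gene_name` and `tss_distance`
#'   (`NA` when the chromosome carries no genes).
#' @export
annotate_tss <- function(sites, genes) {
  ann <- purrr::pmap(list(sites$chrom, sites$position), function(chrom, pos) {
    g <- genes[genes$chrom == chrom, ]
    if (!nrow(g)) {
      return(tibble(tss_gene_name = NA_character_, tss_distance = NA_integer_))
    }
    d <- abs(pos - g$tss)
    g <- g[order(d, g$gene_name), ]
    signed <- if (g$strand[1] == "+") pos - g$tss[1] else g$tss[1] - pos
    tibble(tss_gene_name = g$gene_name[1], tss_distance = as.integer(signed))
  }) |> bind_rows()
  dplyr::bind_cols(sites, ann)
}

#' Annotate sites with custom genomic-feature proximity
#'
#' For a user-provided feature list (e.g. CpG islands, oncogene loci),
#' reports whether each site falls within a feature and its unsigned
#' distance to the closest feature on its chromosome (no distance cap).
#' Ties are broken by feature name.
#'
#' @param sites A tibble with `chrom` and `position` columns.
#' @param features A feature tibble from [read_features_bed()].
#' @return `sites` with added columns `feature_within` (logical),
#'   `nearest_feature` and `feature_distance` (`NA` when the chromosome has
#'   no features).
#' @export
annotate_features <- function(sites, features) {
  ann <- purrr::pmap(list(sites$chrom, sites$position), function(chrom, pos) {
    f <- features[features$chrom == chrom, ]
    if (!nrow(f)) {
      return(tibble(feature_within = FALSE, nearest_feature = NA_character_,
                    feature_distance = NA_integer_))
    }
    d <- ifelse(pos < f$start, f$start - pos,
                ifelse(pos > f$end, pos - f$end, 0L))
    f <- f[order(d, f$feature_name), ]
    d <- sort(d)
    tibble(feature_within = d[1] == 0L, nearest_feature = f$feature_name[1],
           feature_distance = as.integer(d[1]))
  }) |> bind_rows()
  dplyr::bind_cols(sites, ann)
}

#' Pearson chi-squared goodness-of-fit test
#'
#' Tests observed category counts against expected proportions -- here,
#' the proximity classes of observed integration sites against the
#' proportions measured on randomly generated control sites processed
#' through the identical pipeline. The statistic is
#' `sum((obs - N p)^2 / (N p))` with `N` the observed total, compared to a
#' chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @param observed Integer counts per category (named or paired with
#'   `categories`).
#' @param expected_props Expected proportions per category; must sum to 1.
#' @param categories Optional category labels.
#' @return An object of class `ris_chisq` with elements `table` (tibble of
#'   category, observed, expected), `statistic`, `df`, `p_value`. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @examples
#' chisq_gof(c(10, 90), c(0.5, 0.5))
#' @export
chisq_gof <- function(observed, expected_props, categories = NULL) {
  if (length(observed) != length(expected_props) || length(observed) < 2L) {
    abort("observed and expected_props must have equal length >= 2")
  }
  if (abs(sum(expected_props) - 1) > 1e-9) {
    abort("expected_props must sum to 1")
  }
  if (any(expected_props == 0 & observed > 0)) {
    abort(paste("a category with expected proportion 0 has nonzero observed",
                "counts; merge it into a neighbouring category"))
  }
  categories <- categories %||% names(observed) %||%
    paste0("category_", seq_along(observed))
  n <- sum(observed)
  expected <- n * expected_props
  keep <- expected > 0
  statistic <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- length(observed) - 1L
  structure(list(
    table = tibble(category = categories,
                   observed = as.integer(observed),
                   expected = as.numeric(expected)),
    statistic = statistic, df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE)
  ), class = "ris_chisq")
}

#' @export
print.ris_chisq <- function(x, ...) {
  cat(sprintf("Chi-squared goodness of fit: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

# Three-way gene-proximity category used for both observed and random sites.
gene_category <- function(annotated) {
  factor(
    dplyr::case_when(
      annotated$in_gene ~ "in_gene",
      !is.na(annotated$gene_name) ~ "within_5kb",
      TRUE ~ "beyond"
    ),
    levels = c("in_gene", "within_5kb", "beyond")
  )
}

feature_category <- function(annotated) {
  factor(ifelse(annotated$feature_within, "within", "not_within"),
         levels = c("within", "not_within"))
}

#' Summarise an integration profile against random controls
#'
#' Computes headline statistics of the annotated unique-site set (site
#' count, percent within genes, number within 5 kb of a gene) and, when an
#' annotated random-control set is supplied, Pearson chi-squared
#' goodness-of-fit tests of the observed proximity profile against the
#' control proportions: a three-category gene test (in gene / within 5 kb /
#' beyond) and, when features were annotated, a two-category feature test
#' (within / not within).
#'
#' @param annotated Unique sites annotated with [annotate_genes()] (and
#'   optionally [annotate_features()]).
#' @param random_annotated Random control sites annotated with the same
#'   functions and inputs, or `NULL`.
#' @param config A [ris_config()].
#' @return A list of class `ris_summary`: `summary` (one-row tibble),
#'   `gene_test` and `feature_test` (`ris_chisq` or `NULL`).
#' @export
summarize_integration <- function(annotated, random_annotated = NULL,
                                  config = ris_config()) {
  config <- as_ris_config(config)
  n <- nrow(annotated)
  obs_gene <- table(gene_category(annotated))
  summary <- tibble(
    n_unique = n,
    pct_in_genes = if (n) 100 * sum(annotated$in_gene) / n else NA_real_,
    n_within_5kb = as.integer(obs_gene[["within_5kb"]]),
    n_beyond = as.integer(obs_gene[["beyond"]])
  )
  has_features <- "feature_within" %in% names(annotated)
  if (has_features) {
    summary$n_in_features <- sum(annotated$feature_within)
  }
  gene_test <- feature_test <- NULL
  if (is.null(random_annotated) || !nrow(random_annotated)) {
    if (!is.null(random_annotated)) {
      warn("random control set is empty; chi-squared tests skipped")
    }
  } else if (n) {
    props <- as.numeric(prop.table(table(gene_category(random_annotated))))
    gene_test <- chisq_gof(as.integer(obs_gene), props,
                           categories = levels(gene_category(annotated)))
    if (has_features && "feature_within" %in% names(random_annotated)) {
      obs_f <- table(feature_category(annotated))
      props_f <- as.numeric(prop.table(table(feature_category(random_annotated))))
      feature_test <- chisq_gof(as.integer(obs_f), props_f,
                                categories = levels(feature_category(annotated)))
    }
  }
  structure(list(summary = summary, gene_test = gene_test,
                 feature_test = feature_test),
            class = "ris_summary")
}

#' @export
print.ris_summary <- function(x, ...) {
  cat("<integration summary>\n")
  print(x$summary)
  if (!is.null(x$gene_test)) {
    cat("\nGene proximity vs random control:\n")
    print(x$gene_test)
  }
  if (!is.null(x$feature_test)) {
    cat("\nFeature proximity vs random control:\n")
    print(x$feature_test)
  }
  invisible(x)
}
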