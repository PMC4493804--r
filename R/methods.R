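#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the unique integration sites of a pipeline run
#'
#' @param x A `ris_run`.
#' @param ... Unused.
#' @return The concise per-site tibble (see [concise_report()]).
#' @method tidy ris_run
#' @export
tidy.ris_run <- function(x, ...) {
  concise_report(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `ris_run`.
#' @param ... Unused.
#' @return A one-row tibble: read/query/candidate/unique-site counts,
#'   percent of sites in genes and chi-squared results when computed.
#' @method glance ris_run
#' @export
glance.ris_run <- function(x, ...) {
  counts <- stats::setNames(as.list(x$manifest$counts$n),
                            x$manifest$counts$stage)
  out <- tibble(
    n_reads = counts$reads, n_queries = counts$queries,
    n_candidates = counts$candidates, n_unique_ris = counts$unique_ris
  )
  if (!is.null(x$results)) {
    out <- dplyr::bind_cols(out, x$results$summary["pct_in_genes"])
    if (!is.null(x$results$gene_test)) {
      out$gene_statistic <- x$results$gene_test$statistic
      out$gene_p_value <- x$results$gene_test$p_value
    }
  }
  out
}

#' @describeIn chisq_gof Tidy the per-category table.
#' @param x A `ris_chisq`.
#' @param ... Unused.
#' @method tidy ris_chisq
#' @export
tidy.ris_chisq <- function(x, ...) {
  x$table
}

#' @describeIn chisq_gof One-row statistic/df/p tibble.
#' @method glance ris_chisq
#' @export
glance.ris_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Plot unique integration sites along the genome
#'
#' Each site is drawn at its chromosome position with height equal to its
#' read frequency and colour showing its distinct-span count -- the
#' frequency/span contrast separates PCR duplication (high frequency, one
#' span) from clonal expansion (many spans).
#'
#' @param object A `ris_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ris_run
#' @export
autoplot.ris_run <- function(object, ...) {
  df <- object$unique_ris
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   colour = .data$span_count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          linewidth = 0.6) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "chromosome position (bp)", y = "read frequency",
                  colour = "spans",
                  title = "Unique retroviral integration sites") +
    ggplot2::theme_minimal()
}

#' Plot observed vs expected gene-proximity categories
#'
#' Side-by-side bars of the observed unique-site counts and the expected
#' counts derived from the random-control proportions, for the
#' chi-squared gene-proximity test.
#'
#' @param run A `ris_run` whose results include a gene test.
#' @return A ggplot object.
#' @export
plot_gene_proximity <- function(run) {
  t <- run$results$gene_test
  if (is.null(t)) abort("run has no gene-proximity chi-squared test")
  df <- t$table |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "source", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "sites",
                  title = "Gene proximity: observed vs random-control expectation",
                  subtitle = sprintf("X^2 = %.3g, df = %d, p = %.3g",
                                     t$statistic, t$df, t$p_value)) +
    ggplot2::theme_minimal()
}
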