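grid_genes <- function() {
  tibble::tibble(
    gene_name = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(4000L, 9000L, 100L),
    tx_end = c(6000L, 12000L, 900L),
    tss = c(4000L, 12000L, 100L)
  )
}

sites_at <- function(pos, chrom = "chr1") {
  tibble::tibble(chrom = chrom, position = as.integer(pos))
}

test_that("gene annotation reports containment, capped nearest distance and side", {
  g <- grid_genes()
  a <- annotate_genes(sites_at(5000), g)
  expect_true(a$in_gene)
  expect_equal(a$gene_distance, 0L)
  expect_equal(a$gene_name, "geneA")
  expect_equal(a$gene_side, "within")

  a <- annotate_genes(sites_at(3500), g)
  expect_false(a$in_gene)
  expect_equal(a$gene_name, "geneA")
  expect_equal(a$gene_distance, 500L)
  expect_equal(a$gene_side, "upstream")   # 5' of a plus-strand gene

  # past the 5 kb cap: no gene reported
  a <- annotate_genes(sites_at(3500),
                      dplyr::mutate(g[1, ], tx_start = 9000L, tx_end = 11000L))
  expect_true(is.na(a$gene_name))

  # downstream side of a minus-strand gene (left of its tx_start)
  a <- annotate_genes(sites_at(8800), g)
  expect_equal(a$gene_name, "geneB")
  expect_equal(a$gene_side, "downstream")
})

test_that("TSS annotation is signed in gene orientation and may cross genes", {
  g <- grid_genes()
  # at a plus-strand gene's tx_start: distance 0
  a <- annotate_tss(sites_at(4000), g)
  expect_equal(a$tss_distance, 0L)
  # inside geneB (minus strand, TSS at its tx_end 12000), closer to its own TSS
  a <- annotate_tss(sites_at(11900), g)
  expect_equal(a$tss_gene_name, "geneB")
  expect_equal(a$tss_distance, 100L)   # downstream of the minus-strand TSS
  # 300 bp 5' (upstream in gene orientation) of a minus-strand TSS
  a <- annotate_tss(sites_at(12300), g)
  expect_equal(a$tss_distance, -300L)
  # a site inside geneB near position 9100 is closer to geneA's TSS? no --
  # but a site at 8200 (outside both) is closest to geneB's far TSS via geneA:
  a <- annotate_tss(sites_at(5900), g)
  expect_equal(a$tss_gene_name, "geneA")  # |5900-4000| < |12000-5900|
  # no genes on the chromosome
  a <- annotate_tss(sites_at(100, chrom = "chrX"), g)
  expect_true(is.na(a$tss_gene_name))
})

test_that("a site within one gene can be reported nearest another gene's TSS", {
  g <- tibble::tibble(
    gene_name = c("host", "neighbor"),
    chrom = "chr1", strand = c("+", "+"),
    tx_start = c(1000L, 21200L), tx_end = c(21000L, 30000L),
    tss = c(1000L, 21200L)
  )
  a <- annotate_genes(sites_at(20900), g) |> annotate_tss(g)
  expect_true(a$in_gene)
  expect_equal(a$gene_name, "host")
  expect_equal(a$tss_gene_name, "neighbor")
  expect_equal(a$tss_distance, -300L)
})

test_that("gene and TSS annotation match brute-force nearest scans on a random gene set", {
  set.seed(51)
  genes <- tibble::tibble(
    gene_name = sprintf("g%03d", 1:60),
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    strand = sample(c("+", "-"), 60, replace = TRUE),
    tx_start = as.integer(sample(1:80000, 60))
  )
  genes$tx_end <- genes$tx_start + as.integer(sample(500:8000, 60,
                                                     replace = TRUE))
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  sites <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                          position = as.integer(sample(1:90000, 80)))
  ann <- annotate_genes(sites, genes) |> annotate_tss(genes)
  for (i in seq_len(nrow(sites))) {
    want <- oracle_nearest_gene(sites$position[i], sites$chrom[i],
                                as.data.frame(genes))
    expect_equal(ann$in_gene[i], want$in_gene)
    expect_equal(ann$gene_name[i], as.character(want$name))
    if (!is.na(want$dist)) expect_equal(ann$gene_distance[i], want$dist)
    want_tss <- oracle_nearest_tss(sites$position[i], sites$chrom[i],
                                   as.data.frame(genes))
    expect_equal(ann$tss_gene_name[i], as.character(want_tss$name))
    expect_equal(ann$tss_distance[i], want_tss$dist)
  }
})

test_that("feature annotation reports containment, boundary distances and name-order ties", {
  feats <- tibble::tibble(
    feature_name = c("alpha", "beta"),
    chrom = "chr1",
    start = c(1000L, 3000L), end = c(2000L, 4000L)
  )
  a <- annotate_features(sites_at(1500), feats)
  expect_true(a$feature_within)
  expect_equal(a$feature_distance, 0L)
  a <- annotate_features(sites_at(2001), feats)
  expect_false(a$feature_within)
  expect_equal(a$feature_distance, 1L)
  # equidistant between alpha's end and beta's start: name order wins
  a <- annotate_features(sites_at(2500), feats)
  expect_equal(a$nearest_feature, "alpha")
  # no cap on feature distance
  a <- annotate_features(sites_at(90000), feats)
  expect_equal(a$nearest_feature, "beta")
  expect_equal(a$feature_distance, 86000L)
})

test_that("chisq_gof reproduces hand-computed statistics and agrees with the reference implementation", {
  r <- chisq_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- chisq_gof(c(10, 90), c(0.5, 0.5))
  expect_equal(r$statistic, 64)   # 2 * 40^2 / 50
  expect_equal(r$df, 1L)

  r <- chisq_gof(c(30, 20, 50), c(0.3, 0.2, 0.5))
  expect_equal(r$statistic, 0)

  set.seed(52)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    obs <- sample(1:200, k, replace = TRUE)
    props <- prop.table(runif(k, 0.05, 1))
    mine <- chisq_gof(obs, props)
    ref <- suppressWarnings(stats::chisq.test(obs, p = props))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(sum(mine$table$expected), sum(obs))
  }

  expect_error(chisq_gof(c(5, 5), c(0.4, 0.5)), "sum to 1")
  expect_error(chisq_gof(c(5, 5, 0), c(0.5, 0.5, 0)), NA)
  expect_error(chisq_gof(c(5, 5, 1), c(0.5, 0.5, 0)), "merge")
})

test_that("summarize_integration partitions sites into categories and tests against controls", {
  g <- grid_genes()
  set.seed(53)
  # lentiviral-like profile: most sites inside genes
  obs_pos <- c(sample(4000:6000, 70, replace = TRUE),
               sample(6500:8500, 20, replace = TRUE),
               sample(20000:40000, 10, replace = TRUE))
  obs <- annotate_genes(sites_at(obs_pos), g)
  # uniform random control on a mostly gene-free span
  rnd <- annotate_genes(sites_at(sample(1:50000, 400, replace = TRUE)), g)
  res <- summarize_integration(obs, rnd)
  expect_equal(res$summary$n_unique, 100L)
  expect_equal(res$summary$pct_in_genes, 100 * sum(obs$in_gene) / 100)
  # categories partition the site set
  expect_equal(sum(res$gene_test$table$observed), 100L)
  expect_gt(res$gene_test$statistic, 0)
  expect_lt(res$gene_test$p_value, 0.05)
  # identical proportions give statistic 0
  res0 <- summarize_integration(obs, obs)
  expect_equal(res0$gene_test$statistic, 0)
  # empty random set: warning, no tests
  expect_warning(res_na <- summarize_integration(obs, obs[0, ]), "empty")
  expect_null(res_na$gene_test)
})
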