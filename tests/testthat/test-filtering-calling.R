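test_that("config defaults are the recommended thresholds", {
  cfg <- ris_config()
  expect_equal(cfg$min_query_len, 30L)
  expect_equal(cfg$n_run_limit, 3L)
  expect_equal(cfg$min_score, 60)
  expect_equal(cfg$min_identity_initial, 92)
  expect_equal(cfg$max_qstart_offset, 3L)
  expect_equal(cfg$top_k, 5L)
  expect_equal(cfg$ratio_hi, 95)
  expect_equal(cfg$ratio_lo, 90)
  expect_equal(cfg$ratio_score_boundary, 100)
  expect_equal(cfg$min_best_identity, 95)
  expect_equal(cfg$cluster_halfwidth, 5L)
  expect_equal(cfg$gene_max_dist, 5000L)
  expect_equal(cfg$random_n_default, 100000L)
  expect_equal(cfg$random_len_bounds, c(30L, 1000L))
  expect_equal(cfg$random_n_bounds, c(1L, 100000L))
  expect_error(ris_config(min_score = -1), "positive")
})

test_that("initial_filter enforces the score, identity and query-start boundaries exactly", {
  aln <- dplyr::bind_rows(
    make_aln(query_id = "score_low", score = 59.9),
    make_aln(query_id = "boundary_ok", score = 60,
             percent_identity = 92, q_start = 4L),
    make_aln(query_id = "identity_low", score = 100,
             percent_identity = 91.9),
    make_aln(query_id = "offset_high", q_start = 5L)
  )
  kept <- initial_filter(aln)
  expect_equal(kept$query_id, "boundary_ok")
})

test_that("top_alignments keeps the 5 best per query with deterministic tie-breaks", {
  set.seed(41)
  aln <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_aln(query_id = "q1", score = 60 + i, t_start = 1000L + 50L * i,
             t_end = 1039L + 50L * i)
  }))
  top <- top_alignments(aln)
  expect_equal(nrow(top), 5L)
  expect_equal(sort(top$score, decreasing = TRUE), 70:66)

  # two records tied at rank 5: the (target_id, t_start)-lesser one stays
  tie <- dplyr::bind_rows(
    lapply(1:4, function(i) make_aln(query_id = "q2", score = 90 - i)),
    make_aln(query_id = "q2", score = 70, target_id = "chr2", t_start = 500L),
    make_aln(query_id = "q2", score = 70, target_id = "chr1", t_start = 900L)
  )
  top2 <- top_alignments(tie)
  expect_equal(nrow(top2), 5L)
  last <- top2[top2$score == 70, ]
  expect_equal(last$target_id, "chr1")
  expect_equal(last$t_start, 900L)

  two <- dplyr::bind_rows(make_aln(query_id = "q3"),
                          make_aln(query_id = "q3", score = 70))
  expect_equal(nrow(top_alignments(two)), 2L)
})

test_that("classify_queries applies the vector, second-best-ratio and identity filters in order", {
  classify1 <- function(...) {
    cls <- classify_queries(dplyr::bind_rows(...), vector_name = "vec")
    if (nrow(cls$candidates)) cls$candidates else cls$rejected
  }
  # best 200, second 191: 95.5 % > 95 % -> ambiguous
  r <- classify1(make_aln(score = 200), make_aln(score = 191, t_start = 5000L))
  expect_equal(r$reason, "ambiguous_second_best")
  # best 200, second 190: exactly 95 % is not strictly greater -> accepted
  r <- classify1(make_aln(score = 200), make_aln(score = 190, t_start = 5000L))
  expect_equal(r$chrom, "chr1")
  # best 80 (< 100 boundary), second 73: 91.25 % > 90 % -> ambiguous
  r <- classify1(make_aln(score = 80), make_aln(score = 73, t_start = 5000L))
  expect_equal(r$reason, "ambiguous_second_best")
  # best 80, second 72: exactly 90 % -> accepted
  r <- classify1(make_aln(score = 80), make_aln(score = 72, t_start = 5000L))
  expect_equal(r$position, 1000L)
  # best hit to the vector
  r <- classify1(make_aln(target_id = "vec", score = 200), make_aln(score = 90))
  expect_equal(r$reason, "vector_best")
  # best identity below 95
  r <- classify1(make_aln(percent_identity = 94.9))
  expect_equal(r$reason, "low_best_identity")
  # minus-strand candidate: position is t_start (the junction side)
  r <- classify1(make_aln(t_start = 1039L, t_end = 1000L))
  expect_equal(r$strand, "-")
  expect_equal(r$position, 1039L)
  expect_equal(r$far_end, 1000L)
})

test_that("queries with no retained alignment are reported as no_passing_alignment", {
  cls <- classify_queries(make_aln(query_id = "good"),
                          query_ids = c("good", "lost"))
  expect_equal(cls$candidates$read_id, "good")
  expect_equal(cls$rejected,
               tibble::tibble(read_id = "lost",
                              reason = "no_passing_alignment"))
})

test_that("call_unique_ris clusters hand-checked cases", {
  # (1000,80),(1000,60),(1003,70): one site at 1000, one repeat + one in-range
  cands <- make_candidates(pos = c(1000, 1000, 1003), score = c(80, 60, 70),
                           far_end = c(1040, 1040, 1043))
  u <- call_unique_ris(cands)
  expect_equal(nrow(u), 1L)
  expect_equal(u$position, 1000L)
  expect_equal(u$frequency, 3L)
  expect_equal(u$span_count, 2L)
  labels <- sort(u$members[[1]]$label)
  expect_equal(labels, c("in_range_ris", "repeat_ris", "unique"))

  # single candidate
  u1 <- call_unique_ris(make_candidates(1000, 80))
  expect_equal(c(u1$frequency, u1$span_count), c(1L, 1L))

  # 1000 and 1006 with equal scores: distance 6 > 5, two sites
  u2 <- call_unique_ris(make_candidates(c(1000, 1006), c(80, 80)))
  expect_equal(nrow(u2), 2L)

  # span counting: far ends 1040,1040,1051,1062 -> span 3
  u3 <- call_unique_ris(make_candidates(rep(1000, 4), c(90, 80, 70, 60),
                                        far_end = c(1040, 1040, 1051, 1062)))
  expect_equal(u3$frequency, 4L)
  expect_equal(u3$span_count, 3L)

  # opposite strands at the same coordinate remain distinct sites
  both <- dplyr::bind_rows(make_candidates(1000, 80, strand = "+"),
                           make_candidates(1000, 80, strand = "-",
                                           read_id = "r_minus"))
  expect_equal(nrow(call_unique_ris(both)), 2L)
})

test_that("clustering matches the brute-force oracle and is order-independent on fuzzed candidates", {
  set.seed(42)
  cfg <- ris_config()
  for (i in 1:30) {
    n <- sample(1:50, 1)
    cands <- tibble::tibble(
      read_id = sprintf("r%03d", 1:n),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      position = as.integer(sample(1000:1040, n, replace = TRUE)),
      score = as.numeric(sample(60:100, n, replace = TRUE)),
      percent_identity = 100
    )
    cands$far_end <- cands$position + sample(30:45, n, replace = TRUE)
    u <- call_unique_ris(cands, cfg)
    want <- oracle_cluster(as.data.frame(cands), cfg$cluster_halfwidth)
    expect_equal(u$position, want$position)
    expect_equal(u$frequency, want$frequency)
    expect_equal(u$span_count, want$span_count)
    expect_equal(u$score, want$score)

    # conservation and separation invariants
    expect_equal(sum(u$frequency), n)
    sep <- u |>
      dplyr::group_by(chrom, strand) |>
      dplyr::summarise(ok = all(diff(sort(position)) > cfg$cluster_halfwidth),
                       .groups = "drop")
    expect_true(all(sep$ok))
    # exactly one member labelled unique per site
    expect_true(all(vapply(u$members, function(m) sum(m$label == "unique"),
                           integer(1)) == 1L))

    # input order does not matter
    shuffled <- cands[sample(n), ]
    expect_identical(call_unique_ris(shuffled, cfg), u)
  }
})

test_that("tightening score or identity thresholds only shrinks the surviving set", {
  set.seed(43)
  aln <- dplyr::bind_rows(lapply(1:80, function(i) {
    make_aln(query_id = sprintf("q%02d", i),
             score = runif(1, 40, 120),
             percent_identity = runif(1, 85, 100),
             q_start = sample(1:6, 1))
  }))
  base <- initial_filter(aln, ris_config())
  for (ms in c(60, 70, 90)) {
    for (mi in c(92, 95, 98)) {
      tight <- initial_filter(aln, ris_config(min_score = ms,
                                              min_identity_initial = mi))
      expect_true(all(tight$query_id %in% base$query_id))
      expect_lte(nrow(tight), nrow(base))
    }
  }
})
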