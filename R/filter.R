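#' Initial alignment filter
#'
#' Removes alignments that can never support a confident integration-site
#' call: score below `min_score` (default 60), percent identity below
#' `min_identity_initial` (default 92), or an alignment that starts more
#' than `max_qstart_offset` (default 3) bp from the query start
#' (`q_start - 1 > max_qstart_offset`). The query start matters because
#' the first query base is the LTR-proximal junction base that defines the
#' integration coordinate; an alignment that skips it does not anchor the
#' junction.
#'
#' @param alignments A blast8-schema tibble.
#' @param config A [ris_config()].
#' @return The surviving subset, original order preserved.
#' @export
initial_filter <- function(alignments, config = ris_config()) {
  config <- as_ris_config(config)
  filter(alignments,
         .data$score >= config$min_score,
         .data$percent_identity >= config$min_identity_initial,
         .data$q_start - 1L <= config$max_qstart_offset)
}

#' Retain the best-scoring alignments per query
#'
#' For each query, sorts alignments by descending score (ties broken by
#' target then target start, ascending, for determinism) and keeps at most
#' `top_k` (default 5).
#'
#' @inheritParams initial_filter
#' @return A tibble sorted within query by rank, at most `top_k` rows per
#'   `query_id`.
#' @export
top_alignments <- function(alignments, config = ris_config()) {
  config <- as_ris_config(config)
  alignments |>
    arrange(.data$query_id, dplyr::desc(.data$score),
            .data$target_id, .data$t_start) |>
    group_by(.data$query_id) |>
    slice_head(n = config$top_k) |>
    ungroup()
}

# Classify one query's score-sorted top list into a candidate or a reason.
classify_one <- function(top, config, vector_name) {
  best <- top[1, ]
  if (!is.na(vector_name) && best$target_id == vector_name) {
    return(list(reason = "vector_best"))
  }
  if (nrow(top) >= 2L) {
    second <- top[2, ]
    threshold <- if (best$score >= config$ratio_score_boundary)
      config$ratio_hi else config$ratio_lo
    if (100 * second$score / best$score > threshold) {
      return(list(reason = "ambiguous_second_best"))
    }
  }
  if (best$percent_identity < config$min_best_identity) {
    return(list(reason = "low_best_identity"))
  }
  list(candidate = tibble(
    read_id = best$query_id, chrom = best$target_id,
    strand = alignment_strand(best$t_start, best$t_end),
    position = best$t_start, far_end = best$t_end,
    score = best$score, percent_identity = best$percent_identity
  ))
}

#' Classify queries into candidate integration sites
#'
#' Applies the ambiguity filters, in order, to each query's retained
#' top-scoring alignment list: (1) the best alignment is to the vector
#' sequence (`vector_best`); (2) the second-best score exceeds 95 % of the
#' best score -- relaxed to 90 % when the best score is below 100
#' (`ambiguous_second_best`); (3) the best alignment's percent identity is
#' below 95 % (`low_best_identity`). Queries passing all three are assumed
#' to integrate at their best alignment: the candidate position is the
#' target coordinate paired with the query start (`t_start`, on either
#' strand) and the far end is `t_end`, the distal shear-side coordinate.
#'
#' @param top A tibble from [top_alignments()].
#' @param config A [ris_config()].
#' @param vector_name Target name of the vector sequence, or `NA`.
#' @param query_ids Optional character vector of all query ids entering
#'   alignment; queries with no retained alignment are reported with reason
#'   `no_passing_alignment`.
#' @return A list with `candidates` (tibble: `read_id`, `chrom`, `strand`,
#'   `position`, `far_end`, `score`, `percent_identity`) and `rejected`
#'   (tibble: `read_id`, `reason`).
#' @export
classify_queries <- function(top, config = ris_config(), vector_name = NA,
                             query_ids = NULL) {
  config <- as_ris_config(config)
  cands <- list()
  rej <- list()
  for (grp in split(top, factor(top$query_id, levels = unique(top$query_id)))) {
    res <- classify_one(grp, config, vector_name)
    if (is.null(res$candidate)) {
      rej[[length(rej) + 1L]] <- tibble(read_id = grp$query_id[1],
                                        reason = res$reason)
    } else {
      cands[[length(cands) + 1L]] <- res$candidate
    }
  }
  rejected <- if (length(rej)) bind_rows(rej) else empty_filter_reasons()
  if (!is.null(query_ids)) {
    missing <- setdiff(query_ids, unique(top$query_id))
    if (length(missing)) {
      rejected <- bind_rows(rejected,
                            tibble(read_id = missing,
                                   reason = "no_passing_alignment"))
    }
  }
  list(candidates = if (length(cands)) bind_rows(cands) else empty_candidates(),
       rejected = rejected)
}

#' Cluster candidate sites into unique integration sites
#'
#' Candidates within +/- `cluster_halfwidth` bp (default 5, a 10 bp
#' window) on the same chromosome and strand are assumed to represent the
#' same integration event -- repeated recovery arises from PCR
#' amplification, clonal expansion, or sequencing errors that shift the
#' mapped junction by a few bp. Clustering is greedy: the highest-scoring
#' unassigned candidate (ties: lowest position, then read id) becomes a
#' unique RIS and absorbs every unassigned candidate within the window.
#' Absorbed candidates at the identical coordinate are labelled
#' `repeat_ris`; others `in_range_ris`.
#'
#' Each unique site reports its `frequency` (total reads in the cluster)
#' and `span_count` (distinct far-end coordinates, i.e. distinct shear
#' points). A high frequency with a single span suggests PCR duplication;
#' many distinct spans indicate genuine clonal abundance.
#'
#' @param candidates A tibble from [classify_queries()].
#' @param config A [ris_config()].
#' @return A tibble of unique sites: `ris_id`, `chrom`, `strand`,
#'   `position`, `score` (the cluster's best), `frequency`, `span_count`,
#'   and a nested `members` list-column (`read_id`, `position`, `far_end`,
#'   `score`, `label`). Sorted by chromosome, position, strand.
#' @export
call_unique_ris <- function(candidates, config = ris_config()) {
  config <- as_ris_config(config)
  if (!nrow(candidates)) {
    return(tibble(ris_id = character(), chrom = character(),
                  strand = character(), position = integer(),
                  score = double(), frequency = integer(),
                  span_count = integer(), members = list()))
  }
  out <- list()
  for (grp in split(candidates, paste0(candidates$chrom, "\r", candidates$strand))) {
    grp <- arrange(grp, dplyr::desc(.data$score), .data$position, .data$read_id)
    assigned <- rep(FALSE, nrow(grp))
    while (!all(assigned)) {
      u <- which(!assigned)[1]
      in_win <- !assigned &
        abs(grp$position - grp$position[u]) <= config$cluster_halfwidth
      members <- grp[in_win, ] |>
        mutate(label = dplyr::case_when(
          dplyr::row_number() == 1L ~ "unique",
          .data$position == grp$position[u] ~ "repeat_ris",
          TRUE ~ "in_range_ris"
        )) |>
        select("read_id", "position", "far_end", "score", "label")
      assigned[in_win] <- TRUE
      out[[length(out) + 1L]] <- tibble(
        chrom = grp$chrom[u], strand = grp$strand[u],
        position = grp$position[u], score = grp$score[u],
        frequency = nrow(members),
        span_count = dplyr::n_distinct(members$far_end),
        members = list(members)
      )
    }
  }
  bind_rows(out) |>
    arrange(.data$chrom, .data$position, .data$strand) |>
    mutate(ris_id = sprintf("RIS_%04d", row_number()), .before = 1)
}

#' Unnest the per-read members of unique integration sites
#'
#' @param unique_ris Output of [call_unique_ris()].
#' @return A read-level tibble with each member's `read_id`, `position`,
#'   `far_end`, `score` and `label` joined to its `ris_id`.
#' @export
ris_members <- function(unique_ris) {
  unique_ris |>
    select("ris_id", "chrom", "strand", "members") |>
    tidyr::unnest("members")
}
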