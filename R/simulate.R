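#' Simulate an integration-site sequencing dataset with known truth
#'
#' Generates a toy genome, a grid of gene models, a planted set of
#' proviral integration sites, and the LTR-junction reads an LTR-primed
#' (LAM-PCR-like) library would produce from them: each read is
#' `LTR + genomic fragment (+ linker cassette)`, strand-aware from the
#' junction base, with per-site PCR duplicates, shear-varied fragment end
#' points, per-base substitution errors and ambiguous-base (`N`)
#' injections. The truth table records each planted site's coordinate,
#' orientation, read count (expected cluster frequency) and number of
#' distinct fragment end points (expected span count).
#'
#' The genome is drawn from a seeded uniform base generator and each
#' planted site's 40 bp junction flank is verified to occur exactly once
#' in the genome (both strands), so that with zero error every read maps
#' unambiguously and recovery of the truth is exact. Reads deliberately
#' planted in repeats, vector-internal reads or LTR-less reads can be
#' added via `n_vector_reads` / `n_noise_reads` to exercise the filters.
#'
#' @param genome_length Total genome length in bp (default 60000), split
#'   evenly over `n_chromosomes` (default 2).
#' @param n_integrations Number of planted proviruses (default 40).
#' @param reads_per_site Mean reads per site; counts are
#'   `1 + Poisson(reads_per_site - 1)` (default 4).
#' @param shear_spread Fragment end points vary uniformly over
#'   `0..shear_spread` bp beyond the base fragment length (default 12).
#' @param frag_len Base genomic fragment length in bp (default 40).
#' @param error_rate Per-base substitution probability (default 0.003).
#' @param n_rate Per-base probability of replacement by `N` (default 0).
#' @param gene_density Genes per kb (default 1/3; genes are placed on a
#'   regular grid, width half the grid step, alternating strand).
#' @param ltr_seq,lc_seq LTR and linker-cassette sequences appended to
#'   every read (set `lc_seq = NULL` for libraries without a linker).
#' @param n_vector_reads Reads of LTR + vector-internal sequence
#'   (default 0); these should be removed by the vector-best filter.
#' @param n_noise_reads Reads of random sequence without an LTR
#'   (default 0); these should be removed at trimming.
#' @param seed Integer seed (default 1).
#' @return A list of class `ris_simulation` with `genome`, `vector`,
#'   `genes`, `reads`, `truth` tibbles plus `ltr`, `lc` and the call
#'   parameters in `params`.
#' @export
simulate_dataset <- function(genome_length = 60000L,
                             n_chromosomes = 2L,
                             n_integrations = 40L,
                             reads_per_site = 4,
                             shear_spread = 12L,
                             frag_len = 40L,
                             error_rate = 0.003,
                             n_rate = 0,
                             gene_density = 1 / 3,
                             ltr_seq = "TGTGGAAAATCTCTAGCAGT",
                             lc_seq = "GATCCCTAACGCGTTGGATG",
                             n_vector_reads = 0L,
                             n_noise_reads = 0L,
                             seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1, n_rate >= 0, n_rate <= 1)
  chrom_len <- genome_length %/% n_chromosomes
  margin <- frag_len + shear_spread + 10L
  min_gap <- 2L * (frag_len + shear_spread) + 20L
  if (n_integrations * min_gap > n_chromosomes * (chrom_len - 2L * margin)) {
    abort("genome too small to host the requested integrations without overlap")
  }
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rand_seq <- function(len) paste(sample(bases, len, replace = TRUE),
                                    collapse = "")
    chroms <- stats::setNames(
      vapply(seq_len(n_chromosomes), function(i) rand_seq(chrom_len),
             character(1)),
      sprintf("chr%d", seq_len(n_chromosomes))
    )
    vector_seq <- rand_seq(1000L)

    # Planted sites: evenly spread slots with jitter, so fragments never
    # overlap and every flank is genome-unique by construction check below.
    per_chrom <- diff(round(seq(0, n_integrations,
                                length.out = n_chromosomes + 1)))
    truth_rows <- list()
    idx <- 0L
    for (ci in seq_len(n_chromosomes)) {
      k <- per_chrom[ci]
      if (!k) next
      slots <- round(seq(margin, chrom_len - margin, length.out = k + 2L))
      slots <- slots[2:(k + 1L)]
      for (p in slots) {
        idx <- idx + 1L
        pos <- as.integer(p + sample(-10:10, 1L))
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        truth_rows[[idx]] <- tibble(
          site_id = sprintf("site_%03d", idx),
          chrom = names(chroms)[ci], position = pos, strand = strand
        )
      }
    }
    truth <- bind_rows(truth_rows)

    # Verify each planted 40 bp flank is unique in the genome (both strands);
    # collisions in a uniform-random genome are vanishingly rare but checked.
    count_hits <- function(pat) {
      sum(vapply(chroms, function(s) {
        length(gregexpr(pat, s, fixed = TRUE)[[1]][
          gregexpr(pat, s, fixed = TRUE)[[1]] > 0]) +
          length(gregexpr(revcomp(pat), s, fixed = TRUE)[[1]][
            gregexpr(revcomp(pat), s, fixed = TRUE)[[1]] > 0])
      }, numeric(1)))
    }
    flank_of <- function(chrom, pos, strand) {
      if (strand == "+") substr(chroms[[chrom]], pos, pos + frag_len - 1L)
      else revcomp(substr(chroms[[chrom]], pos - frag_len + 1L, pos))
    }
    flanks <- purrr::pmap_chr(truth[c("chrom", "position", "strand")],
                              function(chrom, position, strand)
                                flank_of(chrom, position, strand))
    if (any(vapply(flanks, count_hits, numeric(1)) != 1)) {
      abort("a planted flank is not genome-unique; choose another seed")
    }

    corrupt <- function(s) {
      if (error_rate == 0 && n_rate == 0) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      sub <- stats::runif(length(ch)) < error_rate
      if (any(sub)) {
        ch[sub] <- vapply(ch[sub], function(b) sample(setdiff(bases, b), 1L),
                          character(1))
      }
      amb <- stats::runif(length(ch)) < n_rate
      ch[amb] <- "N"
      paste(ch, collapse = "")
    }

    read_rows <- list()
    rid <- 0L
    freq <- integer(nrow(truth))
    span <- integer(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      n_reads <- 1L + stats::rpois(1L, max(reads_per_site - 1, 0))
      ends <- sample(0:shear_spread, n_reads, replace = TRUE)
      freq[i] <- n_reads
      span[i] <- dplyr::n_distinct(ends)
      for (e in ends) {
        rid <- rid + 1L
        flen <- frag_len + e
        frag <- if (truth$strand[i] == "+") {
          substr(chroms[[truth$chrom[i]]], truth$position[i],
                 truth$position[i] + flen - 1L)
        } else {
          revcomp(substr(chroms[[truth$chrom[i]]],
                         truth$position[i] - flen + 1L, truth$position[i]))
        }
        seq <- paste0(ltr_seq, frag, lc_seq %||% "")
        read_rows[[rid]] <- tibble(
          read_id = sprintf("read_%05d", rid),
          sequence = corrupt(seq),
          site_id = truth$site_id[i]
        )
      }
    }
    for (j in seq_len(n_vector_reads)) {
      rid <- rid + 1L
      st <- sample.int(1000L - frag_len, 1L)
      read_rows[[rid]] <- tibble(
        read_id = sprintf("read_%05d", rid),
        sequence = corrupt(paste0(ltr_seq,
                                  substr(vector_seq, st, st + frag_len - 1L))),
        site_id = "vector"
      )
    }
    for (j in seq_len(n_noise_reads)) {
      rid <- rid + 1L
      read_rows[[rid]] <- tibble(
        read_id = sprintf("read_%05d", rid),
        sequence = rand_seq(frag_len + nchar(ltr_seq)),
        site_id = "noise"
      )
    }
    truth$frequency <- freq
    truth$span_count <- span

    # Gene grid: fixed step from density, width half the step, alternating
    # strand, so in-gene fractions have closed-form expectations.
    step <- max(200L, as.integer(round(1000 / gene_density)))
    width <- step %/% 2L
    gene_rows <- list()
    gi <- 0L
    for (ci in seq_len(n_chromosomes)) {
      starts <- seq(1L, chrom_len - width, by = step)
      for (s in starts) {
        gi <- gi + 1L
        gene_rows[[gi]] <- tibble(
          gene_name = sprintf("gene_%03d", gi),
          chrom = names(chroms)[ci],
          strand = if (gi %% 2L) "+" else "-",
          tx_start = as.integer(s),
          tx_end = as.integer(s + width - 1L)
        )
      }
    }
    genes <- bind_rows(gene_rows) |>
      mutate(tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end))

    structure(list(
      genome = tibble(read_id = names(chroms), sequence = unname(chroms)),
      vector = tibble(read_id = "vector", sequence = vector_seq),
      genes = genes,
      reads = bind_rows(read_rows),
      truth = truth,
      ltr = ltr_seq, lc = lc_seq,
      params = list(genome_length = genome_length,
                    n_chromosomes = n_chromosomes,
                    n_integrations = n_integrations,
                    reads_per_site = reads_per_site,
                    shear_spread = shear_spread, frag_len = frag_len,
                    error_rate = error_rate, n_rate = n_rate,
                    gene_density = gene_density, seed = seed)
    ), class = "ris_simulation")
  })
}
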