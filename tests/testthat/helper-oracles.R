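# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and string scans only.

# Line-by-line FASTA parser.
oracle_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      ids <- c(ids, sub("\\s.*$", "", sub("^>", "", ln)))
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else if (!is.null(cur)) {
      seqs[cur] <- paste0(seqs[cur], toupper(trimws(ln)))
    }
  }
  data.frame(read_id = ids, sequence = seqs)
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# All 0-based offsets just past each occurrence of `pat` in `s`.
oracle_all_occurrences <- function(s, pat) {
  out <- integer(0)
  for (i in seq_len(nchar(s) - nchar(pat) + 1)) {
    if (substr(s, i, i + nchar(pat) - 1) == pat) {
      out <- c(out, i + nchar(pat) - 1L)
    }
  }
  out
}

# Exhaustive all-positions Hamming scan: every full-length placement of
# `query` on both strands of every reference at identity >= min_identity.
oracle_hamming_scan <- function(query_id, query, refs_named, min_identity = 90) {
  len <- nchar(query)
  rows <- list()
  for (tgt in names(refs_named)) {
    tseq <- refs_named[[tgt]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") query else oracle_revcomp(query)
      sv <- strsplit(s, "")[[1]]
      for (st in seq_len(max(nchar(tseq) - len + 1, 0))) {
        fv <- strsplit(substr(tseq, st, st + len - 1), "")[[1]]
        matches <- sum(sv == fv & sv != "N")
        identity <- 100 * matches / len
        if (identity < min_identity) next
        rows[[length(rows) + 1]] <- data.frame(
          query_id = query_id, target_id = tgt, strand = strand,
          start = st, identity = identity,
          score = 2 * matches - 6 * (len - matches)
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), target_id = character(),
                      strand = character(), start = integer(),
                      identity = numeric(), score = numeric()))
  }
  do.call(rbind, rows)
}

# Exhaustive greedy clustering: repeatedly pick the globally best-scoring
# unassigned candidate (ties by position then read_id) and absorb the window.
oracle_cluster <- function(df, halfwidth = 5) {
  df <- df[order(-df$score, df$position, df$read_id), ]
  out <- list()
  assigned <- rep(FALSE, nrow(df))
  key <- paste(df$chrom, df$strand)
  while (!all(assigned)) {
    u <- which(!assigned)[1]
    in_win <- !assigned & key == key[u] &
      abs(df$position - df$position[u]) <= halfwidth
    out[[length(out) + 1]] <- data.frame(
      chrom = df$chrom[u], strand = df$strand[u],
      position = df$position[u], score = df$score[u],
      frequency = sum(in_win),
      span_count = length(unique(df$far_end[in_win]))
    )
    assigned[in_win] <- TRUE
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$position, res$strand), ]
}

# Nearest-interval scans for annotation cross-checks.
oracle_nearest_gene <- function(pos, chrom, genes, max_dist = 5000) {
  g <- genes[genes$chrom == chrom, ]
  if (!nrow(g)) return(list(in_gene = FALSE, name = NA, dist = NA))
  inside <- which(g$tx_start <= pos & pos <= g$tx_end)
  if (length(inside)) {
    spans <- g$tx_end[inside] - g$tx_start[inside]
    pick <- inside[order(spans, g$gene_name[inside])][1]
    return(list(in_gene = TRUE, name = g$gene_name[pick], dist = 0))
  }
  d <- ifelse(pos < g$tx_start, g$tx_start - pos, pos - g$tx_end)
  pick <- order(d, g$gene_name)[1]
  if (d[pick] > max_dist) return(list(in_gene = FALSE, name = NA, dist = NA))
  list(in_gene = FALSE, name = g$gene_name[pick], dist = d[pick])
}

oracle_nearest_tss <- function(pos, chrom, genes) {
  g <- genes[genes$chrom == chrom, ]
  if (!nrow(g)) return(list(name = NA, dist = NA))
  d <- abs(pos - g$tss)
  pick <- order(d, g$gene_name)[1]
  signed <- if (g$strand[pick] == "+") pos - g$tss[pick] else g$tss[pick] - pos
  list(name = g$gene_name[pick], dist = signed)
}

# Small fixture builders -----------------------------------------------------

make_aln <- function(query_id = "q1", target_id = "chr1",
                     percent_identity = 100, aln_length = 40L,
                     mismatches = 0L, gap_openings = 0L,
                     q_start = 1L, q_end = 40L,
                     t_start = 1000L, t_end = 1039L,
                     e_value = 0, score = 80) {
  tibble::tibble(query_id = query_id, target_id = target_id,
                 percent_identity = percent_identity,
                 aln_length = as.integer(aln_length),
                 mismatches = as.integer(mismatches),
                 gap_openings = as.integer(gap_openings),
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 t_start = as.integer(t_start), t_end = as.integer(t_end),
                 e_value = e_value, score = score)
}

make_candidates <- function(pos, score, far_end = pos + 39L,
                            chrom = "chr1", strand = "+",
                            read_id = sprintf("r%03d", seq_along(pos))) {
  tibble::tibble(read_id = read_id, chrom = chrom, strand = strand,
                 position = as.integer(pos), far_end = as.integer(far_end),
                 score = as.numeric(score), percent_identity = 100)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
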