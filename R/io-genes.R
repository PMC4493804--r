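#' Read gene models from a genePred or refFlat file
#'
#' Both dialects store transcription bounds as 0-based half-open
#' coordinates; they are converted to the pipeline's native 1-based
#' inclusive convention at this boundary. The transcription start site (TSS)
#' is the strand-dependent 5' end: `tx_start` on plus-strand genes,
#' `tx_end` on minus-strand genes.
#'
#' genePred columns: name, chrom, strand, txStart, txEnd, ... refFlat
#' prefixes these with a geneName column, which is used as the gene name.
#'
#' @param path Path to the annotation file (tab-separated, no header).
#' @param dialect `"refFlat"` (default) or `"genePred"`.
#' @return A tibble with columns `gene_name`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss` (all coordinates 1-based inclusive).
#' @export
read_genes <- function(path, dialect = c("refFlat", "genePred")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("gene file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble(gene_name = character(), chrom = character(),
                  strand = character(), tx_start = integer(),
                  tx_end = integer(), tss = integer())
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (dialect == "refFlat") 6L else 5L
  if (any(lengths(fields) < min_cols)) {
    abort(sprintf("line %d of %s has fewer than %d columns for dialect %s",
                  which(lengths(fields) < min_cols)[1], path, min_cols, dialect))
  }
  off <- if (dialect == "refFlat") 1L else 0L
  m <- t(vapply(fields, function(f) f[seq_len(5L) + off], character(5)))
  gene_name <- if (dialect == "refFlat") {
    vapply(fields, `[`, character(1), 1L)
  } else {
    m[, 1]
  }
  strand <- m[, 3]
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand symbol %s in %s",
                  strand[!strand %in% c("+", "-")][1], path))
  }
  tx_start <- as.integer(m[, 4]) + 1L   # 0-based half-open -> 1-based inclusive
  tx_end <- as.integer(m[, 5])
  tibble(
    gene_name = gene_name, chrom = m[, 2], strand = strand,
    tx_start = tx_start, tx_end = tx_end,
    tss = ifelse(strand == "+", tx_start, tx_end)
  )
}

#' Write gene models as refFlat
#'
#' Converts 1-based inclusive transcription bounds back to the dialect's
#' 0-based half-open coordinates. The CDS is written as empty
#' (cdsStart = cdsEnd = txEnd) and a single exon spanning the transcript.
#'
#' @param genes A tibble as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(genes, path) {
  s0 <- genes$tx_start - 1L
  e0 <- genes$tx_end
  lines <- paste(genes$gene_name, genes$gene_name, genes$chrom, genes$strand,
                 s0, e0, e0, e0, 1L,
                 paste0(s0, ","), paste0(e0, ","), sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read genomic features from a BED file
#'
#' Accepts BED3+ (chrom, start, end, optionally name). BED's 0-based
#' half-open intervals are converted to 1-based inclusive coordinates.
#' Features without a name column are auto-named `feature_<n>`.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `feature_name`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_features_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(feature_name = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    abort(sprintf("line %d of %s has fewer than 3 BED columns",
                  which(lengths(fields) < 3L)[1], path))
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- as.integer(vapply(fields, `[`, character(1), 2L))
  end0 <- as.integer(vapply(fields, `[`, character(1), 3L))
  if (any(start0 >= end0)) {
    abort(sprintf("line %d of %s: BED start must be < end",
                  which(start0 >= end0)[1], path))
  }
  name <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4L && nzchar(f[4])) f[4] else sprintf("feature_%d", i)
  }, character(1))
  tibble(feature_name = name, chrom = chrom,
         start = start0 + 1L, end = end0)
}
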