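# Assembly of scoreable CpGs into regions by proximity chaining, and
# region-level pooled methylation.

#' Assemble CpG regions by proximity chaining
#'
#' Single-linkage chaining along each chromosome: adjacent scoreable CpGs
#' whose positions differ by at most \code{max_gap} bp are placed in the
#' same region, and a new region starts whenever the gap exceeds
#' \code{max_gap}. Chaining is transitive, so a region can span much more
#' than \code{max_gap}; singleton regions are allowed. Every locus in the
#' matrix belongs to exactly one region.
#'
#' @param matrix A \code{methylome_matrix} (typically after
#'   [filter_scoreable()]).
#' @param max_gap Maximum gap in bp between consecutive member CpGs
#'   (default 50; the gap is inclusive, i.e. exactly 50 bp still merges).
#' @param min_cpgs Minimum number of member CpGs for a region to be kept
#'   (default 1, i.e. singletons are kept).
#' @return A data frame of class \code{cpg_regions}, sorted by
#'   (chrom, start): \code{region_id} (\code{"chrom:start-end"}),
#'   \code{chrom}, \code{start}, \code{end}, \code{n_cpgs}, \code{width},
#'   plus a list column \code{members} of integer row indices into
#'   \code{matrix$loci}.
#' @examples
#' s1 <- methylome_sample("a", "control", rep("chr1", 4),
#'                        c(100, 140, 190, 260), c(9, 9, 9, 9), c(1, 1, 1, 1))
#' s2 <- methylome_sample("b", "treatment", rep("chr1", 4),
#'                        c(100, 140, 190, 260), c(1, 1, 1, 1), c(9, 9, 9, 9))
#' m <- filter_scoreable(intersect_common_loci(list(s1, s2)), quiet = TRUE)
#' assemble_regions(m, max_gap = 50)[, c("region_id", "n_cpgs")]
#' @export
assemble_regions <- function(matrix, max_gap = 50, min_cpgs = 1) {
  stopifnot(inherits(matrix, "methylome_matrix"))
  if (!is_count_scalar(max_gap)) stopf("max_gap must be a single integer >= 0")
  if (!is_count_scalar(min_cpgs) || min_cpgs < 1) {
    stopf("min_cpgs must be a single integer >= 1")
  }
  loci <- matrix$loci
  n <- nrow(loci)
  if (n == 0L) {
    df <- data.frame(region_id = character(), chrom = character(),
                     start = integer(), end = integer(), n_cpgs = integer(),
                     width = integer(), stringsAsFactors = FALSE)
    df$members <- list()
    class(df) <- c("cpg_regions", "data.frame")
    return(df)
  }
  o <- locus_order(loci$chrom, loci$pos)
  if (!identical(o, seq_len(n))) stopf("internal error: matrix loci are not sorted")
  new_chrom <- c(TRUE, loci$chrom[-1L] != loci$chrom[-n])
  gap <- c(0L, diff(loci$pos))
  breaks <- new_chrom | gap > max_gap
  region_idx <- cumsum(breaks)
  start <- tapply(loci$pos, region_idx, min)
  end <- tapply(loci$pos, region_idx, max)
  chrom <- loci$chrom[breaks]
  members <- split(seq_len(n), region_idx)
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end),
                   n_cpgs = as.integer(lengths(members)),
                   stringsAsFactors = FALSE)
  df$region_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df$width <- df$end - df$start + 1L
  df$members <- unname(members)
  df <- df[df$n_cpgs >= min_cpgs,
           c("region_id", "chrom", "start", "end", "n_cpgs", "width",
             "members")]
  rownames(df) <- NULL
  class(df) <- c("cpg_regions", "data.frame")
  df
}

#' Pool read counts over a region's member CpGs and a sample set
#'
#' Sums methylated and unmethylated counts over all member CpGs of one
#' region and all listed samples (coverage-weighted pooling: every read
#' counts once).
#'
#' @param region One row of a \code{cpg_regions} data frame.
#' @param matrix The \code{methylome_matrix} the regions were built from.
#' @param sample_ids Character vector of sample ids to pool (non-empty).
#' @return A named numeric vector \code{c(meth = ..., unmeth = ...)}.
#' @export
pool_region_counts <- function(region, matrix, sample_ids) {
  stopifnot(inherits(matrix, "methylome_matrix"))
  if (length(sample_ids) == 0L) stopf("sample_ids must be non-empty")
  j <- match(sample_ids, matrix$samples$sample_id)
  if (anyNA(j)) stopf("unknown sample id '%s'", sample_ids[is.na(j)][1L])
  idx <- region$members[[1L]]
  c(meth = sum(matrix$meth[idx, j, drop = FALSE]),
    unmeth = sum(matrix$unmeth[idx, j, drop = FALSE]))
}

#' Region methylation percentage from pooled counts
#'
#' @param pooled_meth,pooled_unmeth Pooled read counts; their sum must be
#'   positive.
#' @return \code{100 * meth / (meth + unmeth)}, in \[0, 100\].
#' @export
region_methylation <- function(pooled_meth, pooled_unmeth) {
  cov <- pooled_meth + pooled_unmeth
  if (any(cov <= 0)) stopf("zero pooled coverage: region methylation undefined")
  100 * pooled_meth / cov
}

#' Unweighted mean of per-CpG methylation percentages
#'
#' Sensitivity-analysis alternative to coverage-weighted pooling: the mean
#' over member CpGs of per-CpG percentages, each CpG first pooled across
#' the listed samples.
#'
#' @inheritParams pool_region_counts
#' @return A percentage in \[0, 100\].
#' @export
region_methylation_unweighted <- function(region, matrix, sample_ids) {
  stopifnot(inherits(matrix, "methylome_matrix"))
  if (length(sample_ids) == 0L) stopf("sample_ids must be non-empty")
  j <- match(sample_ids, matrix$samples$sample_id)
  if (anyNA(j)) stopf("unknown sample id '%s'", sample_ids[is.na(j)][1L])
  idx <- region$members[[1L]]
  m <- rowSums(matrix$meth[idx, j, drop = FALSE])
  u <- rowSums(matrix$unmeth[idx, j, drop = FALSE])
  mean(100 * m / (m + u))
}

#' Export regions as BED3
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention on write.
#'
#' @param regions A \code{cpg_regions} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed3 <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d", regions$chrom, regions$start - 1L,
                   regions$end)
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
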