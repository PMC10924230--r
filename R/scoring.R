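# Joint scoreability: intersect samples to common CpG loci and keep only
# loci whose read coverage exceeds the threshold in every sample.

#' Intersect samples to jointly covered CpG loci
#'
#' Builds a locus-by-sample count matrix holding exactly the CpG loci
#' present in every input sample; counts are copied unchanged. This is the
#' step before scoreability filtering: a coverage requirement "across all
#' samples" is only defined on loci all samples actually report.
#'
#' @param samples A list of \code{methylome_sample} objects (at least two).
#' @return An object of class \code{methylome_matrix}: a list with
#'   \itemize{
#'     \item \code{loci}: data frame (\code{chrom}, \code{pos}), strictly
#'       sorted by (chrom, pos);
#'     \item \code{meth}, \code{unmeth}: integer matrices, loci x samples;
#'     \item \code{samples}: data frame (\code{sample_id}, \code{group}).
#'   }
#' @export
intersect_common_loci <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stopf("need at least 2 samples, got %d", length(samples))
  }
  ok <- vapply(samples, inherits, TRUE, "methylome_sample")
  if (!all(ok)) stopf("all inputs must be methylome_sample objects")
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stopf("duplicate sample_id '%s'", ids[duplicated(ids)][1L])
  keys <- lapply(samples, function(s) paste(s$sites$chrom, s$sites$pos))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    stopf(paste0("no CpG locus is covered in every sample; check that the ",
                 "samples share a genome build and chromosome naming ",
                 "(e.g. 'chr1' vs '1') and that coverage is adequate"))
  }
  first <- samples[[1L]]$sites
  sel <- match(common, keys[[1L]])
  loci <- data.frame(chrom = first$chrom[sel], pos = first$pos[sel],
                     stringsAsFactors = FALSE)
  o <- locus_order(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  common <- common[o]
  meth <- matrix(0L, nrow = length(common), ncol = length(samples),
                 dimnames = list(NULL, ids))
  unmeth <- meth
  for (j in seq_along(samples)) {
    idx <- match(common, keys[[j]])
    meth[, j] <- samples[[j]]$sites$meth[idx]
    unmeth[, j] <- samples[[j]]$sites$unmeth[idx]
  }
  structure(list(
    loci = loci, meth = meth, unmeth = unmeth,
    samples = data.frame(sample_id = ids,
                         group = vapply(samples, `[[`, "", "group"),
                         stringsAsFactors = FALSE)),
    class = "methylome_matrix")
}

#' Filter a methylome matrix to scoreable CpGs
#'
#' Retains exactly the loci whose read coverage (methylated + unmethylated)
#' is strictly greater than \code{min_cov_exclusive} in every sample. The
#' default reproduces the usual RRBS scoreability rule "coverage > 8 in all
#' samples", i.e. coverage >= 9.
#'
#' @param matrix A \code{methylome_matrix} from [intersect_common_loci()].
#' @param min_cov_exclusive Exclusive coverage bound (default 8). Set to
#'   \code{k - 1} for an inclusive "coverage >= k" reading.
#' @param quiet Suppress the retained/dropped message.
#' @return A filtered \code{methylome_matrix}.
#' @export
filter_scoreable <- function(matrix, min_cov_exclusive = 8, quiet = FALSE) {
  stopifnot(inherits(matrix, "methylome_matrix"))
  if (!is_count_scalar(min_cov_exclusive)) {
    stopf("min_cov_exclusive must be a single integer >= 0")
  }
  cov <- matrix$meth + matrix$unmeth
  keep <- rowSums(cov > min_cov_exclusive) == ncol(cov)
  out <- matrix
  out$loci <- matrix$loci[keep, , drop = FALSE]
  rownames(out$loci) <- NULL
  out$meth <- matrix$meth[keep, , drop = FALSE]
  out$unmeth <- matrix$unmeth[keep, , drop = FALSE]
  if (!quiet) {
    message(sprintf("scoreability filter (coverage > %d in all %d samples): %d of %d loci retained, %d dropped",
                    as.integer(min_cov_exclusive), ncol(cov),
                    sum(keep), length(keep), sum(!keep)))
  }
  out
}

#' Per-CpG methylation fraction
#'
#' @param meth_count,unmeth_count Non-negative read counts; their sum must
#'   be positive (guaranteed after scoreability filtering).
#' @return \code{meth_count / (meth_count + unmeth_count)}, in \[0, 1\].
#' @export
cpg_methylation <- function(meth_count, unmeth_count) {
  if (any(meth_count < 0) || any(unmeth_count < 0)) stopf("negative read count")
  cov <- meth_count + unmeth_count
  if (any(cov == 0)) stopf("zero coverage: methylation fraction undefined")
  meth_count / cov
}

#' @export
print.methylome_matrix <- function(x, ...) {
  cov <- x$meth + x$unmeth
  cat(sprintf("<methylome_matrix> %d CpG loci x %d samples\n",
              nrow(x$loci), nrow(x$samples)))
  if (nrow(x$loci)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(x$loci$chrom), collapse = ", ")))
    cat(sprintf("  coverage: median %.0f, min %d\n",
                stats::median(cov), min(cov)))
  }
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s(%s)", x$samples$sample_id, x$samples$group),
                    collapse = ", ")))
  invisible(x)
}

#' Flatten a methylome matrix to a data frame
#'
#' One row per locus: \code{chrom}, \code{pos}, then
#' \code{meth_<sample>} / \code{unmeth_<sample>} count columns.
#'
#' @param x A \code{methylome_matrix}.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data frame.
#' @export
as.data.frame.methylome_matrix <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  df <- x$loci
  for (j in seq_len(nrow(x$samples))) {
    df[[paste0("meth_", x$samples$sample_id[j])]] <- x$meth[, j]
    df[[paste0("unmeth_", x$samples$sample_id[j])]] <- x$unmeth[, j]
  }
  df
}
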