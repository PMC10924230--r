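# Differential-methylation calling: per region, pooled control and
# treatment methylation, their difference in percentage points, and a
# pure effect-size classification (no statistical test, by design).

#' Specify a control-vs-treatment comparison
#'
#' @param comparison_id Short label for the comparison (e.g.
#'   \code{"smad4_vs_ev"}).
#' @param control_samples,treatment_samples Non-empty, disjoint character
#'   vectors of sample ids.
#' @param delta_threshold Exclusive bound on the absolute methylation
#'   change in percentage points (default 5): a region is called only when
#'   \code{|delta| > delta_threshold}.
#' @param max_gap Region-chaining gap in bp (default 50); carried along for
#'   pipeline bookkeeping.
#' @param min_cov_exclusive Scoreability bound (default 8); carried along
#'   for pipeline bookkeeping.
#' @return An object of class \code{comparison_spec}.
#' @export
comparison_spec <- function(comparison_id, control_samples, treatment_samples,
                            delta_threshold = 5, max_gap = 50,
                            min_cov_exclusive = 8) {
  if (length(control_samples) == 0L || length(treatment_samples) == 0L) {
    stopf("control and treatment sample sets must be non-empty")
  }
  if (length(intersect(control_samples, treatment_samples)) > 0L) {
    stopf("control and treatment sample sets must be disjoint")
  }
  if (!is.numeric(delta_threshold) || length(delta_threshold) != 1L ||
      delta_threshold <= 0) {
    stopf("delta_threshold must be a single positive number")
  }
  structure(list(comparison_id = as.character(comparison_id),
                 control_samples = as.character(control_samples),
                 treatment_samples = as.character(treatment_samples),
                 delta_threshold = delta_threshold,
                 max_gap = max_gap,
                 min_cov_exclusive = min_cov_exclusive),
            class = "comparison_spec")
}

#' Call differentially methylated regions
#'
#' For every region, pools read counts (coverage-weighted) over the
#' control samples and over the treatment samples, computes methylation
#' percentages and their difference \code{delta = treatment - control} in
#' percentage points, and classifies the region as \code{increased}
#' (\code{delta > threshold}), \code{decreased}
#' (\code{delta < -threshold}) or \code{unchanged} otherwise. The bound is
#' exclusive: a delta of exactly the threshold is \code{unchanged}.
#'
#' @param regions A \code{cpg_regions} data frame from
#'   [assemble_regions()].
#' @param matrix The \code{methylome_matrix} the regions were built from.
#' @param spec A \code{comparison_spec}.
#' @return A data frame of class \code{dmr_calls}, sorted by
#'   (chrom, start): \code{comparison_id}, \code{region_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_cpgs}, \code{meth_control},
#'   \code{meth_treatment}, \code{delta}, \code{direction}. The spec is
#'   attached as attribute \code{"spec"}.
#' @examples
#' s1 <- methylome_sample("ev", "control", rep("chr1", 2), c(100, 120),
#'                        c(20, 20), c(30, 30))
#' s2 <- methylome_sample("s4", "treatment", rep("chr1", 2), c(100, 120),
#'                        c(10, 9), c(40, 41))
#' m <- filter_scoreable(intersect_common_loci(list(s1, s2)), quiet = TRUE)
#' calls <- call_dmrs(assemble_regions(m), m,
#'                    comparison_spec("s4_vs_ev", "ev", "s4"))
#' calls
#' @export
call_dmrs <- function(regions, matrix, spec) {
  stopifnot(inherits(regions, "cpg_regions"),
            inherits(matrix, "methylome_matrix"),
            inherits(spec, "comparison_spec"))
  jc <- match(spec$control_samples, matrix$samples$sample_id)
  jt <- match(spec$treatment_samples, matrix$samples$sample_id)
  if (anyNA(jc)) stopf("control sample '%s' not in matrix",
                       spec$control_samples[is.na(jc)][1L])
  if (anyNA(jt)) stopf("treatment sample '%s' not in matrix",
                       spec$treatment_samples[is.na(jt)][1L])
  n <- nrow(regions)
  # vectorized pooling: per-locus group sums, then per-region sums
  locus_region <- integer(nrow(matrix$loci))
  for (i in seq_len(n)) locus_region[regions$members[[i]]] <- i
  sum_by_region <- function(x) {
    as.numeric(rowsum(x, locus_region, reorder = TRUE))
  }
  if (n > 0L) {
    mc <- sum_by_region(rowSums(matrix$meth[, jc, drop = FALSE]))
    uc <- sum_by_region(rowSums(matrix$unmeth[, jc, drop = FALSE]))
    mt <- sum_by_region(rowSums(matrix$meth[, jt, drop = FALSE]))
    ut <- sum_by_region(rowSums(matrix$unmeth[, jt, drop = FALSE]))
    meth_control <- region_methylation(mc, uc)
    meth_treatment <- region_methylation(mt, ut)
  } else {
    meth_control <- meth_treatment <- numeric()
  }
  delta <- meth_treatment - meth_control
  direction <- classify_delta(delta, spec$delta_threshold)
  df <- data.frame(comparison_id = rep(spec$comparison_id, n),
                   region_id = regions$region_id,
                   chrom = regions$chrom,
                   start = regions$start,
                   end = regions$end,
                   n_cpgs = regions$n_cpgs,
                   meth_control = meth_control,
                   meth_treatment = meth_treatment,
                   delta = delta,
                   direction = direction,
                   stringsAsFactors = FALSE)
  o <- locus_order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "spec") <- spec
  class(df) <- c("dmr_calls", "data.frame")
  df
}

#' @keywords internal
#' @noRd
classify_delta <- function(delta, threshold) {
  ifelse(delta > threshold, "increased",
         ifelse(delta < -threshold, "decreased", "unchanged"))
}

#' Count DMR calls by direction
#'
#' @param calls A \code{dmr_calls} data frame.
#' @return A named integer vector \code{c(increased, decreased, unchanged)}
#'   summing to \code{nrow(calls)}.
#' @export
summarize_directions <- function(calls) {
  dirs <- c("increased", "decreased", "unchanged")
  out <- vapply(dirs, function(d) sum(calls$direction == d), 1L)
  names(out) <- dirs
  out
}

#' Histogram of methylation changes
#'
#' Bins region deltas (percentage points) into equal-width bins spanning
#' \code{range}. Bins are left-closed right-open, except the final bin
#' which is closed so that +100 is counted. Per-direction subtotals are
#' included.
#'
#' @param calls A \code{dmr_calls} data frame.
#' @param bin_width Bin width in percentage points (default 5); must divide
#'   the range evenly.
#' @param range Numeric length-2 delta range (default \code{c(-100, 100)}).
#' @return A data frame: \code{bin_left}, \code{bin_right}, \code{count},
#'   \code{count_increased}, \code{count_decreased}; counts sum to
#'   \code{nrow(calls)}.
#' @export
delta_histogram <- function(calls, bin_width = 5, range = c(-100, 100)) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stopf("bin_width must be a single positive number")
  }
  span <- range[2L] - range[1L]
  nbins <- span / bin_width
  if (abs(nbins - round(nbins)) > 1e-9) {
    stopf("bin_width %g does not divide the range [%g, %g] evenly",
          bin_width, range[1L], range[2L])
  }
  nbins <- as.integer(round(nbins))
  left <- range[1L] + bin_width * (seq_len(nbins) - 1L)
  right <- left + bin_width
  bin_of <- function(delta) {
    b <- floor((delta - range[1L]) / bin_width) + 1L
    pmin(pmax(b, 1L), nbins)  # final bin closed at range[2]
  }
  tab <- function(sub) tabulate(bin_of(sub), nbins)
  data.frame(bin_left = left, bin_right = right,
             count = tab(calls$delta),
             count_increased = tab(calls$delta[calls$direction == "increased"]),
             count_decreased = tab(calls$delta[calls$direction == "decreased"]))
}

#' @export
print.dmr_calls <- function(x, ...) {
  spec <- attr(x, "spec")
  counts <- summarize_directions(x)
  cat(sprintf("<dmr_calls> comparison '%s': %d regions\n",
              spec$comparison_id %||% "?", nrow(x)))
  cat(sprintf("  threshold |delta| > %g points: %d increased, %d decreased, %d unchanged\n",
              spec$delta_threshold %||% NA, counts[["increased"]],
              counts[["decreased"]], counts[["unchanged"]]))
  if (nrow(x)) {
    cat("  first calls:\n")
    print.data.frame(utils::head(as.data.frame(x)[, c("region_id", "n_cpgs",
                                                      "meth_control",
                                                      "meth_treatment",
                                                      "delta", "direction")],
                                 5L), digits = 4)
  }
  invisible(x)
}

#' @export
summary.dmr_calls <- function(object, bin_width = 5, ...) {
  structure(list(spec = attr(object, "spec"),
                 n_regions = nrow(object),
                 directions = summarize_directions(object),
                 delta_quartiles = stats::quantile(object$delta,
                                                  c(0, 0.25, 0.5, 0.75, 1)),
                 histogram = delta_histogram(object, bin_width = bin_width)),
            class = "summary.dmr_calls")
}

#' @export
print.summary.dmr_calls <- function(x, ...) {
  cat(sprintf("DMR calls for comparison '%s'\n", x$spec$comparison_id))
  cat(sprintf("  %d regions; |delta| > %g percentage points\n",
              x$n_regions, x$spec$delta_threshold))
  cat(sprintf("  increased %d, decreased %d, unchanged %d\n",
              x$directions[["increased"]], x$directions[["decreased"]],
              x$directions[["unchanged"]]))
  cat("  delta quartiles (points):\n")
  print(round(x$delta_quartiles, 2))
  invisible(x)
}

#' Plot the delta-methylation histogram of a set of DMR calls
#'
#' Bars of region counts binned by methylation change; increases and
#' decreases beyond the threshold are shaded red resp. blue, unchanged
#' regions grey.
#'
#' @param x A \code{dmr_calls} object.
#' @param bin_width Bin width in percentage points.
#' @param called_only Drop the unchanged regions before binning.
#' @param ... Passed to [graphics::barplot()].
#' @return The histogram data frame, invisibly.
#' @export
plot.dmr_calls <- function(x, bin_width = 5, called_only = FALSE, ...) {
  sub <- if (called_only) x[x$direction != "unchanged", , drop = FALSE] else x
  h <- delta_histogram(sub, bin_width = bin_width)
  other <- h$count - h$count_increased - h$count_decreased
  height <- rbind(unchanged = other, increased = h$count_increased,
                  decreased = h$count_decreased)
  graphics::barplot(height,
                    names.arg = sprintf("%g", h$bin_left),
                    col = c("grey80", "firebrick", "steelblue"),
                    border = NA, space = 0,
                    xlab = "change in DNA methylation (percentage points)",
                    ylab = "regions", ...)
  invisible(h)
}
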