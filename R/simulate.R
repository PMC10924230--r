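# Synthetic RRBS methylomes with the structure the analysis assumes:
# CpG positions from a two-scale gap mixture (dense clusters separated by
# long gaps), read coverage from a negative binomial, methylation counts
# from a beta-binomial around a cluster-level baseline, and planted
# regions of shifted methylation with a ground-truth table.

#' Configuration for the synthetic methylome generator
#'
#' Defaults describe a desk-scale RRBS-like experiment: 2 chromosomes of
#' 10 Mb (~50,000 CpGs), one library per condition, mean coverage 50 with
#' negative-binomial overdispersion, bimodal baseline methylation, mild
#' beta-binomial dispersion, and 200 planted differentially methylated
#' regions of +/- 25 percentage points.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @param n_chroms,chrom_length Number and length (bp) of simulated
#'   chromosomes (named \code{chr1}, \code{chr2}, ...).
#' @param p_cluster Probability that the next inter-CpG gap is a
#'   within-cluster gap.
#' @param gap_in_mean Mean within-cluster gap in bp (minimum 2, the CpG
#'   dinucleotide itself).
#' @param gap_out_mean Mean between-cluster gap in bp (minimum 51, so that
#'   clusters are separated under the default 50-bp chaining rule).
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and
#'   size parameter for per-CpG per-sample read coverage; draws of zero
#'   leave the CpG absent from that sample's table (as in real coverage
#'   files, which omit uncovered CpGs).
#' @param baseline_meth_alpha,baseline_meth_beta Beta parameters of the
#'   cluster-level baseline methylation level (defaults give the bimodal
#'   low/high pattern typical of CpG methylomes).
#' @param meth_precision Beta-binomial concentration: per CpG and sample
#'   the methylation probability is drawn from
#'   \code{Beta(mu * precision, (1 - mu) * precision)}. \code{Inf} gives
#'   pure binomial counts.
#' @param n_planted Number of planted differentially methylated regions.
#' @param planted_width_cpgs Length-2 integer range of cluster sizes (in
#'   CpGs) eligible for planting.
#' @param planted_delta Signed planted effect size(s) in percentage
#'   points, recycled over the planted regions (default half decreased,
#'   half increased at 25 points).
#' @param group_sizes Named integer vector \code{c(control = ...,
#'   treatment = ...)}.
#' @param n_genes Number of genes for [simulate_gene_annotation()].
#' @param placement \code{"random"} places planted regions in randomly
#'   chosen eligible clusters; \code{"tss_stratified"} (requires genes at
#'   simulation time) places positive deltas within \code{tss_near_bp} of
#'   a TSS and negative deltas at least \code{tss_far_bp} from every TSS.
#' @param tss_near_bp,tss_far_bp Distance bounds used by
#'   \code{"tss_stratified"} placement.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e7,
                       p_cluster = 0.88,
                       gap_in_mean = 15,
                       gap_out_mean = 3200,
                       coverage_mean = 50,
                       coverage_dispersion = 5,
                       baseline_meth_alpha = 0.7,
                       baseline_meth_beta = 0.7,
                       meth_precision = 100,
                       n_planted = 200L,
                       planted_width_cpgs = c(4L, 12L),
                       planted_delta = c(-25, 25),
                       group_sizes = c(control = 1L, treatment = 1L),
                       n_genes = 200L,
                       placement = c("random", "tss_stratified"),
                       tss_near_bp = 2000,
                       tss_far_bp = 50000) {
  placement <- match.arg(placement)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, p_cluster = p_cluster,
              gap_in_mean = gap_in_mean, gap_out_mean = gap_out_mean,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              baseline_meth_alpha = baseline_meth_alpha,
              baseline_meth_beta = baseline_meth_beta,
              meth_precision = meth_precision,
              n_planted = as.integer(n_planted),
              planted_width_cpgs = as.integer(planted_width_cpgs),
              planted_delta = planted_delta,
              group_sizes = group_sizes,
              n_genes = as.integer(n_genes),
              placement = placement,
              tss_near_bp = tss_near_bp, tss_far_bp = tss_far_bp)
  pos_flds <- c("chrom_length", "gap_in_mean", "gap_out_mean",
                "coverage_mean", "coverage_dispersion",
                "baseline_meth_alpha", "baseline_meth_beta",
                "meth_precision")
  for (f in pos_flds) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stopf("%s must be > 0", f)
  }
  if (cfg$p_cluster < 0 || cfg$p_cluster >= 1) stopf("p_cluster must be in [0, 1)")
  if (cfg$gap_in_mean <= 2) stopf("gap_in_mean must exceed 2")
  if (cfg$gap_out_mean <= 51) stopf("gap_out_mean must exceed 51")
  if (any(abs(cfg$planted_delta) > 100)) stopf("|planted_delta| must be <= 100")
  if (cfg$n_planted < 0) stopf("n_planted must be >= 0")
  if (length(cfg$planted_width_cpgs) != 2L ||
      cfg$planted_width_cpgs[1L] < 1L ||
      cfg$planted_width_cpgs[1L] > cfg$planted_width_cpgs[2L]) {
    stopf("planted_width_cpgs must be an increasing length-2 integer range")
  }
  if (is.null(names(cfg$group_sizes)) ||
      !all(c("control", "treatment") %in% names(cfg$group_sizes)) ||
      any(cfg$group_sizes < 1L)) {
    stopf("group_sizes must be a named vector c(control = ..., treatment = ...), each >= 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene annotation
#'
#' Places non-overlapping multi-exon gene models on the simulated
#' chromosomes: gene lengths uniform in 2-50 kb, exponential intergenic
#' gaps scaled to fill the chromosome, 2-8 exons per gene with the first
#' and last exon anchored at the span ends, random strands. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @return A \code{gene_models} data frame (empty when
#'   \code{config$n_genes == 0}).
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000003L)
  if (config$n_genes == 0L) return(finalize_gene_models(list()))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1L)))
  models <- list()
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    n <- per_chrom[ci]
    if (n == 0L) next
    len <- round(stats::runif(n, 2000, 50000))
    slack <- config$chrom_length - sum(len)
    if (slack <= n) {
      stopf("cannot pack %d genes of total length %.0f into a %.0f bp chromosome",
            n, sum(len), config$chrom_length)
    }
    gaps <- stats::rexp(n, 1)
    gaps <- pmax(round(gaps / sum(gaps) * (slack - n)), 1)
    start <- round(cumsum(gaps) + cumsum(c(0, len[-n])) + 1)
    end <- start + len - 1
    if (any(end > config$chrom_length)) {
      stopf("gene packing exceeded chromosome length on %s; reduce n_genes", chrom)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    for (g in seq_len(n)) {
      n_ex <- sample(2:8, 1L)
      # split the span into 2*n_ex - 1 alternating exon/intron segments
      w <- stats::rexp(2L * n_ex - 1L) + 0.02
      seg <- diff(round(c(0, cumsum(w / sum(w))) * (len[g] - 1)))
      seg[seg < 1] <- 1
      bounds <- start[g] + cumsum(c(0, seg))
      ex_start <- bounds[seq(1L, by = 2L, length.out = n_ex)]
      ex_end <- pmin(bounds[seq(2L, by = 2L, length.out = n_ex)] - 1L, end[g])
  ex_end[n_ex] <- end[g]
      ok <- ex_start <= ex_end
      models[[length(models) + 1L]] <- list(
        gene_id = sprintf("gene_%s_%03d", chrom, g), chrom = chrom,
        strand = strand[g], span_start = as.integer(start[g]),
        span_end = as.integer(end[g]),
        exons = cbind(start = as.integer(ex_start[ok]),
                      end = as.integer(ex_end[ok])))
    }
  }
  finalize_gene_models(models)
}

# CpG positions for one chromosome from the two-scale gap mixture.
#' @keywords internal
#' @noRd
draw_positions <- function(config) {
  mean_gap <- config$p_cluster * config$gap_in_mean +
    (1 - config$p_cluster) * config$gap_out_mean
  n_draw <- ceiling(config$chrom_length / mean_gap * 1.25) + 1000L
  within <- stats::runif(n_draw) < config$p_cluster
  gap <- integer(n_draw)
  gap[within] <- 2L + stats::rgeom(sum(within), 1 / (config$gap_in_mean - 1))
  gap[!within] <- 51L + stats::rgeom(sum(!within),
                                     1 / (config$gap_out_mean - 50))
  pos <- cumsum(c(sample(100:1000, 1L), gap))
  pos[pos <= config$chrom_length]
}

#' Simulate methylomes with planted differentially methylated regions
#'
#' Draws clustered CpG positions per chromosome, assigns each CpG cluster
#' (maximal run of CpGs at gaps <= 50 bp) a baseline methylation level
#' from the beta baseline, plants \code{n_planted} shifted regions in
#' eligible clusters, and generates per-sample counts: coverage ~
#' negative binomial (zero-coverage CpGs are absent from that sample),
#' methylated reads ~ beta-binomial around the cluster mean. Treatment
#' samples have the planted clusters' mean shifted by
#' \code{planted_delta / 100}, clamped to \[0.01, 0.99\]; control samples
#' are never shifted. Planted clusters draw their baseline so the full
#' shift fits inside the clamp bounds; if a user-supplied delta cannot
#' fit, the achieved (clamped) delta is recorded in the truth table with
#' a warning.
#'
#' @param config A [sim_config()].
#' @param genes Optional \code{gene_models}, required for
#'   \code{placement = "tss_stratified"}.
#' @return A list with \code{samples} (list of \code{methylome_sample}),
#'   \code{truth} (data frame \code{chrom}, \code{start}, \code{end},
#'   \code{true_delta} in percentage points, \code{direction}) and
#'   \code{n_cpgs} (total simulated CpGs).
#' @export
simulate_methylomes <- function(config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$placement == "tss_stratified" &&
      (is.null(genes) || nrow(genes) == 0L)) {
    stopf("tss_stratified placement requires a non-empty gene annotation")
  }
  set.seed(config$seed)
  chrom <- character(0)
  pos <- integer(0)
  for (ci in seq_len(config$n_chroms)) {
    p <- draw_positions(config)
    chrom <- c(chrom, rep(paste0("chr", ci), length(p)))
    pos <- c(pos, p)
  }
  n <- length(pos)
  # cluster = maximal run at gaps <= 50 bp (matches the default chaining rule)
  new_cluster <- c(TRUE, chrom[-1L] != chrom[-n] | diff(pos) > 50L)
  cluster <- cumsum(new_cluster)
  n_clusters <- cluster[n]
  cl_size <- tabulate(cluster, n_clusters)
  cl_first <- which(new_cluster)
  cl_chrom <- chrom[cl_first]
  cl_start <- pos[cl_first]
  cl_end <- pos[c(cl_first[-1L] - 1L, n)]

  mu0 <- stats::rbeta(n_clusters, config$baseline_meth_alpha,
                      config$baseline_meth_beta)
  mu0 <- pmin(pmax(mu0, 0.01), 0.99)

  # ---- planted regions ----
  planted <- integer(0)
  deltas <- numeric(0)
  if (config$n_planted > 0L) {
    eligible <- which(cl_size >= config$planted_width_cpgs[1L] &
                      cl_size <= config$planted_width_cpgs[2L])
    deltas <- rep_len(config$planted_delta, config$n_planted)
    if (config$placement == "tss_stratified") {
      idx <- build_tss_index(genes)
      mid <- as.integer(floor((as.numeric(cl_start[eligible]) +
                               cl_end[eligible]) / 2))
      d <- nearest_tss(idx, cl_chrom[eligible], mid)$abs_distance_kb * 1000
      near <- eligible[!is.na(d) & d <= config$tss_near_bp]
      far <- eligible[is.na(d) | d >= config$tss_far_bp]
      n_pos <- sum(deltas > 0)
      n_neg <- sum(deltas < 0)
      if (length(near) < n_pos || length(far) < n_neg) {
        stopf("not enough clusters near/far from TSSs to plant %d/%d regions (have %d/%d)",
              n_pos, n_neg, length(near), length(far))
      }
      planted <- integer(config$n_planted)
      planted[deltas > 0] <- sample(near, n_pos)
      planted[deltas < 0] <- sample(far, n_neg)
      planted[deltas == 0] <- sample(setdiff(eligible, planted), sum(deltas == 0))
    } else {
      if (length(eligible) < config$n_planted) {
        stopf("only %d clusters of %d-%d CpGs available for %d planted regions",
              length(eligible), config$planted_width_cpgs[1L],
              config$planted_width_cpgs[2L], config$n_planted)
      }
      planted <- sample(eligible, config$n_planted)
    }
    # draw planted baselines so the full shift fits within the clamp bounds
    lo <- pmax(0.01, 0.01 - deltas / 100)
    hi <- pmin(0.99, 0.99 - deltas / 100)
    feasible <- lo < hi
    for (k in seq_len(config$n_planted)) {
      if (!feasible[k]) next
      for (tries in 1:1000) {
        m <- stats::rbeta(1L, config$baseline_meth_alpha,
                          config$baseline_meth_beta)
        if (m >= lo[k] && m <= hi[k]) { mu0[planted[k]] <- m; break }
      }
      if (tries == 1000L) mu0[planted[k]] <- (lo[k] + hi[k]) / 2
    }
  }
  mu_treat <- mu0
  if (length(planted)) {
    mu_treat[planted] <- pmin(pmax(mu0[planted] + deltas / 100, 0.01), 0.99)
    achieved <- 100 * (mu_treat[planted] - mu0[planted])
    if (any(abs(achieved - deltas) > 1e-6)) {
      warnf("%d planted delta(s) clamped at the [0.01, 0.99] bounds; truth records the achieved delta",
            sum(abs(achieved - deltas) > 1e-6))
    }
  } else {
    achieved <- numeric(0)
  }

  # ---- per-sample counts ----
  gs <- config$group_sizes
  groups <- c(rep("control", gs[["control"]]), rep("treatment", gs[["treatment"]]))
  ids <- c(sprintf("control_%d", seq_len(gs[["control"]])),
           sprintf("treatment_%d", seq_len(gs[["treatment"]])))
  mu_ctrl_cpg <- mu0[cluster]
  mu_trt_cpg <- mu_treat[cluster]
  samples <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    cov <- stats::rnbinom(n, size = config$coverage_dispersion,
                          mu = config$coverage_mean)
    present <- cov > 0L
    mu <- if (groups[s] == "treatment") mu_trt_cpg else mu_ctrl_cpg
    if (is.finite(config$meth_precision)) {
      p <- stats::rbeta(n, mu * config$meth_precision,
                        (1 - mu) * config$meth_precision)
    } else {
      p <- mu
    }
    meth <- stats::rbinom(sum(present), cov[present], p[present])
    samples[[s]] <- methylome_sample(ids[s], groups[s],
                                     chrom[present], pos[present],
                                     meth, cov[present] - meth)
  }
  truth <- if (length(planted)) {
    o <- locus_order(cl_chrom[planted], cl_start[planted])
    data.frame(chrom = cl_chrom[planted][o],
               start = cl_start[planted][o],
               end = cl_end[planted][o],
               true_delta = achieved[o],
               direction = classify_delta(achieved[o], 0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               true_delta = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  }
  list(samples = samples, truth = truth, n_cpgs = n)
}

#' Write a self-contained synthetic fixture set
#'
#' Emits exactly the formats the pipeline consumes: one gzipped Bismark
#' coverage file per sample, a BED12 gene annotation, the ground-truth
#' table as TSV, and the configuration echoed as YAML.
#'
#' @param sim Output of [simulate_methylomes()].
#' @param genes A \code{gene_models} data frame.
#' @param config The [sim_config()] used.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite a non-empty \code{out_dir}.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(sim, genes, config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stopf("output directory '%s' is not empty (use force = TRUE)", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (s in sim$samples) {
    p <- file.path(out_dir, paste0(s$sample_id, ".cov.gz"))
    write_bismark_coverage(s, p)
    paths[s$sample_id] <- p
  }
  paths["genes"] <- file.path(out_dir, "genes.bed")
  write_gene_models_bed12(genes, paths[["genes"]])
  paths["truth"] <- file.path(out_dir, "truth.tsv")
  write_tsv_table(sim$truth, paths[["truth"]])
  paths["config"] <- file.path(out_dir, "config.yaml")
  cfg <- unclass(config)
  cfg$group_sizes <- as.list(cfg$group_sizes)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Recovery of planted regions by a set of DMR calls
#'
#' @param calls A \code{dmr_calls} data frame.
#' @param truth The truth table from [simulate_methylomes()] (non-empty).
#' @return A list: \code{sensitivity} (planted regions overlapped by a
#'   same-direction call / number planted), \code{precision}
#'   (same-direction-overlapping calls / all calls beyond threshold),
#'   \code{direction_accuracy} (among planted regions overlapped by any
#'   call, the fraction overlapped by a same-direction call),
#'   \code{delta_rmse} (RMSE of call delta vs true delta over matched
#'   pairs), \code{confusion} (truth direction x best-call direction),
#'   \code{n_truth}, \code{n_called}.
#' @export
evaluate_recovery <- function(calls, truth) {
  if (nrow(truth) == 0L) stopf("empty truth table")
  called <- calls[calls$direction != "unchanged", , drop = FALSE]
  same_dir_hit <- logical(nrow(truth))
  any_hit <- overlaps_reference(truth, called)
  for (d in c("increased", "decreased")) {
    sel <- truth$direction == d
    same_dir_hit[sel] <- overlaps_reference(
      truth[sel, , drop = FALSE],
      called[called$direction == d, , drop = FALSE])
  }
  # precision: called regions overlapping a same-direction truth region
  call_hit <- logical(nrow(called))
  for (d in c("increased", "decreased")) {
    sel <- called$direction == d
    call_hit[sel] <- overlaps_reference(
      called[sel, , drop = FALSE],
      truth[truth$direction == d, , drop = FALSE])
  }
  # matched pairs: per truth region, the overlapping called region of the
  # same direction with the largest overlap
  best_call <- rep(NA_integer_, nrow(truth))
  best_dir <- rep(NA_character_, nrow(truth))
  if (nrow(called)) {
    for (ch in intersect(unique(truth$chrom), unique(called$chrom))) {
      ti <- which(truth$chrom == ch)
      ci <- which(called$chrom == ch)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(truth$start[ti], truth$end[ti]),
        IRanges::IRanges(called$start[ci], called$end[ci]))
      if (length(ov) == 0L) next
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- pmin(truth$end[ti][qh], called$end[ci][sh]) -
           pmax(truth$start[ti][qh], called$start[ci][sh]) + 1L
      same <- truth$direction[ti][qh] == called$direction[ci][sh]
      for (t in unique(qh)) {
        cand <- which(qh == t & same)
        pool <- if (length(cand)) cand else which(qh == t)
        pick <- pool[which.max(w[pool])]
        best_call[ti[t]] <- ci[sh[pick]]
        best_dir[ti[t]] <- called$direction[ci[sh[pick]]]
      }
    }
  }
  matched <- which(!is.na(best_call) &
                   best_dir == truth$direction)
  rmse <- if (length(matched)) {
    sqrt(mean((called$delta[best_call[matched]] -
               truth$true_delta[matched])^2))
  } else NA_real_
  confusion <- table(truth = truth$direction,
                     call = ifelse(is.na(best_dir), "missed", best_dir))
  list(sensitivity = mean(same_dir_hit),
       precision = if (nrow(called)) mean(call_hit) else NA_real_,
       direction_accuracy = if (any(any_hit)) {
         sum(same_dir_hit) / sum(any_hit)
       } else NA_real_,
       delta_rmse = rmse,
       confusion = confusion,
       n_truth = nrow(truth),
       n_called = nrow(called))
}
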