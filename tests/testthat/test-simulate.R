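# Synthetic methylome generator: determinism, planted truth, fixtures.

small_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 101, n_chroms = 1L, chrom_length = 5e5, n_planted = 10L,
         n_genes = 10L),
    list(...))
  do.call(sim_config, args)
}

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(p_cluster = 1.2), "p_cluster")
  expect_error(sim_config(planted_delta = 150), "planted_delta")
  expect_error(sim_config(coverage_mean = -1), "coverage_mean")
  expect_error(sim_config(group_sizes = c(control = 0, treatment = 1)),
               "group_sizes")
  expect_error(sim_config(planted_width_cpgs = c(5, 2)), "planted_width")
})

test_that("gene annotation is deterministic and respects the strand rule", {
  cfg <- small_config()
  g1 <- simulate_gene_annotation(cfg)
  g2 <- simulate_gene_annotation(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 10L)
  expect_true(all(g1$span_start <= g1$span_end))
  plus <- g1$strand == "+"
  expect_equal(g1$tss[plus], g1$span_start[plus])
  expect_equal(g1$tss[!plus], g1$span_end[!plus])
  for (i in seq_len(nrow(g1))) {
    ex <- g1$exons[[i]]
    expect_true(all(ex[, "start"] >= g1$span_start[i]))
    expect_true(all(ex[, "end"] <= g1$span_end[i]))
    expect_true(all(ex[, "start"] <= ex[, "end"]))
  }
  # genes do not overlap within a chromosome
  o <- order(g1$span_start)
  expect_true(all(g1$span_start[o][-1] > g1$span_end[o][-nrow(g1)]))
  # zero genes is a valid degenerate annotation
  g0 <- simulate_gene_annotation(small_config(n_genes = 0L))
  expect_equal(nrow(g0), 0L)
})

test_that("methylome simulation is deterministic given the config", {
  cfg <- small_config()
  s1 <- simulate_methylomes(cfg)
  s2 <- simulate_methylomes(cfg)
  expect_identical(s1$samples[[1]]$sites, s2$samples[[1]]$sites)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".cov.gz")
  f2 <- tempfile(fileext = ".cov.gz")
  write_bismark_coverage(s1$samples[[2]], f1)
  write_bismark_coverage(s2$samples[[2]], f2)
  expect_identical(readLines(con1 <- gzfile(f1)), readLines(con2 <- gzfile(f2)))
  close(con1); close(con2)
})

test_that("truth records n_planted regions with sign-consistent directions", {
  sim <- simulate_methylomes(small_config())
  expect_equal(nrow(sim$truth), 10L)
  expect_true(all(sim$truth$start <= sim$truth$end))
  up <- sim$truth$true_delta > 0
  expect_equal(sim$truth$direction[up], rep("increased", sum(up)))
  expect_equal(sim$truth$direction[!up], rep("decreased", sum(!up)))
  # default effect size is +/- 25 points, half each
  expect_equal(sort(unique(round(abs(sim$truth$true_delta), 6))), 25)
  expect_equal(sum(up), 5L)
})

test_that("planted truth regions never overlap and sit > 50 bp apart", {
  sim <- simulate_methylomes(small_config(n_planted = 30L))
  tr <- sim$truth[order(tr_key <- sim$truth$start), ]
  expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] > 50))
})

test_that("a null simulation is direction-exchangeable up to sampling error", {
  cfg <- small_config(n_planted = 0L, seed = 5)
  sim <- simulate_methylomes(cfg)
  m <- filter_scoreable(intersect_common_loci(sim$samples), quiet = TRUE)
  calls <- call_dmrs(assemble_regions(m), m,
                     comparison_spec("null", "control_1", "treatment_1"))
  d <- summarize_directions(calls)
  n_called <- d[["increased"]] + d[["decreased"]]
  # under the null, increases ~ Binomial(n_called, 1/2)
  expect_gt(stats::binom.test(d[["increased"]], n_called)$p.value, 1e-4)
})

test_that("at very high coverage the observed delta concentrates on truth", {
  cfg <- small_config(coverage_mean = 10000, meth_precision = Inf,
                      n_planted = 5L, seed = 7)
  sim <- simulate_methylomes(cfg)
  m <- filter_scoreable(intersect_common_loci(sim$samples), quiet = TRUE)
  calls <- call_dmrs(assemble_regions(m), m,
                     comparison_spec("c", "control_1", "treatment_1"))
  ev <- evaluate_recovery(calls, sim$truth)
  expect_equal(ev$sensitivity, 1)
  expect_lt(ev$delta_rmse, 1)
})

test_that("an infeasible planted shift is clamped with a warning and recorded", {
  cfg <- small_config(planted_delta = 99, baseline_meth_alpha = 5,
                      baseline_meth_beta = 5, n_planted = 3L)
  expect_warning(sim <- simulate_methylomes(cfg), "clamped")
  expect_true(all(sim$truth$true_delta < 99))
  expect_true(all(sim$truth$true_delta > 0))
})

test_that("fixtures round trip through the package readers", {
  cfg <- small_config()
  genes <- simulate_gene_annotation(cfg)
  sim <- simulate_methylomes(cfg, genes)
  out <- file.path(tempfile(), "fx")
  paths <- write_fixtures(sim, genes, cfg, out)
  expect_error(write_fixtures(sim, genes, cfg, out), "not empty")
  s <- read_bismark_coverage(paths[["control_1"]], "control_1", "control")
  expect_identical(s$sites, sim$samples[[1]]$sites)
  g <- read_gene_models(paths[["genes"]])
  expect_equal(g$gene_id, genes$gene_id)
  expect_equal(g$tss, genes$tss)
  expect_equal(g$exons, genes$exons)
  tr <- read_tsv_table(paths[["truth"]])
  expect_equal(nrow(tr), nrow(sim$truth))
  cfg_back <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg_back$seed, cfg$seed)
  # percentage column equals 100 * meth / cov to 2 decimals
  lines <- readLines(con <- gzfile(paths[["control_1"]])); close(con)
  f <- strsplit(lines[1:50], "\t")
  pct <- as.numeric(vapply(f, `[`, "", 4))
  meth <- as.numeric(vapply(f, `[`, "", 5))
  unmeth <- as.numeric(vapply(f, `[`, "", 6))
  expect_equal(round(pct, 2), round(100 * meth / (meth + unmeth), 2))
})

test_that("recovery metrics behave at the edges", {
  truth <- data.frame(chrom = "chr1", start = c(100L, 500L),
                      end = c(150L, 550L), true_delta = c(25, -25),
                      direction = c("increased", "decreased"),
                      stringsAsFactors = FALSE)
  perfect <- data.frame(comparison_id = "c", region_id = c("r1", "r2"),
                        chrom = "chr1", start = c(100L, 500L),
                        end = c(150L, 550L), n_cpgs = 3L,
                        meth_control = c(40, 60),
                        meth_treatment = c(65, 35),
                        delta = c(25, -25),
                        direction = c("increased", "decreased"),
                        stringsAsFactors = FALSE)
  class(perfect) <- c("dmr_calls", "data.frame")
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$direction_accuracy, 1)
  expect_equal(ev$delta_rmse, 0)
  none <- perfect[0, ]
  class(none) <- c("dmr_calls", "data.frame")
  ev0 <- evaluate_recovery(none, truth)
  expect_equal(ev0$sensitivity, 0)
  expect_error(evaluate_recovery(perfect, truth[0, ]), "empty truth")
})
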