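# Effect-size DMR calling, direction classification and the delta
# histogram.

test_that("delta is pooled treatment minus control with strict threshold", {
  # control 40/100 = 40%, treatment 19/40 = 47.5% -> +7.5, increased
  m <- make_matrix("chr1", 100, 40, 60, 19, 21)
  calls <- call_dmrs(assemble_regions(m), m, comparison_spec("c", "a", "b"))
  expect_equal(calls$meth_control, 40)
  expect_equal(calls$meth_treatment, 47.5)
  expect_equal(calls$delta, 7.5)
  expect_equal(calls$direction, "increased")
})

test_that("a change of exactly the threshold is not called", {
  # control 50.0%, treatment 45.0% -> delta -5.0, unchanged
  m <- make_matrix("chr1", 100, 50, 50, 45, 55)
  calls <- call_dmrs(assemble_regions(m), m, comparison_spec("c", "a", "b"))
  expect_equal(calls$delta, -5)
  expect_equal(calls$direction, "unchanged")
})

test_that("identical groups give delta zero", {
  m <- make_matrix("chr1", 100, 30, 70, 30, 70)
  calls <- call_dmrs(assemble_regions(m), m, comparison_spec("c", "a", "b"))
  expect_equal(calls$delta, 0)
  expect_equal(calls$direction, "unchanged")
})

test_that("unknown samples in the spec are rejected", {
  m <- make_matrix("chr1", 100, 5, 5, 5, 5)
  expect_error(call_dmrs(assemble_regions(m), m,
                         comparison_spec("c", "zz", "b")), "zz")
  expect_error(comparison_spec("c", "a", "a"), "disjoint")
  expect_error(comparison_spec("c", character(0), "b"), "non-empty")
  expect_error(comparison_spec("c", "a", "b", delta_threshold = 0),
               "positive")
})

test_that("swapping groups negates deltas and swaps direction counts", {
  set.seed(13)
  for (r in 1:25) {
    m <- random_matrix(60, 2)
    m$meth <- m$meth + 9L  # scoreable everywhere
    reg <- assemble_regions(m)
    fwd <- call_dmrs(reg, m, comparison_spec("f", "s1", "s2"))
    rev <- call_dmrs(reg, m, comparison_spec("r", "s2", "s1"))
    expect_equal(rev$delta, -fwd$delta)
    f <- summarize_directions(fwd)
    b <- summarize_directions(rev)
    expect_equal(b[["increased"]], f[["decreased"]])
    expect_equal(b[["decreased"]], f[["increased"]])
    expect_equal(b[["unchanged"]], f[["unchanged"]])
  }
})

test_that("raising the threshold never adds calls", {
  set.seed(17)
  m <- random_matrix(80, 2)
  m$meth <- m$meth + 9L
  reg <- assemble_regions(m)
  n_called <- vapply(c(1, 5, 10, 25), function(t) {
    d <- summarize_directions(
      call_dmrs(reg, m, comparison_spec("c", "s1", "s2",
                                        delta_threshold = t)))
    d[["increased"]] + d[["decreased"]]
  }, 1L)
  expect_true(all(diff(n_called) <= 0))
})

test_that("direction counts sum to the number of regions", {
  set.seed(19)
  m <- random_matrix(100, 2)
  m$meth <- m$meth + 9L
  reg <- assemble_regions(m)
  calls <- call_dmrs(reg, m, comparison_spec("c", "s1", "s2"))
  expect_equal(sum(summarize_directions(calls)), nrow(reg))
})

fake_calls <- function(deltas, threshold = 5) {
  n <- length(deltas)
  df <- data.frame(comparison_id = rep("c", n),
                   region_id = sprintf("r%d", seq_len(n)),
                   chrom = rep("chr1", n), start = seq_len(n) * 1000L,
                   end = seq_len(n) * 1000L + 10L, n_cpgs = rep(1L, n),
                   meth_control = rep(50, n), meth_treatment = 50 + deltas,
                   delta = deltas,
                   direction = rrbsdmr:::classify_delta(deltas, threshold),
                   stringsAsFactors = FALSE)
  class(df) <- c("dmr_calls", "data.frame")
  attr(df, "spec") <- comparison_spec("c", "a", "b",
                                      delta_threshold = threshold)
  df
}

test_that("histogram bins are left-closed right-open with a closed last bin", {
  h <- delta_histogram(fake_calls(c(-7, -6, 3, 12)))
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count[h$bin_left == -10], 2L)
  expect_equal(h$count[h$bin_left == 0], 1L)
  expect_equal(h$count[h$bin_left == 10], 1L)
  expect_equal(sum(h$count[!h$bin_left %in% c(-10, 0, 10)]), 0L)

  h5 <- delta_histogram(fake_calls(-5))
  expect_equal(h5$count[h5$bin_left == -5], 1L)

  h100 <- delta_histogram(fake_calls(100))
  expect_equal(h100$count[h100$bin_left == 95], 1L)

  h0 <- delta_histogram(fake_calls(numeric(0)))
  expect_true(all(h0$count == 0L))
  expect_equal(nrow(h0), 40L)

  expect_error(delta_histogram(fake_calls(1), bin_width = 3), "evenly")
})

test_that("histogram mass and per-direction subtotals are conserved", {
  set.seed(23)
  for (r in 1:10) {
    calls <- fake_calls(runif(50, -100, 100))
    h <- delta_histogram(calls)
    expect_equal(sum(h$count), 50L)
    d <- summarize_directions(calls)
    expect_equal(sum(h$count_increased), d[["increased"]])
    expect_equal(sum(h$count_decreased), d[["decreased"]])
  }
})

test_that("direction tallies match hand classification", {
  d <- summarize_directions(fake_calls(c(7.5, -6, -12, 0)))
  expect_equal(unname(d), c(1L, 2L, 1L))
  d0 <- summarize_directions(fake_calls(c(-5, 5, 4.9, -4.9)))
  expect_equal(unname(d0), c(0L, 0L, 4L))
})

test_that("dmr_calls print, summary and plot run quietly", {
  calls <- fake_calls(c(-20, 8, 1))
  expect_output(print(calls), "increased")
  s <- summary(calls)
  expect_s3_class(s, "summary.dmr_calls")
  expect_output(print(s), "quartiles")
  pdf(NULL)
  on.exit(dev.off())
  h <- plot(calls)
  expect_equal(sum(h$count), 3L)
})
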