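# Fixture builders and independent brute-force oracles used across the
# suite. Each oracle deliberately takes a different algorithmic route from
# the implementation it checks.

# Two-sample matrix from parallel count vectors at shared loci.
make_matrix <- function(chrom, pos, meth_a, unmeth_a, meth_b, unmeth_b,
                        groups = c("control", "treatment")) {
  a <- methylome_sample("a", groups[1], chrom, pos, meth_a, unmeth_a)
  b <- methylome_sample("b", groups[2], chrom, pos, meth_b, unmeth_b)
  intersect_common_loci(list(a, b))
}

# Random small methylome matrix (shared loci, uniform counts).
random_matrix <- function(n_loci = 30, n_samples = 3, max_count = 15) {
  chrom <- sample(c("chr1", "chr2"), n_loci, replace = TRUE)
  pos <- integer(n_loci)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sample.int(10000, k)
  }
  samples <- lapply(seq_len(n_samples), function(j) {
    methylome_sample(paste0("s", j), if (j == 1) "control" else "treatment",
                     chrom, pos,
                     sample.int(max_count + 1L, n_loci, replace = TRUE) - 1L,
                     sample.int(max_count + 1L, n_loci, replace = TRUE) - 1L)
  })
  intersect_common_loci(samples)
}

# Oracle for the scoreability filter: explicit per-locus loop.
brute_force_scoreable <- function(matrix, min_cov_exclusive) {
  keep <- logical(nrow(matrix$loci))
  for (i in seq_along(keep)) {
    ok <- TRUE
    for (j in seq_len(nrow(matrix$samples))) {
      if (matrix$meth[i, j] + matrix$unmeth[i, j] <= min_cov_exclusive) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  keep
}

# Oracle for region assembly: connected components of the graph linking
# positions <= max_gap apart, via union-find over all pairs.
brute_force_components <- function(pos, max_gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && abs(pos[i] - pos[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(pos, roots)
}

# Oracle for priority annotation: per-region loop over all genes, plain
# interval comparisons in priority order.
brute_force_annotate <- function(region, genes, tss_window, promoter_window) {
  ov <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  hit <- function(pred) {
    any(vapply(seq_len(nrow(g)), function(i) pred(g[i, ]), TRUE))
  }
  if (nrow(g) == 0) return("intergenic")
  if (hit(function(x) ov(region$start, region$end,
                         x$tss - tss_window, x$tss + tss_window))) return("TSS")
  if (hit(function(x) {
    if (x$strand == "+") {
      ps <- x$tss - promoter_window; pe <- x$tss - tss_window - 1
    } else {
      ps <- x$tss + tss_window + 1; pe <- x$tss + promoter_window
    }
    ps <= pe && ov(region$start, region$end, max(ps, 1), pe)
  })) return("promoter")
  if (hit(function(x) {
    ex <- x$exons[[1]]
    any(vapply(seq_len(nrow(ex)), function(k)
      ov(region$start, region$end, ex[k, "start"], ex[k, "end"]), TRUE))
  })) return("exon")
  if (hit(function(x) ov(region$start, region$end, x$span_start, x$span_end)))
    return("intron")
  "intergenic"
}

# Oracle for nearest TSS: full scan with the documented tie rules.
brute_force_nearest_tss <- function(genes, chrom, point) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  d <- abs(point - g$tss)
  best <- which(d == min(d))
  best <- best[order(g$tss[best], g$gene_id[best])][1]
  g[best, ]
}

# Oracle for conservation: all-pairs double loop.
brute_force_conserved <- function(query, reference) {
  hit <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(reference))) {
      if (regions_overlap(query[i, ], reference[j, ])) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# Random gene models built directly (not via files).
random_gene_models <- function(n_genes = 5, chrom_length = 50000,
                               chroms = c("chr1", "chr2")) {
  models <- lapply(seq_len(n_genes), function(i) {
    len <- sample(500:5000, 1)
    start <- sample.int(chrom_length - len, 1)
    n_ex <- sample(1:4, 1)
    bounds <- sort(sample(seq(start, start + len - 1), 2 * n_ex))
    bounds[1] <- start
    bounds[2 * n_ex] <- start + len - 1
    list(gene_id = sprintf("g%02d", i),
         chrom = sample(chroms, 1),
         strand = sample(c("+", "-"), 1),
         span_start = start, span_end = start + len - 1,
         exons = cbind(start = bounds[seq(1, 2 * n_ex, 2)],
                       end = bounds[seq(2, 2 * n_ex, 2)]))
  })
  rrbsdmr:::finalize_gene_models(models)
}

# Random DMR-call-shaped table for conservation tests.
random_calls <- function(n = 20, chroms = c("chr1", "chr2"), span = 5000) {
  start <- sample.int(span, n, replace = TRUE)
  df <- data.frame(
    comparison_id = "x",
    region_id = sprintf("r%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(200, n, replace = TRUE),
    n_cpgs = 1L, meth_control = 0, meth_treatment = 0, delta = 0,
    direction = sample(c("increased", "decreased", "unchanged"), n,
                       replace = TRUE),
    stringsAsFactors = FALSE)
  class(df) <- c("dmr_calls", "data.frame")
  df
}
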