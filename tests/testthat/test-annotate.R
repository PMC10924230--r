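# Priority genomic-context annotation and nearest-TSS distances.

genes_from <- function(...) {
  # each argument: list(gene_id, chrom, strand, span_start, span_end, exons)
  rrbsdmr:::finalize_gene_models(list(...))
}

simple_gene <- function(gene_id, chrom, strand, start, end,
                        exons = cbind(start = start, end = end)) {
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       span_start = start, span_end = end, exons = exons)
}

region_df <- function(chrom, start, end) {
  data.frame(region_id = sprintf("%s:%d-%d", chrom, start, end),
             chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("nearest-TSS queries pick the closest, ties to lower coordinate", {
  g <- genes_from(simple_gene("gA", "chr1", "+", 1000, 1500),
                  simple_gene("gB", "chr1", "+", 9000, 9500))
  idx <- build_tss_index(g)
  expect_equal(nearest_tss(idx, "chr1", 5001)$nearest_gene, "gB")
  expect_equal(nearest_tss(idx, "chr1", 5000)$nearest_gene, "gA")
  expect_equal(nearest_tss(idx, "chr1", 100)$nearest_gene, "gA")
  expect_true(is.na(nearest_tss(idx, "chrX", 100)$nearest_gene))
  single <- build_tss_index(genes_from(simple_gene("g1", "chr1", "+", 50, 99)))
  expect_equal(nearest_tss(single, "chr1", 1e6)$nearest_gene, "g1")
  expect_error(build_tss_index(genes_from()), "empty")
})

test_that("nearest-TSS matches a full scan with tie rules on random sets", {
  set.seed(31)
  for (r in 1:100) {
    g <- random_gene_models(sample(1:8, 1))
    idx <- build_tss_index(g)
    chrom <- sample(c("chr1", "chr2"), 1)
    point <- sample.int(60000, 1)
    got <- nearest_tss(idx, chrom, point)
    want <- brute_force_nearest_tss(g, chrom, point)
    if (is.null(want)) {
      expect_true(is.na(got$nearest_gene))
    } else {
      expect_equal(got$nearest_gene, want$gene_id)
      expect_equal(abs(got$signed_distance_bp), abs(point - want$tss))
    }
  }
})

test_that("signed distance is negative upstream in the gene orientation", {
  gp <- genes_from(simple_gene("gp", "chr1", "+", 10000, 12000))
  ctx <- annotate_regions(region_df("chr1", 8500, 8540), gp)
  expect_equal(ctx$signed_distance_bp, -1480L)  # midpoint 8520, upstream of +
  expect_equal(ctx$abs_distance_kb, 1.48)
  expect_equal(ctx$context, "promoter")
  gm <- genes_from(simple_gene("gm", "chr1", "-", 8000, 10000))
  ctx2 <- annotate_regions(region_df("chr1", 11455, 11465), gm)
  expect_equal(ctx2$signed_distance_bp, -1460L)  # midpoint beyond a - TSS
  expect_equal(ctx2$context, "promoter")
})

test_that("the TSS window wins over everything and intergenic is the catch-all", {
  g <- genes_from(simple_gene("g", "chr1", "+", 1000, 3000))
  expect_equal(annotate_regions(region_df("chr1", 950, 1050), g)$context, "TSS")
  expect_equal(annotate_regions(region_df("chr1", 950, 1050), g)$signed_distance_bp, 0L)
  expect_equal(annotate_regions(region_df("chr1", 500000, 500050), g)$context,
               "intergenic")
  # no genes at all
  empty <- genes_from()
  ctx <- annotate_regions(region_df("chr1", 10, 20), empty)
  expect_equal(ctx$context, "intergenic")
  expect_true(is.na(ctx$signed_distance_bp))
})

test_that("exon and intron classification follows the gene structure", {
  g <- genes_from(simple_gene("g", "chr1", "+", 10000, 20000,
                              exons = cbind(start = c(10000L, 19000L),
                                            end = c(10500L, 20000L))))
  expect_equal(annotate_regions(region_df("chr1", 10400, 10450), g)$context, "exon")
  expect_equal(annotate_regions(region_df("chr1", 15000, 15050), g)$context, "intron")
  expect_equal(annotate_regions(region_df("chr1", 13000, 19100), g)$context, "exon")
})

test_that("annotation equals the brute-force all-genes scan", {
  set.seed(37)
  for (r in 1:300) {
    g <- random_gene_models(sample(1:6, 1))
    start <- sample.int(55000, 1)
    reg <- region_df(sample(c("chr1", "chr2"), 1), start,
                     start + sample.int(300, 1))
    got <- annotate_regions(reg, g)$context
    want <- brute_force_annotate(reg, g, 100, 2000)
    expect_equal(got, want)
  }
})

test_that("every region receives exactly one of the five labels", {
  set.seed(41)
  g <- random_gene_models(10)
  starts <- sample.int(60000, 200)
  regs <- region_df(sample(c("chr1", "chr2"), 200, TRUE), starts,
                    starts + sample.int(500, 200, TRUE))
  regs$region_id <- sprintf("r%d", seq_len(200))
  ctx <- annotate_regions(regs, g)
  expect_equal(nrow(ctx), 200L)
  expect_true(all(ctx$context %in% c("TSS", "promoter", "exon", "intron",
                                     "intergenic")))
})

test_that("contexts and distances are invariant under coordinate translation", {
  set.seed(43)
  g <- random_gene_models(6, chroms = "chr1")
  starts <- sample.int(40000, 50)
  regs <- region_df("chr1", starts, starts + 100L)
  ctx1 <- annotate_regions(regs, g)
  shift <- 12345L
  g2 <- g
  g2$tss <- g2$tss + shift
  g2$span_start <- g2$span_start + shift
  g2$span_end <- g2$span_end + shift
  g2$exons <- lapply(g2$exons, function(e) e + shift)
  regs2 <- regs
  regs2$start <- regs2$start + shift
  regs2$end <- regs2$end + shift
  ctx2 <- annotate_regions(regs2, g2)
  expect_equal(ctx1$context, ctx2$context)
  expect_equal(ctx1$signed_distance_bp, ctx2$signed_distance_bp)
})

test_that("context composition tabulates counts and percentages per direction", {
  ctx <- data.frame(region_id = sprintf("r%d", 1:5),
                    context = c("intergenic", "intergenic", "intron", "exon",
                                "TSS"),
                    nearest_gene = "g", signed_distance_bp = 0L,
                    abs_distance_kb = 0, stringsAsFactors = FALSE)
  calls <- data.frame(region_id = sprintf("r%d", 1:5),
                      direction = c(rep("decreased", 4), "increased"),
                      stringsAsFactors = FALSE)
  comp <- context_composition(ctx, calls)
  dec <- comp[comp$direction == "decreased", ]
  expect_equal(dec$count[dec$context == "intergenic"], 2L)
  expect_equal(dec$percent[dec$context == "intergenic"], 50)
  expect_equal(dec$percent[dec$context == "intron"], 25)
  expect_equal(sum(dec$percent), 100)
  inc <- comp[comp$direction == "increased", ]
  expect_equal(sum(inc$count), 1L)
  # empty direction: counts zero, percentages absent
  none <- context_composition(ctx, calls[calls$direction == "increased", ])
  dec0 <- none[none$direction == "decreased", ]
  expect_equal(sum(dec0$count), 0L)
  expect_true(all(is.na(dec0$percent)))
  # unannotated region is an error
  expect_error(context_composition(ctx[-1, ], calls), "r1")
})

test_that("distance summaries report quartiles per group", {
  ctx <- data.frame(region_id = sprintf("r%d", 1:4),
                    context = "intergenic", nearest_gene = "g",
                    signed_distance_bp = c(1000L, 3000L, 5000L, 70L),
                    abs_distance_kb = c(1, 3, 5, 0.07),
                    stringsAsFactors = FALSE)
  ds <- distance_summary(ctx, list(far = c("r1", "r2", "r3"), near = "r4"))
  expect_equal(ds$median[ds$group == "far"], 3)
  near <- ds[ds$group == "near", ]
  expect_equal(near$min, near$max)
  expect_warning(distance_summary(ctx, list(none = character(0))), "empty")
})
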