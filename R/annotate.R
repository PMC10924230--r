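# Priority genomic-context annotation (TSS > promoter > exon > intron >
# intergenic) and signed distance to the nearest transcription start site.
# This mirrors peak-annotation practice (first matching category wins);
# interval overlap goes through IRanges, the nearest-TSS query is a binary
# search with an explicit tie rule.

#' Build a nearest-TSS index
#'
#' @param genes A \code{gene_models} data frame with at least one gene.
#' @return An object of class \code{tss_index}: per chromosome, TSS
#'   positions sorted ascending with strand and gene id. Ties in a
#'   nearest-TSS query are broken toward the lower-coordinate TSS, then
#'   the lexicographically smaller gene id.
#' @export
build_tss_index <- function(genes) {
  if (!inherits(genes, "gene_models")) stopf("genes must be a gene_models object")
  if (nrow(genes) == 0L) stopf("cannot build a TSS index from an empty gene list")
  by_chrom <- split(genes[, c("tss", "strand", "gene_id")], genes$chrom)
  by_chrom <- lapply(by_chrom, function(df) {
    df <- df[order(df$tss, df$gene_id, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  structure(by_chrom, class = "tss_index")
}

#' Query the nearest TSS for genomic points
#'
#' @param index A \code{tss_index}.
#' @param chrom,pos Parallel vectors of query points (1-based bp).
#' @return A data frame: \code{nearest_gene}, \code{tss}, \code{strand},
#'   \code{signed_distance_bp} (negative when the point lies upstream of
#'   the TSS in the gene's orientation), \code{abs_distance_kb}. Rows are
#'   \code{NA} for chromosomes absent from the index.
#' @export
nearest_tss <- function(index, chrom, pos) {
  stopifnot(inherits(index, "tss_index"), length(chrom) == length(pos))
  n <- length(pos)
  gene <- rep(NA_character_, n)
  tss <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    tab <- index[[ch]]
    if (is.null(tab)) next
    sel <- which(chrom == ch)
    p <- pos[sel]
    # rightmost TSS <= p; candidates are i and i+1
    i <- findInterval(p, tab$tss)
    left <- pmax(i, 1L)
    right <- pmin(i + 1L, nrow(tab))
    dl <- abs(p - tab$tss[left])
    dr <- abs(p - tab$tss[right])
    # i == 0: no TSS at or below p, only the right candidate is real
    dl[i == 0L] <- Inf
    # tie in absolute distance -> lower coordinate, i.e. the left candidate;
    # equal-position genes were pre-sorted by gene_id, so 'left' already
    # holds the lexicographically smallest gene at that coordinate
    pick <- ifelse(dl <= dr, left, right)
    gene[sel] <- tab$gene_id[pick]
    tss[sel] <- tab$tss[pick]
    strand[sel] <- tab$strand[pick]
  }
  signed <- ifelse(strand == "+", pos - tss, tss - pos)
  data.frame(nearest_gene = gene, tss = tss, strand = strand,
             signed_distance_bp = as.integer(signed),
             abs_distance_kb = abs(signed) / 1000,
             stringsAsFactors = FALSE)
}

#' Annotate regions with genomic context and TSS distance
#'
#' Priority classification, first match wins:
#' \enumerate{
#'   \item \code{TSS} - the region overlaps \code{[tss - tss_window,
#'     tss + tss_window]} of any gene;
#'   \item \code{promoter} - the region overlaps the strand-aware upstream
#'     band \code{[tss - promoter_window, tss - tss_window - 1]} for a
#'     \code{+} gene (mirrored for \code{-});
#'   \item \code{exon} - the region overlaps any exon;
#'   \item \code{intron} - the region overlaps a transcript span but no
#'     exon;
#'   \item \code{intergenic} - otherwise.
#' }
#' The signed TSS distance is measured from the region midpoint
#' (\code{floor((start + end) / 2)}), negative when the midpoint lies
#' upstream of the nearest TSS in that gene's orientation.
#'
#' @param regions A \code{cpg_regions} data frame (or any data frame with
#'   \code{region_id}, \code{chrom}, \code{start}, \code{end}).
#' @param genes A \code{gene_models} data frame. An empty gene set labels
#'   every region \code{intergenic} with \code{NA} distances.
#' @param tss_window Half-width in bp of the near-TSS window (default 100).
#' @param promoter_window Upstream extent in bp of the promoter band
#'   (default 2000).
#' @return A data frame of class \code{genomic_context}: \code{region_id},
#'   \code{context}, \code{nearest_gene}, \code{signed_distance_bp},
#'   \code{abs_distance_kb}.
#' @export
annotate_regions <- function(regions, genes, tss_window = 100,
                             promoter_window = 2000) {
  stopifnot(is.data.frame(regions))
  if (!is_count_scalar(tss_window) || !is_count_scalar(promoter_window)) {
    stopf("tss_window and promoter_window must be single integers >= 0")
  }
  if (promoter_window <= tss_window) {
    stopf("promoter_window (%d) must exceed tss_window (%d)",
          promoter_window, tss_window)
  }
  n <- nrow(regions)
  context <- rep("intergenic", n)
  if (nrow(genes) > 0L && n > 0L) {
    prom <- promoter_intervals(genes, tss_window, promoter_window)
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      gq <- IRanges::IRanges(regions$start[ri], regions$end[ri])
      gsel <- genes$chrom == ch
      if (!any(gsel)) next
      g <- genes[gsel, , drop = FALSE]
      hit_tss <- IRanges::overlapsAny(
        gq, IRanges::IRanges(pmax(g$tss - tss_window, 1L), g$tss + tss_window))
      p <- prom[prom$chrom == ch & prom$start <= prom$end, , drop = FALSE]
      hit_prom <- if (nrow(p)) {
        IRanges::overlapsAny(gq, IRanges::IRanges(p$start, p$end))
      } else rep(FALSE, length(ri))
      ex <- do.call(rbind, g$exons)
      hit_exon <- IRanges::overlapsAny(
        gq, IRanges::IRanges(ex[, "start"], ex[, "end"]))
      hit_span <- IRanges::overlapsAny(
        gq, IRanges::IRanges(g$span_start, g$span_end))
      context[ri] <- ifelse(hit_tss, "TSS",
                     ifelse(hit_prom, "promoter",
                     ifelse(hit_exon, "exon",
                     ifelse(hit_span, "intron", "intergenic"))))
    }
  }
  mid <- as.integer(floor((as.numeric(regions$start) + regions$end) / 2))
  if (nrow(genes) > 0L) {
    nt <- nearest_tss(build_tss_index(genes), regions$chrom, mid)
  } else {
    nt <- data.frame(nearest_gene = rep(NA_character_, n),
                     signed_distance_bp = rep(NA_integer_, n),
                     abs_distance_kb = rep(NA_real_, n))
  }
  out <- data.frame(region_id = regions$region_id, context = context,
                    nearest_gene = nt$nearest_gene,
                    signed_distance_bp = nt$signed_distance_bp,
                    abs_distance_kb = nt$abs_distance_kb,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_context", "data.frame")
  out
}

# Strand-aware upstream promoter band, clipped to positive coordinates.
#' @keywords internal
#' @noRd
promoter_intervals <- function(genes, tss_window, promoter_window) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - promoter_window, genes$tss + tss_window + 1L)
  end <- ifelse(plus, genes$tss - tss_window - 1L, genes$tss + promoter_window)
  data.frame(chrom = genes$chrom, start = pmax(as.integer(start), 1L),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Context composition of DMR calls by direction
#'
#' For each call direction, tabulates counts and percentages over the five
#' genomic-context labels. Percentages are omitted (NA) for directions with
#' no calls.
#'
#' @param contexts A \code{genomic_context} data frame.
#' @param calls A \code{dmr_calls} data frame; joined to \code{contexts} by
#'   \code{region_id}.
#' @param directions Directions to tabulate (default increased and
#'   decreased).
#' @return A data frame: \code{direction}, \code{context}, \code{count},
#'   \code{percent}; per direction with any calls the percentages sum
#'   to 100.
#' @export
context_composition <- function(contexts, calls,
                                directions = c("increased", "decreased")) {
  labels <- c("TSS", "promoter", "exon", "intron", "intergenic")
  idx <- match(calls$region_id, contexts$region_id)
  if (anyNA(idx)) {
    stopf("region '%s' in calls has no annotation",
          calls$region_id[is.na(idx)][1L])
  }
  ctx <- contexts$context[idx]
  out <- do.call(rbind, lapply(directions, function(d) {
    sub <- ctx[calls$direction == d]
    count <- vapply(labels, function(l) sum(sub == l), 1L)
    percent <- if (length(sub)) 100 * count / length(sub) else rep(NA_real_, 5L)
    data.frame(direction = d, context = labels, count = count,
               percent = percent, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Five-number summary of absolute TSS distances per group
#'
#' @param contexts A \code{genomic_context} data frame.
#' @param grouping A named list of region-id vectors, one entry per group
#'   (e.g. the increased and decreased calls of a comparison). Empty groups
#'   are skipped with a warning.
#' @return A data frame: \code{group}, \code{n}, \code{min}, \code{q1},
#'   \code{median}, \code{q3}, \code{max} (absolute distance in kb).
#' @export
distance_summary <- function(contexts, grouping) {
  stopifnot(is.list(grouping), length(names(grouping)) == length(grouping))
  rows <- lapply(names(grouping), function(g) {
    idx <- match(grouping[[g]], contexts$region_id)
    d <- contexts$abs_distance_kb[idx[!is.na(idx)]]
    d <- d[!is.na(d)]
    if (length(d) == 0L) {
      warnf("distance_summary: group '%s' is empty, skipped", g)
      return(NULL)
    }
    q <- stats::quantile(d, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = g, n = length(d), min = q[1L], q1 = q[2L],
               median = q[3L], q3 = q[4L], max = q[5L],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(group = character(), n = integer(), min = numeric(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      max = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
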