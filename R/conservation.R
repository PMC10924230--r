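# Cross-comparison conservation: how many direction-matched DMRs of one
# comparison overlap DMRs of another. Overlap queries go through an
# IRanges interval index; the brute-force all-pairs scan lives in the test
# suite as the oracle.

#' Do two regions overlap?
#'
#' 1-based inclusive overlap: true iff the regions share at least one base
#' pair on the same chromosome (exact string match).
#'
#' @param a,b Lists or one-row data frames with \code{chrom}, \code{start},
#'   \code{end}.
#' @return Logical scalar.
#' @export
regions_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

# Which query regions overlap >= 1 reference region (optionally requiring a
# minimal reciprocal overlap fraction)?
#' @keywords internal
#' @noRd
overlaps_reference <- function(query, reference, min_reciprocal = 0) {
  hit <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(reference) == 0L) return(hit)
  for (ch in intersect(unique(query$chrom), unique(reference$chrom))) {
    qi <- which(query$chrom == ch)
    ri <- which(reference$chrom == ch)
    qr <- IRanges::IRanges(query$start[qi], query$end[qi])
    rr <- IRanges::IRanges(reference$start[ri], reference$end[ri])
    if (min_reciprocal <= 0) {
      hit[qi] <- IRanges::overlapsAny(qr, rr)
    } else {
      ov <- IRanges::findOverlaps(qr, rr)
      qh <- S4Vectors::queryHits(ov)
      rh <- S4Vectors::subjectHits(ov)
      shared <- IRanges::width(IRanges::pintersect(qr[qh], rr[rh]))
      okq <- shared / IRanges::width(qr)[qh] >= min_reciprocal
      okr <- shared / IRanges::width(rr)[rh] >= min_reciprocal
      hit[qi[unique(qh[okq & okr])]] <- TRUE
    }
  }
  hit
}

#' Conservation of direction-matched DMRs between two comparisons
#'
#' Restricts both call sets to one direction, then counts query regions
#' overlapping at least one same-direction reference region (>= 1 shared
#' bp by default). Because no convention fixes which comparison is the
#' denominator, the fraction is reported in both orientations, together
#' with a Jaccard-style symmetric statistic: the number of conserved
#' regions in either set divided by the total number of regions in both
#' sets.
#'
#' @param query_calls,reference_calls \code{dmr_calls} data frames on the
#'   same genome coordinates.
#' @param direction \code{"increased"} or \code{"decreased"}.
#' @param min_reciprocal Minimum reciprocal overlap fraction in (0, 1\];
#'   the default 0 counts any 1-bp overlap.
#' @return A data frame of class \code{conservation_report} with one row
#'   per orientation: \code{direction}, \code{orientation},
#'   \code{n_query}, \code{n_conserved}, \code{fraction}, \code{jaccard}.
#' @examples
#' s1 <- methylome_sample("a", "control", rep("chr1", 2), c(100, 400),
#'                        c(50, 50), c(50, 50))
#' s2 <- methylome_sample("b", "treatment", rep("chr1", 2), c(100, 400),
#'                        c(90, 10), c(10, 90))
#' m <- filter_scoreable(intersect_common_loci(list(s1, s2)), quiet = TRUE)
#' calls <- call_dmrs(assemble_regions(m), m, comparison_spec("c1", "a", "b"))
#' conserved_fraction(calls, calls, "increased")
#' @export
conserved_fraction <- function(query_calls, reference_calls, direction,
                               min_reciprocal = 0) {
  if (!direction %in% c("increased", "decreased")) {
    stopf("unknown direction '%s' (use 'increased' or 'decreased')", direction)
  }
  if (!is.numeric(min_reciprocal) || min_reciprocal < 0 || min_reciprocal > 1) {
    stopf("min_reciprocal must be in [0, 1]")
  }
  q <- query_calls[query_calls$direction == direction, , drop = FALSE]
  r <- reference_calls[reference_calls$direction == direction, , drop = FALSE]
  q_cons <- sum(overlaps_reference(q, r, min_reciprocal))
  r_cons <- sum(overlaps_reference(r, q, min_reciprocal))
  total <- nrow(q) + nrow(r)
  jac <- if (total > 0) (q_cons + r_cons) / total else NA_real_
  out <- data.frame(
    direction = direction,
    orientation = c("query_vs_reference", "reference_vs_query"),
    n_query = c(nrow(q), nrow(r)),
    n_conserved = c(q_cons, r_cons),
    fraction = c(if (nrow(q)) q_cons / nrow(q) else NA_real_,
                 if (nrow(r)) r_cons / nrow(r) else NA_real_),
    jaccard = jac,
    stringsAsFactors = FALSE)
  class(out) <- c("conservation_report", "data.frame")
  out
}
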