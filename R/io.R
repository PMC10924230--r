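# Readers and writers for the file formats the pipeline touches:
# Bismark CpG coverage tables, gene models (BED12 / minimal GTF) and the
# tab-separated result tables. All coordinates are 1-based inclusive
# internally; BED dialects are converted at the boundary.

#' Read a Bismark CpG coverage table
#'
#' Parses the standard six-column Bismark coverage format (chromosome,
#' start, end, methylation percentage, methylated count, unmethylated
#' count), plain or gzip-compressed (detected by a \code{.gz} suffix).
#' Counts in columns 5-6 are authoritative; the percentage column is only
#' cross-checked and a warning is raised when it disagrees with
#' \code{100 * meth / (meth + unmeth)} by more than 0.5.
#'
#' @param path Path to the coverage file (optionally \code{.gz}).
#' @param sample_id Sample identifier attached to the result.
#' @param group Group label (e.g. \code{"control"} or \code{"treatment"}).
#' @return An object of class \code{methylome_sample}: a list with elements
#'   \code{sample_id}, \code{group} and \code{sites}, where \code{sites} is a
#'   data frame with columns \code{chrom}, \code{pos} (1-based cytosine
#'   position), \code{meth} and \code{unmeth}, sorted by (chrom, pos).
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines(c("chr1\t100\t100\t75\t3\t1", "chr1\t142\t142\t50\t5\t5"), f)
#' s <- read_bismark_coverage(f, "lineA", "control")
#' s$sites
#' @export
read_bismark_coverage <- function(path, sample_id, group) {
  if (!file.exists(path)) stopf("coverage file does not exist: %s", path)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^\\s*(#|track\\b|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        meth = integer(), unmeth = integer(),
                        stringsAsFactors = FALSE)
    return(new_methylome_sample(sample_id, group, sites))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stopf("%s: line %d has %d tab-separated fields, expected 6",
          path, lineno[bad], nf[bad])
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 6L, byrow = TRUE)
  chrom <- m[, 1L]
  pos <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  pct <- suppressWarnings(as.numeric(m[, 4L]))
  meth <- suppressWarnings(as.numeric(m[, 5L]))
  unmeth <- suppressWarnings(as.numeric(m[, 6L]))
  check_int <- function(x, raw, what) {
    bad <- which(is.na(x) | x != floor(x))
    if (length(bad)) {
      stopf("%s: line %d: %s '%s' is not an integer",
            path, lineno[bad[1L]], what, raw[bad[1L]])
    }
  }
  check_int(pos, m[, 2L], "start position")
  check_int(end, m[, 3L], "end position")
  check_int(meth, m[, 5L], "methylated count")
  check_int(unmeth, m[, 6L], "unmethylated count")
  if (any(meth < 0) || any(unmeth < 0)) {
    bad <- which(meth < 0 | unmeth < 0)[1L]
    stopf("%s: line %d: negative read count", path, lineno[bad])
  }
  if (any(pos < 1L)) {
    bad <- which(pos < 1L)[1L]
    stopf("%s: line %d: position %d < 1", path, lineno[bad], pos[bad])
  }
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stopf("%s: duplicate CpG locus %s", path, sub(" ", ":", d))
  }
  cov <- meth + unmeth
  has_cov <- cov > 0 & !is.na(pct)
  off <- abs(pct[has_cov] - 100 * meth[has_cov] / cov[has_cov])
  if (any(off > 0.5)) {
    warnf(paste0("%s: %d line(s) where the reported methylation percentage ",
                 "disagrees with the counts by > 0.5; counts are used"),
          path, sum(off > 0.5))
  }
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      meth = as.integer(meth), unmeth = as.integer(unmeth),
                      stringsAsFactors = FALSE)
  new_methylome_sample(sample_id, group, sites)
}

#' @keywords internal
#' @noRd
new_methylome_sample <- function(sample_id, group, sites) {
  o <- locus_order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group),
                 sites = sites),
            class = "methylome_sample")
}

#' Construct a per-sample methylome from counts
#'
#' Convenience constructor used by the simulator and in tests: builds the
#' same object as [read_bismark_coverage()] from in-memory vectors.
#'
#' @param sample_id,group Identifiers, as in [read_bismark_coverage()].
#' @param chrom,pos,meth,unmeth Parallel vectors of CpG loci and counts.
#' @return A \code{methylome_sample} object.
#' @export
methylome_sample <- function(sample_id, group, chrom, pos, meth, unmeth) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(meth),
            length(meth) == length(unmeth))
  if (any(meth < 0) || any(unmeth < 0)) stopf("negative read count")
  if (any(pos < 1)) stopf("positions must be >= 1")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) stopf("duplicate CpG locus")
  sites <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      meth = as.integer(meth), unmeth = as.integer(unmeth),
                      stringsAsFactors = FALSE)
  new_methylome_sample(sample_id, group, sites)
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("<methylome_sample> %s (group %s): %d CpG sites on %d chromosome(s)\n",
              x$sample_id, x$group, nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' Write a Bismark-format coverage table
#'
#' Inverse of [read_bismark_coverage()]: writes the six-column coverage
#' layout with the percentage column recomputed from the counts. A
#' \code{.gz} suffix triggers gzip compression.
#'
#' @param sample A \code{methylome_sample}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bismark_coverage <- function(sample, path) {
  s <- sample$sites
  cov <- s$meth + s$unmeth
  pct <- ifelse(cov > 0, 100 * s$meth / cov, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", s$chrom, s$pos, s$pos,
                   formatC(pct, format = "f", digits = 4), s$meth, s$unmeth)
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read gene models from BED12 or a minimal GTF
#'
#' Normalizes gene models to 1-based inclusive coordinates and derives the
#' transcription start site per strand: for \code{+} the TSS is the span
#' start, for \code{-} the span end (BED12: \code{chromStart + 1} resp.
#' \code{chromEnd}).
#'
#' @param path Path to the annotation (optionally \code{.gz}).
#' @param dialect \code{"bed12"}, \code{"gtf"}, or \code{"auto"} (by file
#'   extension, \code{.bed} vs \code{.gtf}/\code{.gff}).
#' @return A data frame of class \code{gene_models}, sorted by
#'   (chrom, span_start), with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{span_start}, \code{span_end} and a
#'   list column \code{exons} of two-column matrices (1-based inclusive
#'   start/end per exon).
#' @export
read_gene_models <- function(path, dialect = c("auto", "bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    base <- sub("\\.gz$", "", path)
    dialect <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "bed12"
               else if (grepl("\\.(gtf|gff)$", base, ignore.case = TRUE)) "gtf"
               else stopf("cannot infer annotation dialect from '%s'", path)
  }
  if (!file.exists(path)) stopf("annotation file does not exist: %s", path)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^\\s*(#|track\\b|browser\\b|$)", lines)]
  models <- if (dialect == "bed12") parse_bed12(lines) else parse_gtf_lite(lines)
  finalize_gene_models(models)
}

#' @keywords internal
#' @noRd
parse_bed12 <- function(lines) {
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 12L) stopf("BED12 line %d has %d fields, expected 12", i, length(f))
    strand <- f[6L]
    if (!strand %in% c("+", "-")) stopf("BED12 line %d: unknown strand '%s'", i, strand)
    chrom_start <- as.integer(f[2L])  # 0-based
    chrom_end <- as.integer(f[3L])    # half-open end == 1-based inclusive end
    span_start <- chrom_start + 1L
    span_end <- chrom_end
    n_blocks <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
    starts <- as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stopf("BED12 line %d: blockCount disagrees with block lists", i)
    }
    ex_start <- chrom_start + starts + 1L
    ex_end <- ex_start + sizes - 1L
    if (any(ex_start < span_start) || any(ex_end > span_end)) {
      stopf("BED12 line %d: exon outside transcript span", i)
    }
    list(gene_id = f[4L], chrom = f[1L], strand = strand,
         span_start = span_start, span_end = span_end,
         exons = cbind(start = ex_start, end = ex_end))
  })
}

#' @keywords internal
#' @noRd
parse_gtf_lite <- function(lines) {
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) stopf("GTF line %d has %d fields, expected 9", which(nf < 9L)[1L], nf[nf < 9L][1L])
  m <- do.call(rbind, lapply(fields, function(f) f[1:9]))
  feat <- m[, 3L]
  keep <- feat %in% c("transcript", "exon")
  m <- m[keep, , drop = FALSE]
  feat <- feat[keep]
  attr_id <- function(a) {
    id <- sub('.*transcript_id[ =]+"?([^";]+)"?;?.*', "\\1", a)
    ifelse(id == a, sub('.*gene_id[ =]+"?([^";]+)"?;?.*', "\\1", a), id)
  }
  ids <- attr_id(m[, 9L])
  strand <- m[, 7L]
  if (any(!strand %in% c("+", "-"))) {
    stopf("GTF: unknown strand '%s' for '%s'",
          strand[!strand %in% c("+", "-")][1L], ids[!strand %in% c("+", "-")][1L])
  }
  start <- as.integer(m[, 4L])
  end <- as.integer(m[, 5L])
  out <- list()
  for (id in unique(ids[feat == "transcript"])) {
    tr <- which(ids == id & feat == "transcript")
    if (length(tr) != 1L) stopf("GTF: transcript '%s' defined %d times", id, length(tr))
    ex <- which(ids == id & feat == "exon")
    ex_start <- start[ex]
    ex_end <- end[ex]
    if (any(ex_start < start[tr]) || any(ex_end > end[tr])) {
      stopf("GTF: exon outside transcript span for '%s'", id)
    }
    o <- order(ex_start)
    out[[length(out) + 1L]] <- list(
      gene_id = id, chrom = m[tr, 1L], strand = strand[tr],
      span_start = start[tr], span_end = end[tr],
      exons = cbind(start = ex_start[o], end = ex_end[o]))
  }
  out
}

#' @keywords internal
#' @noRd
finalize_gene_models <- function(models) {
  if (length(models) == 0L) {
    df <- data.frame(gene_id = character(), chrom = character(),
                     strand = character(), tss = integer(),
                     span_start = integer(), span_end = integer(),
                     stringsAsFactors = FALSE)
    df$exons <- list()
    class(df) <- c("gene_models", "data.frame")
    return(df)
  }
  df <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    span_start = vapply(models, function(m) as.integer(m$span_start), 1L),
    span_end = vapply(models, function(m) as.integer(m$span_end), 1L),
    stringsAsFactors = FALSE)
  if (any(df$span_start > df$span_end)) stopf("gene model with span_start > span_end")
  df$tss <- ifelse(df$strand == "+", df$span_start, df$span_end)
  df$exons <- lapply(models, function(m) {
    ex <- m$exons
    storage.mode(ex) <- "integer"
    ex
  })
  o <- locus_order(df$chrom, df$span_start)
  df <- df[o, c("gene_id", "chrom", "strand", "tss", "span_start",
                "span_end", "exons")]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models as BED12
#'
#' @param genes A \code{gene_models} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1L]]
    chrom_start <- g$span_start - 1L  # back to 0-based
    sizes <- paste0(paste(ex[, "end"] - ex[, "start"] + 1L, collapse = ","), ",")
    starts <- paste0(paste(ex[, "start"] - 1L - chrom_start, collapse = ","), ",")
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom, chrom_start, g$span_end, g$gene_id, g$strand,
            chrom_start, g$span_end, nrow(ex), sizes, starts)
  }, "")
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- tabular output ---------------------------------------------------------

#' Write a result table as headered TSV
#'
#' All pipeline outputs go through this writer: tab-separated, header row,
#' 1-based inclusive coordinates, floating-point columns rendered with 4
#' decimal places, and a deterministic row order (chrom, start, then any
#' comparison id column if present).
#'
#' @param records A data frame (list columns are dropped with a message).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv_table <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  is_list <- vapply(df, is.list, TRUE)
  df <- df[, !is_list, drop = FALSE]
  ord <- intersect(c("chrom", "start", "comparison_id"), names(df))
  if (length(ord)) {
    df <- df[do.call(order, c(unname(df[ord]), list(method = "radix"))), ,
             drop = FALSE]
  }
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, format = "f", digits = 4))
  con <- file(path, "wt")
  on.exit(close(con))
  ok <- try(utils::write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stopf("cannot write table to %s", path)
  invisible(path)
}

#' Read a table written by [write_tsv_table()]
#'
#' @param path Path to a headered TSV.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
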