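# End-to-end orchestration from a single config: read coverage tables,
# scoreability filter, region assembly, DMR calling, annotation,
# summaries, cross-comparison conservation, and a structured run log.

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file with the fields documented in
#'   [run_pipeline()].
#' @return The configuration list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file does not exist: %s", path)
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Performs every referential and range check before any heavy I/O and
#' returns all violations, not just the first.
#'
#' @param config A configuration list (see [run_pipeline()]).
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_pipeline_config <- function(config) {
  v <- character(0)
  add <- function(fmt, ...) v <<- c(v, sprintf(fmt, ...))
  samples <- config$samples
  if (is.null(samples) || length(samples) == 0L) {
    add("no samples in manifest")
    samples <- list()
  }
  ids <- vapply(samples, function(s) as.character(s$sample_id %||% ""), "")
  if (anyDuplicated(ids[ids != ""])) {
    add("duplicate sample_id '%s' in manifest", ids[duplicated(ids)][1L])
  }
  for (s in samples) {
    if (is.null(s$sample_id) || !nzchar(s$sample_id)) add("manifest entry without sample_id")
    if (is.null(s$path)) {
      add("sample '%s' has no path", s$sample_id %||% "?")
    } else if (!file.exists(s$path)) {
      add("sample '%s': file not found: %s", s$sample_id %||% "?", s$path)
    }
    if (is.null(s$group) || !nzchar(s$group)) add("sample '%s' has no group", s$sample_id %||% "?")
  }
  comps <- config$comparisons
  if (is.null(comps) || length(comps) == 0L) add("no comparisons specified")
  for (cm in comps) {
    id <- cm$comparison_id %||% "?"
    ctrl <- unlist(cm$control_samples)
    trt <- unlist(cm$treatment_samples)
    if (length(ctrl) == 0L) add("comparison '%s': empty control set", id)
    if (length(trt) == 0L) add("comparison '%s': empty treatment set", id)
    if (length(intersect(ctrl, trt))) {
      add("comparison '%s': control and treatment overlap (%s)", id,
          paste(intersect(ctrl, trt), collapse = ", "))
    }
    for (x in setdiff(c(ctrl, trt), ids)) {
      add("comparison '%s': sample '%s' not in manifest", id, x)
    }
    thr <- cm$delta_threshold %||% config$delta_threshold %||% 5
    if (!is.numeric(thr) || thr <= 0) add("comparison '%s': delta_threshold must be > 0", id)
  }
  for (f in c("max_gap", "min_cov_exclusive", "tss_window", "promoter_window",
              "bin_width")) {
    val <- config[[f]]
    if (!is.null(val) && (!is.numeric(val) || val < 0)) {
      add("%s must be a non-negative number", f)
    }
  }
  if (!is.null(config$annotation) && !is.null(config$annotation$path) &&
      !file.exists(config$annotation$path)) {
    add("annotation file not found: %s", config$annotation$path)
  }
  v
}

#' Run the full DMR pipeline
#'
#' Orchestrates the stages in order: read the sample manifest, intersect
#' to jointly covered loci, apply the scoreability filter, assemble
#' 50-bp-chained regions, call DMRs per comparison, annotate regions and
#' summarize contexts and TSS distances (when an annotation is given),
#' and compute conservation between every pair of comparisons. Writes one
#' TSV per result plus a key=value run log, and returns all results.
#'
#' @param config A list (or path handled by [load_pipeline_config()]) with
#'   fields: \code{samples} (list of \code{sample_id}, \code{group},
#'   \code{path}), \code{comparisons} (list of \code{comparison_id},
#'   \code{control_samples}, \code{treatment_samples}, optional
#'   per-comparison \code{delta_threshold}), optional \code{annotation}
#'   (\code{path}, \code{dialect}), and optional global parameters
#'   \code{min_cov_exclusive} (8), \code{max_gap} (50),
#'   \code{delta_threshold} (5), \code{tss_window} (100),
#'   \code{promoter_window} (2000), \code{bin_width} (5),
#'   \code{out_dir}, \code{force}.
#' @param out_dir Output directory; overrides \code{config$out_dir}.
#' @return An object of class \code{dmr_pipeline} (invisibly): list with
#'   \code{matrix}, \code{regions}, \code{calls} (per comparison),
#'   \code{annotation}, \code{composition}, \code{distances},
#'   \code{conservation}, \code{counts} (the run-log counts) and
#'   \code{files}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  violations <- validate_pipeline_config(config)
  if (length(violations)) {
    stopf("invalid pipeline config:\n%s",
          paste0("  - ", violations, collapse = "\n"))
  }
  out_dir <- out_dir %||% config$out_dir
  write_out <- !is.null(out_dir)
  if (write_out) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L &&
        !isTRUE(config$force)) {
      stopf("output directory '%s' is not empty (set force: true)", out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  log <- c()
  note <- function(key, val) log <<- c(log, sprintf("%s=%s", key, as.character(val)))
  note("rrbsdmr_version", as.character(utils::packageVersion("rrbsdmr")))
  min_cov <- config$min_cov_exclusive %||% 8
  max_gap <- config$max_gap %||% 50
  thr_default <- config$delta_threshold %||% 5
  bin_width <- config$bin_width %||% 5
  note("min_cov_exclusive", min_cov)
  note("max_gap", max_gap)
  note("delta_threshold", thr_default)

  # stage: read
  samples <- lapply(config$samples, function(s) {
    sm <- tryCatch(read_bismark_coverage(s$path, s$sample_id, s$group),
                   error = function(e) stopf("stage read: sample '%s': %s",
                                             s$sample_id, conditionMessage(e)))
    note(paste0("loci_read_", s$sample_id), nrow(sm$sites))
    sm
  })

  # stage: scoreability
  mat <- tryCatch(intersect_common_loci(samples),
                  error = function(e) stopf("stage intersect: %s",
                                            conditionMessage(e)))
  note("loci_common", nrow(mat$loci))
  mat <- filter_scoreable(mat, min_cov_exclusive = min_cov, quiet = TRUE)
  note("loci_scoreable", nrow(mat$loci))

  # stage: regions
  regions <- assemble_regions(mat, max_gap = max_gap,
                              min_cpgs = config$min_cpgs %||% 1)
  note("n_regions", nrow(regions))

  files <- c()
  emit <- function(df, name) {
    if (!write_out) return(invisible(NULL))
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_table(df, p)
    files[name] <<- p
  }
  emit(regions, "regions")

  # stage: annotation (shared across comparisons)
  contexts <- NULL
  if (!is.null(config$annotation)) {
    genes <- read_gene_models(config$annotation$path,
                              dialect = config$annotation$dialect %||% "auto")
    note("n_genes", nrow(genes))
    contexts <- annotate_regions(regions, genes,
                                 tss_window = config$tss_window %||% 100,
                                 promoter_window = config$promoter_window %||% 2000)
    emit(contexts, "annotation")
  }

  # stage: DMR calls per comparison
  calls <- list()
  composition <- list()
  distances <- list()
  for (cm in config$comparisons) {
    spec <- comparison_spec(cm$comparison_id,
                            unlist(cm$control_samples),
                            unlist(cm$treatment_samples),
                            delta_threshold = cm$delta_threshold %||% thr_default,
                            max_gap = max_gap, min_cov_exclusive = min_cov)
    cl <- call_dmrs(regions, mat, spec)
    dirs <- summarize_directions(cl)
    note(paste0("n_increased_", spec$comparison_id), dirs[["increased"]])
    note(paste0("n_decreased_", spec$comparison_id), dirs[["decreased"]])
    note(paste0("n_unchanged_", spec$comparison_id), dirs[["unchanged"]])
    calls[[spec$comparison_id]] <- cl
    emit(as.data.frame(cl), paste0("dmr_calls_", spec$comparison_id))
    emit(delta_histogram(cl, bin_width = bin_width),
         paste0("delta_histogram_", spec$comparison_id))
    emit(delta_histogram(cl[cl$direction != "unchanged", , drop = FALSE],
                         bin_width = bin_width),
         paste0("delta_histogram_called_", spec$comparison_id))
    if (!is.null(contexts)) {
      comp <- context_composition(contexts, cl)
      composition[[spec$comparison_id]] <- comp
      emit(comp, paste0("context_composition_", spec$comparison_id))
      grouping <- list(
        increased = cl$region_id[cl$direction == "increased"],
        decreased = cl$region_id[cl$direction == "decreased"],
        unchanged = cl$region_id[cl$direction == "unchanged"])
      ds <- suppressWarnings(distance_summary(contexts, grouping))
      distances[[spec$comparison_id]] <- ds
      emit(ds, paste0("tss_distance_", spec$comparison_id))
    }
  }

  # stage: conservation across comparison pairs
  conservation <- list()
  cids <- names(calls)
  if (length(cids) >= 2L) {
    for (i in seq_along(cids)) {
      for (j in seq_along(cids)) {
        if (i >= j) next
        rep_list <- lapply(c("increased", "decreased"), function(d) {
          conserved_fraction(calls[[cids[i]]], calls[[cids[j]]], d)
        })
        rep_df <- do.call(rbind, rep_list)
        rep_df <- cbind(query = cids[i], reference = cids[j], rep_df)
        key <- paste0(cids[i], "__", cids[j])
        conservation[[key]] <- rep_df
        for (k in seq_len(nrow(rep_df))) {
          note(sprintf("conserved_%s_%s_%s", key, rep_df$direction[k],
                       rep_df$orientation[k]),
               sprintf("%.6f", rep_df$fraction[k]))
        }
        emit(rep_df, paste0("conservation_", key))
      }
    }
  }

  if (write_out) {
    writeLines(log, file.path(out_dir, "run_log.txt"))
    files["run_log"] <- file.path(out_dir, "run_log.txt")
  }
  res <- structure(list(matrix = mat, regions = regions, calls = calls,
                        annotation = contexts, composition = composition,
                        distances = distances, conservation = conservation,
                        counts = parse_run_log(log), files = files),
                   class = "dmr_pipeline")
  invisible(res)
}

#' @keywords internal
#' @noRd
parse_run_log <- function(lines) {
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' @export
print.dmr_pipeline <- function(x, ...) {
  cat("<dmr_pipeline>\n")
  cat(sprintf("  scoreable loci: %s of %s common\n",
              x$counts[["loci_scoreable"]], x$counts[["loci_common"]]))
  cat(sprintf("  regions: %s\n", x$counts[["n_regions"]]))
  for (id in names(x$calls)) {
    d <- summarize_directions(x$calls[[id]])
    cat(sprintf("  %s: %d increased, %d decreased, %d unchanged\n", id,
                d[["increased"]], d[["decreased"]], d[["unchanged"]]))
  }
  invisible(x)
}
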