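#' Pipeline run configuration
#'
#' Every tunable of the end-to-end analysis, with the defaults the
#' package is designed around: analysis band 0.009-0.08 Hz, threshold
#' grid 0.2-0.6 in steps of 0.1, robust sharp-change detector at z = 5
#' with 0.5 s dilation, differential pathlength factor 6 and 3 cm
#' channels for optical input, clustering on oxy-Hb efficiency features
#' at threshold 0.4.
#'
#' @param band two Hz values, band-pass edges.
#' @param delta_grid correlation thresholds, each in `[0, 1)`.
#' @param z_threshold,dilation_s sharp-change detector settings.
#' @param dpf,distance_cm modified Beer-Lambert parameters for optical
#'   input.
#' @param cluster_chromophore,cluster_delta feature source for K-means
#'   subtyping; `cluster_delta` must be on `delta_grid`.
#' @param alpha significance level for the conditional partial-correlation
#'   rule (default 0.05).
#' @param demean_segments de-mean retained segments at excision
#'   (default `TRUE`).
#' @param detrend_segments remove retained segments' linear trends at
#'   excision (default `TRUE`; implies de-meaning).
#' @param seed integer seed for the clustering restarts.
#' @return list of class `run_config`.
#' @export
run_config <- function(band = c(0.009, 0.08),
                       delta_grid = seq(0.2, 0.6, by = 0.1),
                       z_threshold = 5, dilation_s = 0.5,
                       dpf = 6, distance_cm = 3,
                       cluster_chromophore = "oxy", cluster_delta = 0.4,
                       alpha = 0.05, demean_segments = TRUE,
                       detrend_segments = TRUE, seed = 1L) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be an increasing pair of positive frequencies")
  if (length(delta_grid) == 0 || any(delta_grid < 0) || any(delta_grid >= 1))
    stop("delta_grid entries must lie in [0, 1)")
  if (!cluster_chromophore %in% c("oxy", "deoxy", "total"))
    stop("cluster_chromophore must be oxy, deoxy or total")
  if (!any(abs(delta_grid - cluster_delta) < 1e-9))
    stop("cluster_delta must be one of the delta_grid values")
  structure(list(band = band, delta_grid = delta_grid,
                 z_threshold = z_threshold, dilation_s = dilation_s,
                 dpf = dpf, distance_cm = distance_cm,
                 cluster_chromophore = cluster_chromophore,
                 cluster_delta = cluster_delta, alpha = alpha,
                 demean_segments = demean_segments,
                 detrend_segments = detrend_segments, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages, in fixed order, per subject: optional inverse Beer-Lambert
#' conversion (for `od_recording` input), sharp-change detection,
#' excision of invalid samples, band-pass filtering; then per chromophore
#' a Pearson correlation matrix and the efficiency sweep over the
#' threshold grid. Across subjects: step 1 tests the bivariate age-ABC
#' correlation -- if it is significant at `alpha`, every step-2
#' association (efficiency vs age and vs ABC) is a first-order partial
#' correlation controlling the other covariate, otherwise bivariate --
#' followed by K-means subtyping on the configured efficiency features
#' with a pooled t-test on ABC totals between subtypes.
#'
#' @param recordings named list (names = subject ids) of `hb_recording`
#'   or `od_recording` objects.
#' @param cohort data.frame with `subject_id`, `age_years`, `abc_total`.
#' @param config a `run_config`.
#' @param out_dir optional directory; when given, writes
#'   `efficiency.csv`, `associations.csv`, `clusters.csv`,
#'   `quality.json`, `config.yaml` and `run_log.txt` there.
#' @return list of class `pipeline_result`: `efficiency` (long
#'   data.frame), `associations`, `clusters` (data.frame), `cluster_test`
#'   (`cluster_result`), `step1` (`assoc_result`), `use_partial`,
#'   `quality` (data.frame), `log` (character).
#' @export
run_pipeline <- function(recordings, cohort, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(recordings) < 4) stop("at least 4 subjects are required")
  ids <- names(recordings)
  if (is.null(ids) || any(ids == ""))
    stop("recordings must be a named list keyed by subject id")
  missing_subj <- setdiff(ids, cohort$subject_id)
  if (length(missing_subj))
    stop("cohort table lacks rows for subject(s): ",
         paste(missing_subj, collapse = ", "))
  for (col in c("age_years", "abc_total"))
    if (!col %in% names(cohort))
      stop("cohort table is missing column: ", col)

  log_lines <- sprintf("pipeline started: %d subjects, band %.3g-%.3g Hz, grid {%s}",
                       length(ids), config$band[1], config$band[2],
                       paste(config$delta_grid, collapse = ", "))
  eff_rows <- list()
  quality_rows <- list()
  for (id in ids) {
    rec <- recordings[[id]]
    stage <- "input"
    res <- tryCatch({
      if (inherits(rec, "od_recording")) {
        stage <- "mbll_inverse"
        rec <- mbll_inverse(rec, dpf = config$dpf,
                            distance = config$distance_cm)
      }
      stage <- "detect_sharp_changes"
      rec$valid_mask <- detect_sharp_changes(
        rec, z_threshold = config$z_threshold,
        dilation = round(config$dilation_s / rec$sampling_interval))
      stage <- "excise"
      ex <- excise(rec, demean_segments = config$demean_segments,
                   detrend_segments = config$detrend_segments)
      stage <- "bandpass"
      filtered <- bandpass(ex$recording, config$band[1], config$band[2])
      stage <- "network"
      eff <- do.call(rbind, lapply(c("oxy", "deoxy", "total"), function(ch) {
        cm <- correlation_matrix(filtered, ch)
        cbind(subject_id = id, efficiency_sweep(cm, config$delta_grid))
      }))
      list(eff = eff, report = ex$report)
    }, error = function(e) {
      stop(sprintf("stage '%s' failed for subject %s: %s", stage, id,
                   conditionMessage(e)), call. = FALSE)
    })
    eff_rows[[id]] <- res$eff
    quality_rows[[id]] <- data.frame(
      subject_id = id,
      excluded_fraction = res$report$excluded_fraction,
      retained_duration_min = res$report$retained_duration_min)
  }
  efficiency <- do.call(rbind, eff_rows)
  rownames(efficiency) <- NULL
  quality <- do.call(rbind, quality_rows)
  rownames(quality) <- NULL
  log_lines <- c(log_lines, sprintf(
    "preprocessing: mean excluded fraction %.3f, mean retained %.2f min",
    mean(quality$excluded_fraction), mean(quality$retained_duration_min)))

  cohort_used <- cohort[match(ids, cohort$subject_id), ]
  step1 <- pearson_assoc(cohort_used$age_years, cohort_used$abc_total)
  use_partial <- step1$p < config$alpha
  log_lines <- c(log_lines, sprintf(
    "step 1: age-ABC r(%d) = %.3f, p = %.4g -> step 2 uses %s correlation",
    step1$n, step1$r, step1$p,
    if (use_partial) "partial" else "bivariate"))

  associations <- rbind(
    association_sweep(efficiency, cohort_used, outcome = "age",
                      control = if (use_partial) "abc" else NULL),
    association_sweep(efficiency, cohort_used, outcome = "abc",
                      control = if (use_partial) "age" else NULL))

  feat <- efficiency[efficiency$chromophore == config$cluster_chromophore &
                       abs(efficiency$delta - config$cluster_delta) < 1e-9, ]
  feat <- feat[match(ids, feat$subject_id), ]
  cluster_test <- kmeans_subtype(feat[c("e_glob", "e_loc")],
                                 abc_total = cohort_used$abc_total,
                                 seed = config$seed)
  clusters <- data.frame(subject_id = ids,
                         cluster_label = as.character(cluster_test$labels))
  log_lines <- c(log_lines, sprintf(
    "clustering (%s, delta = %.1f): Type I n = %d, Type II n = %d, ABC t = %.3f, p = %.4g",
    config$cluster_chromophore, config$cluster_delta,
    cluster_test$sizes[1], cluster_test$sizes[2],
    cluster_test$t_stat, cluster_test$p))

  result <- structure(
    list(efficiency = efficiency, associations = associations,
         clusters = clusters, cluster_test = cluster_test,
         step1 = step1, use_partial = use_partial,
         quality = quality, log = log_lines, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write a pipeline result bundle to a directory
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(result$efficiency, file.path(out_dir, "efficiency.csv"))
  data.table::fwrite(result$associations, file.path(out_dir, "associations.csv"))
  data.table::fwrite(result$clusters, file.path(out_dir, "clusters.csv"))
  jsonlite::write_json(result$quality, file.path(out_dir, "quality.json"),
                       dataframe = "rows", digits = NA)
  cfg <- unclass(result$config)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
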