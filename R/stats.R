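#' Significance band of a p-value
#'
#' The reporting convention used throughout the analysis: `significant`
#' for p < 0.05, `marginal` for 0.05 <= p < 0.1, `ns` otherwise. No
#' multiple-comparison correction is applied anywhere in the package, by
#' design: efficiencies at different thresholds and chromophores are
#' treated as distinct topologies.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of bands.
#' @export
significance_band <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.1, "marginal", "ns"))
}

assoc_result <- function(r, p, n, df, controlled = "none") {
  structure(list(r = unname(r), p = unname(p), n = n, df = df,
                 controlled = controlled,
                 significance_band = significance_band(p)),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  ctl <- if (identical(x$controlled, "none")) "" else
    sprintf(" | %s", x$controlled)
  cat(sprintf("r(%d)%s = %.3f, p = %.4g [%s]\n", x$n, ctl, x$r, x$p,
              x$significance_band))
  invisible(x)
}

#' Bivariate Pearson correlation with two-tailed p-value
#'
#' Sample Pearson correlation and its two-tailed test on
#' `t = r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom
#' (delegated to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite, each with
#'   positive variance.
#' @return an `assoc_result`: `r`, `p`, `n`, `df`, `controlled = "none"`,
#'   `significance_band`.
#' @export
pearson_assoc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("at least 3 observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input")
  ct <- stats::cor.test(x, y)
  assoc_result(r = ct$estimate, p = ct$p.value, n = n, df = n - 2L)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single control variable `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' equal to the Pearson correlation of the residuals of `x` and `y` each
#' regressed on `z`. Two-tailed p-value from the t distribution with
#' `n - 3` degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length `n >= 4`.
#' @param control_name label recorded in the result (default `"z"`).
#' @return an `assoc_result` with `controlled = control_name`.
#' @export
partial_correlation <- function(x, y, z, control_name = "z") {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("at least 4 observations are required (df = n - 3 >= 1)")
  if (!all(is.finite(c(x, y, z)))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("correlation undefined: zero variance input")
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate control: z is collinear with x or y")
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- min(1, max(-1, r))
  df <- n - 3L
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df)
  }
  assoc_result(r = r, p = p, n = n, df = df, controlled = control_name)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t statistic with pooled variance and
#' `df = n_a + n_b - 2`, two-tailed (delegated to
#' [stats::t.test()] with `var.equal = TRUE`).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                 error = function(e) stop("t-test failed: ", conditionMessage(e),
                                          call. = FALSE))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Association sweep: efficiency vs an outcome over the threshold grid
#'
#' For every (chromophore, threshold, metric) cell of an efficiency table,
#' correlates that efficiency across subjects with an outcome variable
#' (ABC total or age), optionally partialling out a control covariate.
#' No multiple-comparison correction is applied.
#'
#' @param efficiency data.frame with columns `subject_id`, `chromophore`,
#'   `delta`, `e_glob`, `e_loc` (one row per subject x chromophore x
#'   threshold); every subject must have every cell.
#' @param cohort data.frame with `subject_id` and the outcome/control
#'   columns (`abc_total`, `age_years`).
#' @param outcome `"abc"` or `"age"`.
#' @param control `NULL` for bivariate correlation, or `"age"`/`"abc"`
#'   for a first-order partial correlation.
#' @return data.frame with one row per cell: `chromophore`, `delta`,
#'   `metric`, `outcome`, `r`, `p`, `n`, `df`, `method`, `controlled`,
#'   `band`.
#' @export
association_sweep <- function(efficiency, cohort, outcome = c("abc", "age"),
                              control = NULL) {
  outcome <- match.arg(outcome)
  var_of <- c(abc = "abc_total", age = "age_years")
  need <- c("subject_id", var_of[[outcome]],
            if (!is.null(control)) var_of[[control]])
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  cells <- unique(efficiency[c("chromophore", "delta")])
  counts <- table(efficiency$subject_id)
  if (length(unique(counts)) > 1 || any(counts != nrow(cells))) {
    bad <- names(counts)[counts != nrow(cells)]
    stop("incomplete efficiency cells for subject(s): ",
         paste(bad, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- efficiency[efficiency$chromophore == cells$chromophore[i] &
                        efficiency$delta == cells$delta[i], ]
    sub <- merge(sub, cohort, by = "subject_id")
    for (metric in c("e_glob", "e_loc")) {
      n_sub <- nrow(sub)
      res <- if (stats::sd(sub[[metric]]) == 0) {
        # e.g. a threshold at which every subject's graph is empty or
        # complete: the association is undefined, reported as NA
        assoc_result(r = NA_real_, p = NA_real_, n = n_sub,
                     df = n_sub - (if (is.null(control)) 2L else 3L),
                     controlled = if (is.null(control)) "none" else control)
      } else if (is.null(control)) {
        pearson_assoc(sub[[metric]], sub[[var_of[[outcome]]]])
      } else {
        partial_correlation(sub[[metric]], sub[[var_of[[outcome]]]],
                            sub[[var_of[[control]]]],
                            control_name = control)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chromophore = cells$chromophore[i], delta = cells$delta[i],
        metric = metric, outcome = outcome, r = res$r, p = res$p,
        n = res$n, df = res$df,
        method = if (is.null(control)) "bivariate" else "partial",
        controlled = res$controlled, band = res$significance_band)
    }
  }
  do.call(rbind, rows)
}

#' K-means subtyping on efficiency features
#'
#' Splits subjects into two clusters by K-means on z-scored
#' (E_glob, E_loc) features, with many seeded restarts for determinism.
#' The cluster with the higher mean raw E_glob is labeled `Type I`
#' (higher-efficiency subtype), the other `Type II`, regardless of
#' internal cluster numbering; a pooled-variance t-test compares ABC
#' totals between the two labels when provided.
#'
#' @param features data.frame or matrix with columns `e_glob`, `e_loc`,
#'   one row per subject (>= 4 rows, finite, not all identical).
#' @param abc_total optional numeric vector of ABC totals (same order).
#' @param seed integer seed for the restarts (default 1).
#' @param n_start number of K-means restarts (default 50).
#' @return list of class `cluster_result`: `labels` (factor
#'   `Type I`/`Type II`), `centroids` (2 x 2, original scale), `sizes`,
#'   and -- when `abc_total` is given -- `t_stat`, `p`, `abc_means`.
#' @export
kmeans_subtype <- function(features, abc_total = NULL, seed = 1L,
                           n_start = 50L) {
  features <- as.data.frame(features)
  if (!all(c("e_glob", "e_loc") %in% names(features)))
    stop("features must have columns e_glob and e_loc")
  fm <- as.matrix(features[c("e_glob", "e_loc")])
  if (nrow(fm) < 4) stop("at least 4 subjects are required")
  if (!all(is.finite(fm))) stop("features must be finite")
  sds <- apply(fm, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate clustering: all features identical")
  fz <- fm[, sds > 0, drop = FALSE]
  fz <- scale(fz)
  set.seed(seed)
  km <- stats::kmeans(fz, centers = 2, nstart = n_start)
  mean_eglob <- tapply(fm[, "e_glob"], km$cluster, mean)
  type1 <- as.integer(names(which.max(mean_eglob)))
  labels <- factor(ifelse(km$cluster == type1, "Type I", "Type II"),
                   levels = c("Type I", "Type II"))
  centroids <- rbind(`Type I` = colMeans(fm[labels == "Type I", , drop = FALSE]),
                     `Type II` = colMeans(fm[labels == "Type II", , drop = FALSE]))
  out <- list(labels = labels, centroids = centroids,
              sizes = c(`Type I` = sum(labels == "Type I"),
                        `Type II` = sum(labels == "Type II")))
  if (!is.null(abc_total)) {
    if (length(abc_total) != nrow(fm))
      stop("abc_total must have one value per subject")
    if (min(out$sizes) >= 2) {
      tt <- two_sample_t(abc_total[labels == "Type II"],
                         abc_total[labels == "Type I"])
      out$t_stat <- tt$t
      out$p <- tt$p
    } else {
      warning("a cluster has fewer than 2 subjects; ABC t-test skipped")
      out$t_stat <- NA_real_
      out$p <- NA_real_
    }
    out$abc_means <- c(`Type I` = mean(abc_total[labels == "Type I"]),
                       `Type II` = mean(abc_total[labels == "Type II"]))
  }
  structure(out, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> Type I n = %d, Type II n = %d\n",
              x$sizes[1], x$sizes[2]))
  if (!is.null(x$t_stat))
    cat(sprintf("  ABC total Type II vs Type I: t = %.3f, p = %.4g\n",
                x$t_stat, x$p))
  invisible(x)
}
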