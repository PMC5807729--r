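#' Cohort specification for synthetic study populations
#'
#' Describes the simulated clinical sample: its size, age distribution,
#' the distribution of Autism Behavior Checklist (ABC) totals, the target
#' age-ABC correlation, and the planted links from severity and age to
#' each subject's ground-truth connectivity density. Defaults reproduce
#' the study conditions the package is designed around: 46 children aged
#' 2.0-8.9 years, ABC totals with mean 61.33, SD 21.79, range 33-119, an
#' age-ABC correlation of 0.51, and a negative severity-to-connectivity
#' effect (more severe behavior, sparser planted network, hence lower
#' network efficiency downstream) with no direct age effect.
#'
#' @param n_subjects cohort size (default 46; must be >= 4 so a
#'   first-order partial correlation has df >= 1).
#' @param age_range years, default `c(2.0, 8.9)`; ages drawn uniformly.
#' @param abc_mean,abc_sd,abc_range ABC total score distribution targets
#'   (defaults 61.33, 21.79, `c(33, 119)`; totals are rounded and clipped
#'   to the range).
#' @param age_abc_corr target Pearson correlation between age and ABC
#'   total (default 0.51); must be in `[-1, 1]`.
#' @param efficiency_abc_effect planted slope of connectivity density per
#'   SD of ABC total (default -0.12).
#' @param efficiency_age_effect planted slope of density per SD of age
#'   (default 0).
#' @param density_base mean planted density (default 0.35).
#' @param density_noise_sd subject-level density noise SD (default 0.03).
#' @param n_channels nodes per subject network (default 44).
#' @param sex_ratio probability a subject is male (default 36/46).
#' @param seed integer seed (default 1).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 46L,
                        age_range = c(2.0, 8.9),
                        abc_mean = 61.33, abc_sd = 21.79,
                        abc_range = c(33, 119),
                        age_abc_corr = 0.51,
                        efficiency_abc_effect = -0.12,
                        efficiency_age_effect = 0,
                        density_base = 0.35,
                        density_noise_sd = 0.03,
                        n_channels = 44L,
                        sex_ratio = 36 / 46,
                        seed = 1L) {
  if (n_subjects < 4L)
    stop("n_subjects must be >= 4 (partial correlation needs df = n - 3 >= 1)")
  if (abs(age_abc_corr) > 1)
    stop("age_abc_corr is an infeasible correlation target (|r| > 1)")
  max_total <- sum(abc_weight_table()$weight)
  if (abc_range[1] < 0 || abc_range[2] > max_total)
    stop(sprintf("abc_range must lie within [0, %d]", max_total))
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 abc_mean = abc_mean, abc_sd = abc_sd, abc_range = abc_range,
                 age_abc_corr = age_abc_corr,
                 efficiency_abc_effect = efficiency_abc_effect,
                 efficiency_age_effect = efficiency_age_effect,
                 density_base = density_base,
                 density_noise_sd = density_noise_sd,
                 n_channels = as.integer(n_channels),
                 sex_ratio = sex_ratio, seed = seed),
            class = "cohort_spec")
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' Draws ages and ABC totals with the specified correlation (the ABC
#' deviate is orthogonalized against age before mixing, so the planted
#' sample correlation is exact up to rounding/clipping of the scores),
#' derives each subject's ground-truth connectivity density from the
#' planted severity and age slopes plus noise, realizes a clique-union
#' graph at that density, and (optionally) simulates the corresponding
#' hemoglobin recording with motion artifacts. Everything needed to score
#' downstream recovery -- densities, graphs, clean/contaminated truth
#' masks, per-subject seeds -- is returned.
#'
#' @param spec a `cohort_spec`.
#' @param signal a `signal_params`; its `seed` is ignored (per-subject
#'   sub-seeds are derived from `spec$seed`).
#' @param recordings if `FALSE`, skip signal simulation and return only
#'   the cohort table and ground truth (fast; useful for calibration
#'   studies of the statistical stages).
#' @return list with `recordings` (named list of `hb_recording` or
#'   `NULL`), `cohort` (data.frame: `subject_id`, `age_years`, `sex`,
#'   `abc_total`, five `abc_<area>` subscale columns) and `truth` (list:
#'   `density`, `graphs`, `truth_masks`, `subject_seeds`).
#' @export
generate_cohort <- function(spec = cohort_spec(), signal = signal_params(),
                            recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects

  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  z_age <- as.numeric(scale(age))
  eps <- stats::rnorm(n)
  eps <- stats::residuals(stats::lm(eps ~ z_age))
  z_eps <- as.numeric(scale(eps))
  rho <- spec$age_abc_corr
  abc_latent <- rho * z_age + sqrt(max(0, 1 - rho^2)) * z_eps
  abc <- round(spec$abc_mean + spec$abc_sd * abc_latent)
  abc <- pmin(pmax(abc, spec$abc_range[1]), spec$abc_range[2])

  z_abc <- as.numeric(scale(abc))
  density <- spec$density_base +
    spec$efficiency_abc_effect * z_abc +
    spec$efficiency_age_effect * z_age +
    stats::rnorm(n, 0, spec$density_noise_sd)
  density <- pmin(pmax(density, 0.02), 0.9)

  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
  subject_seeds <- matrix(sample.int(2147483646L, 3L * n), ncol = 3L)

  graphs <- vector("list", n)
  recs <- if (recordings) vector("list", n) else NULL
  masks <- vector("list", n)
  subscales <- matrix(0, n, 5)
  abc_total <- numeric(n)
  ids <- sprintf("S%02d", seq_len(n))
  areas <- levels(abc_weight_table()$area)

  for (i in seq_len(n)) {
    graphs[[i]] <- generate_graph(spec$n_channels, density[i],
                                  seed = subject_seeds[i, 1], model = "cliques")
    items <- generate_abc_items(abc[i], seed = subject_seeds[i, 2])
    sc <- score_abc(items)
    abc_total[i] <- sc$total
    subscales[i, ] <- sc$subscale[areas]
    if (recordings) {
      p_i <- signal
      p_i$seed <- subject_seeds[i, 3]
      rec <- generate_hemoglobin(graphs[[i]], p_i)
      art <- inject_artifacts(rec, p_i)
      recs[[i]] <- art$recording
      masks[[i]] <- art$truth_mask
    }
  }
  if (recordings) names(recs) <- ids

  cohort <- data.frame(subject_id = ids, age_years = age, sex = sex,
                       abc_total = abc_total)
  colnames(subscales) <- paste0("abc_", areas)
  cohort <- cbind(cohort, as.data.frame(subscales))

  list(recordings = recs, cohort = cohort,
       truth = list(density = density, graphs = graphs,
                    truth_masks = masks, subject_seeds = subject_seeds))
}
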