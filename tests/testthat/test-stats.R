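test_that("Pearson association recovers exact linear relations and known p-values", {
  x <- rnorm(20)
  expect_equal(pearson_assoc(x, 3 * x + 2)$r, 1)
  expect_equal(pearson_assoc(x, -0.5 * x + 1)$r, -1)

  # r = 0.51 at n = 46 is highly significant
  set.seed(31)
  repeat {
    a <- rnorm(46)
    b <- 0.51 * scale(a)[, 1] + sqrt(1 - 0.51^2) * scale(resid(lm(rnorm(46) ~ a)))[, 1]
    if (abs(cor(a, b) - 0.51) < 1e-6) break
  }
  res <- pearson_assoc(a, b)
  expect_equal(res$r, 0.51, tolerance = 1e-5)
  expect_lt(res$p, 0.001)
  expect_equal(res$df, 44)
  expect_equal(res$significance_band, "significant")

  expect_error(pearson_assoc(x, rep(1, 20)), "zero variance")
  expect_error(pearson_assoc(x[1:2], x[1:2]), "at least 3")
})

test_that("partial correlation matches its closed form and the residual oracle", {
  # constructed data with r_xy = r_xz = r_yz = 0.5 -> r_xy.z = 1/3
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  L <- chol(S)
  set.seed(32)
  Z <- scale(matrix(rnorm(3 * 2000), ncol = 3), center = TRUE, scale = FALSE)
  X <- qr.Q(qr(Z)) %*% L  # columns mean-zero, exact sample correlation S
  res <- partial_correlation(X[, 1], X[, 2], X[, 3])
  expect_equal(res$r, 1 / 3, tolerance = 1e-10)
  expect_equal(res$df, nrow(X) - 3)

  for (s in 1:100) {
    set.seed(4000 + s)
    n <- sample(8:40, 1)
    x <- rnorm(n); z <- rnorm(n)
    y <- 0.5 * z + rnorm(n)
    x <- x + 0.3 * z
    expect_equal(partial_correlation(x, y, z)$r,
                 partial_corr_oracle(x, y, z), tolerance = 1e-10)
  }
})

test_that("a control collinear with an input is rejected as degenerate", {
  set.seed(33)
  x <- rnorm(10); y <- rnorm(10)
  expect_error(partial_correlation(x, y, y), "degenerate")
  expect_error(partial_correlation(x, y, rnorm(9)), "equal length")
  expect_error(partial_correlation(x[1:3], y[1:3], x[1:3] * 2), "at least 4")
})

test_that("uncorrelated control leaves the correlation unchanged", {
  set.seed(34)
  n <- 5000
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); z <- rnorm(n)
  expect_equal(partial_correlation(x, y, z)$r, cor(x, y), tolerance = 0.05)
})

test_that("null-case type-I error of the association tests is near nominal", {
  set.seed(35)
  n_rep <- 1000
  hits_p <- hits_b <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
    hits_b[i] <- pearson_assoc(x, y)$p < 0.05
    hits_p[i] <- partial_correlation(x, y, z)$p < 0.05
  }
  tol <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(hits_b) - 0.05), tol)
  expect_lt(abs(mean(hits_p) - 0.05), tol)
})

test_that("the pooled t-test matches hand computation", {
  same <- c(1, 2, 3, 4)
  res0 <- two_sample_t(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$t), 3 / (1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "t-test failed")
})

test_that("K-means subtyping recovers separated groups and labels by efficiency", {
  set.seed(36)
  f <- data.frame(e_glob = c(rnorm(10, 0.8, 0.02), rnorm(12, 0.3, 0.02)),
                  e_loc = c(rnorm(10, 0.7, 0.02), rnorm(12, 0.2, 0.02)))
  truth <- rep(c("Type I", "Type II"), c(10, 12))
  res <- kmeans_subtype(f, seed = 2)
  expect_equal(as.character(res$labels), truth)
  expect_gt(res$centroids["Type I", "e_glob"], res$centroids["Type II", "e_glob"])

  # invariant to subject order and affine feature rescaling
  perm <- sample(22)
  res_perm <- kmeans_subtype(f[perm, ], seed = 2)
  expect_equal(as.character(res_perm$labels), truth[perm])
  f_scaled <- data.frame(e_glob = 100 * f$e_glob - 3, e_loc = 0.01 * f$e_loc + 5)
  res_scaled <- kmeans_subtype(f_scaled, seed = 2)
  expect_equal(as.character(res_scaled$labels), as.character(res$labels))

  expect_error(kmeans_subtype(f[1:3, ]), "at least 4")
  expect_error(kmeans_subtype(data.frame(e_glob = rep(1, 6),
                                         e_loc = rep(2, 6))),
               "degenerate")
})

test_that("the ABC t-test attached to clustering compares Type II against Type I", {
  set.seed(37)
  f <- data.frame(e_glob = c(rnorm(8, 0.8, 0.02), rnorm(8, 0.3, 0.02)),
                  e_loc = c(rnorm(8, 0.7, 0.02), rnorm(8, 0.2, 0.02)))
  abc <- c(rnorm(8, 45, 5), rnorm(8, 80, 5))  # severe cases in low-eff group
  res <- kmeans_subtype(f, abc_total = abc, seed = 3)
  expect_gt(res$t_stat, 0)   # Type II mean higher
  expect_lt(res$p, 0.001)
  expect_lt(res$abc_means["Type I"], res$abc_means["Type II"])
})

test_that("association sweep produces one row per cell and validates inputs", {
  set.seed(38)
  n <- 12
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:n),
                       age_years = runif(n, 2, 9),
                       abc_total = sample(33:119, n))
  eff <- expand.grid(subject_id = cohort$subject_id,
                     chromophore = c("oxy", "deoxy", "total"),
                     delta = seq(0.2, 0.6, by = 0.1),
                     stringsAsFactors = FALSE)
  eff$e_glob <- runif(nrow(eff))
  eff$e_loc <- runif(nrow(eff))
  out <- association_sweep(eff, cohort, outcome = "abc", control = "age")
  expect_equal(nrow(out), 30)  # 3 chromophores x 5 deltas x 2 metrics
  expect_true(all(out$method == "partial"))
  expect_true(all(out$df == n - 3))

  out_biv <- association_sweep(eff, cohort, outcome = "age")
  expect_true(all(out_biv$method == "bivariate"))
  expect_true(all(out_biv$df == n - 2))

  # a degenerate cell (zero variance across subjects) yields NA, not an abort
  eff_flat <- eff
  eff_flat$e_glob[eff_flat$chromophore == "deoxy" & eff_flat$delta == 0.6] <- 0
  out_flat <- association_sweep(eff_flat, cohort, "abc", "age")
  na_row <- out_flat$chromophore == "deoxy" & out_flat$delta == 0.6 &
    out_flat$metric == "e_glob"
  expect_true(all(is.na(out_flat$r[na_row])))
  expect_true(all(!is.na(out_flat$r[out_flat$metric == "e_loc" &
                                      out_flat$chromophore == "oxy"])))

  expect_error(association_sweep(eff[-1, ], cohort, "abc", "age"),
               "incomplete efficiency cells")
  expect_error(association_sweep(eff, cohort[c("subject_id", "age_years")],
                                 "abc", "age"),
               "missing column")
})
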