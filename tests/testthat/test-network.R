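test_that("correlation matrices are symmetric with unit diagonal and catch duplicates", {
  rec <- noise_recording(5, 400, seed = 21)
  rec$oxy[2, ] <- rec$oxy[1, ]  # duplicated channel
  r <- correlation_matrix(rec, "oxy")
  expect_equal(unname(r[1, 2]), 1)
  expect_true(isSymmetric(unclass(r)))
  expect_equal(unname(diag(r)), rep(1, 5))
})

test_that("a 44-channel recording yields 946 distinct channel pairs", {
  rec <- noise_recording(44, 100, seed = 22)
  r <- correlation_matrix(rec, "oxy")
  expect_equal(sum(upper.tri(r)), 946)
})

test_that("independent long noise series are near-uncorrelated", {
  rec <- noise_recording(2, 1e4, seed = 23)
  r <- correlation_matrix(rec, "oxy")
  expect_lt(abs(r[1, 2]), 0.05)
})

test_that("zero-variance channels get zero correlation with a warning", {
  rec <- noise_recording(3, 100, seed = 24)
  rec$oxy[3, ] <- 7
  expect_warning(r <- correlation_matrix(rec, "oxy"), "zero-variance")
  expect_true(all(r[3, -3] == 0))
  expect_equal(unname(r[3, 3]), 1)
})

test_that("binarization uses a strict absolute threshold", {
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.45
  cm[1, 3] <- cm[3, 1] <- -0.45
  cm[2, 3] <- cm[3, 2] <- 0.4
  g4 <- binarize(cm, 0.4)
  expect_true(g4[1, 2])          # 0.45 > 0.4
  expect_true(g4[1, 3])          # |-0.45| > 0.4
  expect_false(g4[2, 3])         # 0.4 is not > 0.4 (strict)
  g5 <- binarize(cm, 0.5)
  expect_false(g5[1, 2])
  expect_true(all(!diag(g4)))
  expect_error(binarize(cm, 1), "delta")
})

test_that("BFS path lengths match closed forms and the Floyd-Warshall oracle", {
  K4 <- 1 - diag(4)
  expect_true(all(shortest_paths(K4)[upper.tri(K4)] == 1))
  P3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(shortest_paths(P3)[1, 3], 2)
  disconnected <- adj_from_edges(4, list(c(1, 2)))
  expect_true(is.infinite(shortest_paths(disconnected)[1, 3]))

  for (s in 1:100) {
    n <- sample(2:12, 1)
    A <- rand_adj(n, runif(1, 0.1, 0.9), seed = s)
    expect_equal(shortest_paths(A), floyd_warshall(A))
  }
})

test_that("global efficiency matches closed forms and the oracle", {
  expect_equal(global_efficiency(1 - diag(5)), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  P3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_error(global_efficiency(matrix(0, 1, 1)), "at least 2")

  for (s in 1:100) {
    n <- sample(2:12, 1)
    A <- rand_adj(n, runif(1, 0, 1), seed = 1000 + s)
    expect_equal(global_efficiency(A), global_eff_oracle(A))
  }
})

test_that("local efficiency matches closed forms and the double-loop oracle", {
  triangle <- 1 - diag(3)
  expect_equal(local_efficiency(triangle), 1)
  star <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(local_efficiency(star), 0)

  for (s in 1:100) {
    n <- sample(3:10, 1)
    A <- rand_adj(n, runif(1, 0.2, 0.9), seed = 2000 + s)
    expect_equal(local_efficiency(A), local_eff_oracle(A))
  }
})

test_that("efficiencies stay within [0, 1] and are label-permutation invariant", {
  for (s in 1:20) {
    A <- rand_adj(9, runif(1, 0.1, 0.9), seed = 3000 + s)
    eg <- global_efficiency(A)
    el <- local_efficiency(A)
    expect_true(eg >= 0 && eg <= 1)
    expect_true(el >= 0 && el <= 1)
    perm <- sample(9)
    expect_equal(global_efficiency(A[perm, perm]), eg)
    expect_equal(local_efficiency(A[perm, perm]), el)
  }
})

test_that("the efficiency sweep covers the grid and is monotone in the threshold", {
  rec <- noise_recording(10, 300, seed = 25)
  cm <- correlation_matrix(rec, "oxy")
  sweep <- efficiency_sweep(cm)
  expect_equal(nrow(sweep), 5)
  expect_equal(sweep$delta, seq(0.2, 0.6, by = 0.1))
  expect_true(all(diff(sweep$e_glob) <= 1e-12))

  ones <- matrix(1, 6, 6)
  sweep1 <- efficiency_sweep(ones)
  expect_true(all(sweep1$e_glob == 1))
  expect_error(efficiency_sweep(cm, numeric(0)), "non-empty")
})
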