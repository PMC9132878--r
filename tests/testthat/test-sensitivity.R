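test_that("pick-freeze design has the prescribed structure", {
  pr <- unit_prior(3)
  des <- saltelli_design(pr, 4)
  ## 4 * (2 + 3) = 20 evaluation rows in total
  total_rows <- nrow(des$A) + nrow(des$B) + sum(vapply(des$AB, nrow, integer(1)))
  expect_equal(total_rows, 20)
  ## AB^(i) differs from A only in column i
  for (k in 1:3) {
    diffs <- vapply(names(des$A), function(nm) {
      any(des$AB[[k]][[nm]] != des$A[[nm]])
    }, logical(1))
    expect_identical(unname(which(diffs)), k)
    expect_equal(des$AB[[k]][[k]], des$B[[k]])
  }
  ## columns of A marginally match the prior
  des_big <- saltelli_design(unit_prior(3), 1024)
  for (nm in names(des_big$A)) {
    expect_gt(stats::ks.test(des_big$A[[nm]], "punif")$p.value, 0.01)
  }
  ## fixed entries are constant and excluded from the varying set
  prf <- sa_prior(c("x1", "x2"), dist = c("uniform", "fixed"),
                  bounds = list(x1 = c(0, 1)), fixed = c(x2 = 7))
  desf <- saltelli_design(prf, 8)
  expect_identical(desf$varying, "x1")
  expect_true(all(desf$A$x2 == 7))
})

test_that("estimators recover analytic indices for additive functions", {
  cs <- c(2, 1, 0.5)
  f <- function(X) drop(X %*% cs)
  des <- saltelli_design(unit_prior(3), 2^14)
  yA <- f(as.matrix(des$A)); yB <- f(as.matrix(des$B))
  S_true <- cs^2 / sum(cs^2)
  for (k in 1:3) {
    yAB <- f(as.matrix(des$AB[[k]]))
    S <- sobol_first_order(yA, yB, yAB)
    T <- sobol_total_effect(yA, yB, yAB)
    expect_lt(abs(S - S_true[k]), 0.02)
    ## additive: total equals first-order
    expect_lt(abs(T - S_true[k]), 0.02)
    expect_gte(T, S - 0.02)
  }
})

test_that("pure interactions show zero first-order but unit total effect", {
  f <- function(X) X[, 1] * X[, 2]
  pr <- sa_prior(c("x1", "x2"),
                 bounds = list(x1 = c(-1, 1), x2 = c(-1, 1)))
  des <- saltelli_design(pr, 2^14)
  yA <- f(as.matrix(des$A)); yB <- f(as.matrix(des$B))
  for (k in 1:2) {
    yAB <- f(as.matrix(des$AB[[k]]))
    expect_lt(abs(sobol_first_order(yA, yB, yAB)), 0.02)
    expect_gt(sobol_total_effect(yA, yB, yAB), 0.98)
  }
})

test_that("Ishigami-style nonlinear function matches brute force", {
  f <- function(X) {
    A <- 2 * pi * (X - 0.5)
    sin(A[, 1]) + 5 * sin(A[, 2])^2 + 2 * A[, 3]^4 * sin(A[, 1])
  }
  des <- saltelli_design(unit_prior(3), 2^14)
  yA <- f(as.matrix(des$A)); yB <- f(as.matrix(des$B))
  for (k in 1:3) {
    yAB <- f(as.matrix(des$AB[[k]]))
    S <- sobol_first_order(yA, yB, yAB)
    T <- sobol_total_effect(yA, yB, yAB)
    expect_lt(abs(S - brute_force_S(f, 3, k)), 0.02)
    expect_gte(T + 0.02, S)
  }
})

test_that("index estimates outside [0,1] are clipped with a warning", {
  ## crafted evaluations with a first-order estimate of 2
  yA <- rep(c(1, -1), 25); yB <- yA; yAB <- 3 * yA
  expect_warning(s <- sobol_first_order(yA, yB, yAB))
  expect_gte(s, -0.05)
  expect_lte(s, 1.05)
  expect_error(sobol_first_order(rep(1, 10), rep(1, 10), rep(1, 10)),
               class = "myouq_degenerate_error")
})

test_that("index ensembles are invariant to input relabelling", {
  f <- function(X) 2 * X[, 1] + 0.3 * X[, 2] * X[, 3]
  des1 <- saltelli_design(unit_prior(3), 2^12)
  y <- function(des, perm) {
    M <- function(df) as.matrix(df)[, perm, drop = FALSE]
    list(A = f(M(des$A)), B = f(M(des$B)),
         AB = lapply(des$AB, function(m) f(M(m))))
  }
  e1 <- y(des1, c(1, 2, 3))
  S_1 <- vapply(1:3, function(k) sobol_first_order(e1$A, e1$B, e1$AB[[k]]), numeric(1))
  ## relabel inputs 2 and 3: the function sees permuted columns, so the
  ## index of "x2" under the permutation must equal the index of "x3"
  e2 <- y(des1, c(1, 3, 2))
  S_2 <- vapply(1:3, function(k) sobol_first_order(e2$A, e2$B, e2$AB[[k]]), numeric(1))
  expect_lt(abs(S_1[2] - S_2[3]), 0.02)
  expect_lt(abs(S_1[3] - S_2[2]), 0.02)
  expect_lt(abs(S_1[1] - S_2[1]), 0.02)
})

test_that("emulator-based ensembles recover a single-input function", {
  ## noise-free emulator of Y = X1 on [0,1]^2
  set.seed(9)
  X <- as.data.frame(sobol_sequence(60, 2))
  names(X) <- c("x1", "x2")
  y <- X$x1
  em <- gp_fit(X, y, log_cols = character(0), restarts = 1)
  ens <- sobol_from_emulator(em, unit_prior(2), N = 256, n_gp_samples = 100,
                             seed = 3)
  expect_equal(dim(ens$S), c(100, 2))
  m <- ens$summary
  s1 <- m$mean[m$input == "x1" & m$index_type == "first_order"]
  expect_lt(abs(s1 - 1), 0.03)
  expect_lt(abs(m$mean[m$input == "x2" & m$index_type == "total_effect"]), 0.03)
  ## summaries consistent with stored draws
  expect_equal(s1, mean(ens$S[, "x1"]))
  ## determinism
  ens2 <- sobol_from_emulator(em, unit_prior(2), N = 256, n_gp_samples = 100,
                              seed = 3)
  expect_identical(ens$summary, ens2$summary)
})
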