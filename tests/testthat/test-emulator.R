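test_that("kernel evaluates the ARD squared-exponential formula", {
  hyp <- list(sigma_f = 1.5, lengthscales = c(1, 2), eta = 0.1)
  X <- rbind(c(0, 0), c(1, 1))
  K <- ard_kernel(X, X, hyp, nugget = TRUE)
  ## same point: sigma_f^2 + eta^2
  expect_equal(K[1, 1], 1.5^2 + 0.1^2)
  ## off-diagonal: direct formula
  expect_equal(K[1, 2], 1.5^2 * exp(-0.5 * (1 / 1^2 + 1 / 2^2)))
  ## unit hyperparameters, squared distance 2 -> exp(-1)
  hyp1 <- list(sigma_f = 1, lengthscales = c(1, 1), eta = 1e-12)
  K1 <- ard_kernel(rbind(c(0, 0)), rbind(c(1, 1)), hyp1)
  expect_equal(K1[1, 1], exp(-1))
  ## decay to zero at large separation
  expect_lt(ard_kernel(rbind(0), rbind(50), list(sigma_f = 1, lengthscales = 1, eta = 0.1))[1, 1],
            1e-12)
  expect_error(ard_kernel(rbind(c(0, 0)), rbind(c(1, 1)),
                          list(sigma_f = 1, lengthscales = 1, eta = 0.1)),
               class = "myouq_validation_error")
})

test_that("posterior prediction matches an independent dense implementation", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    D <- sample(1:3, 1)
    X <- matrix(stats::runif(n * D, -2, 2), n, D)
    y <- stats::rnorm(n)
    hyp <- list(sigma_f = exp(stats::runif(1, -0.5, 0.5)),
                lengthscales = exp(stats::runif(D, -0.5, 0.5)),
                eta = 0.1)
    em <- make_toy_emulator(X, y, hyp)
    Xs <- matrix(stats::runif(8 * D, -2, 2), 8, D)
    pr <- gp_predict(em, Xs, full_cov = TRUE)
    ## dense oracle built from scratch with base linear algebra
    kse <- function(A, B) {
      K <- matrix(0, nrow(A), nrow(B))
      for (i in seq_len(nrow(A))) {
        for (j in seq_len(nrow(B))) {
          K[i, j] <- hyp$sigma_f^2 *
            exp(-0.5 * sum((A[i, ] - B[j, ])^2 / hyp$lengthscales^2))
        }
      }
      K
    }
    Knn <- kse(X, X) + hyp$eta^2 * diag(n)
    Kns <- kse(X, Xs)
    Kss <- kse(Xs, Xs) + hyp$eta^2 * diag(8)
    mu <- t(Kns) %*% solve(Knn, y)
    S <- Kss - t(Kns) %*% solve(Knn, Kns)
    expect_lt(max(abs(pr$mean - mu)), 1e-8)
    expect_lt(max(abs(pr$cov_std - S)), 1e-8)
    ## conditioning never inflates the marginal variance
    expect_true(all(diag(pr$cov_std) <= hyp$sigma_f^2 + hyp$eta^2 + 1e-10))
  }
})

test_that("near-interpolation at training points for a small nugget", {
  set.seed(5)
  X <- matrix(stats::runif(30, -1, 1), 15, 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  em <- make_toy_emulator(X, y, list(sigma_f = 1, lengthscales = c(0.7, 0.7),
                                     eta = 1e-5))
  pr <- gp_predict(em, X)
  expect_lt(max(abs(pr$mean - y)), 1e-4)
})

test_that("marginal-likelihood fit recovers known hyperparameters and contracts", {
  set.seed(2)
  n <- 200; D <- 3
  X <- matrix(stats::runif(n * D, -2, 2), n, D)
  colnames(X) <- paste0("x", 1:D)
  hyp_true <- list(sigma_f = 1.5, lengthscales = c(0.6, 1.2, 2.5), eta = 0.05)
  K <- ard_kernel(X, X, hyp_true, nugget = TRUE)
  y <- drop(t(chol(K)) %*% stats::rnorm(n))
  em <- gp_fit(X, y, log_cols = character(0), restarts = 2)
  ## recovered lengthscales within a factor 2 (on the original input scale)
  ratio <- em$hyp$lengthscales * apply(X, 2, stats::sd) / hyp_true$lengthscales
  expect_true(all(ratio > 0.5 & ratio < 2))
  ## lml at optimum at least as good as at the default start
  phi0 <- c(0, rep(0, D), log(0.05))
  Xs <- myouq:::gp_transform(X, em$transform)
  ys <- (y - em$y_mean) / em$y_sd
  expect_gte(em$lml, -myouq:::gp_nlml(phi0, Xs, ys, D)$value)
  ## duplicated training point is absorbed by the nugget
  X2 <- rbind(X[1:30, ], X[1, , drop = FALSE])
  y2 <- c(y[1:30], y[1] + 0.01)
  expect_s3_class(gp_fit(X2, y2, log_cols = character(0), restarts = 1),
                  "gp_emulator")
})

test_that("de-standardized predictions are invariant to output shift/scale", {
  set.seed(8)
  X <- matrix(stats::runif(60, -1, 1), 30, 2)
  colnames(X) <- c("x1", "x2")
  y <- sin(2 * X[, 1]) * X[, 2]
  Xs <- matrix(stats::runif(10, -1, 1), 5, 2)
  colnames(Xs) <- c("x1", "x2")
  em1 <- gp_fit(X, y, log_cols = character(0), restarts = 1)
  em2 <- gp_fit(X, 100 + 7 * y, log_cols = character(0), restarts = 1)
  p1 <- gp_predict(em1, Xs)$mean
  p2 <- (gp_predict(em2, Xs)$mean - 100) / 7
  ## invariance holds up to the optimizer's stopping tolerance (the
  ## standardized training data are identical only to rounding)
  expect_equal(p1, p2, tolerance = 1e-2)
})

test_that("posterior sampling is reproducible and has correct moments", {
  set.seed(12)
  X <- matrix(seq(-2, 2, length.out = 12), ncol = 1)
  y <- sin(X[, 1])
  em <- make_toy_emulator(X, y, list(sigma_f = 1, lengthscales = 0.8, eta = 0.05))
  Xs <- matrix(c(-1.3, 0.2, 1.7), ncol = 1)
  s1 <- gp_sample(em, Xs, n_samples = 50, seed = 3)
  s2 <- gp_sample(em, Xs, n_samples = 50, seed = 3)
  expect_identical(s1, s2)
  pr <- gp_predict(em, Xs, full_cov = TRUE)
  big <- gp_sample(em, Xs, n_samples = 10000, seed = 4)
  se <- sqrt(diag(pr$cov_std) / 10000)
  expect_true(all(abs(rowMeans(big) - pr$mean) < 3 * pmax(se, 1e-6)))
  ## pathwise draws agree with dense draws in distribution
  pw <- gp_sample_pathwise(em, Xs, n_samples = 10000, n_features = 2048, seed = 5)
  expect_lt(max(abs(rowMeans(pw) - pr$mean)), 0.05)
  expect_lt(max(abs(apply(pw, 1, stats::sd) - apply(big, 1, stats::sd))), 0.06)
})

test_that("emulator archives round-trip through the versioned JSON format", {
  set.seed(21)
  X <- data.frame(a = exp(stats::runif(25, log(0.2), log(5))),
                  edp = stats::runif(25, 4, 30))
  y <- log(X$a) + 0.1 * X$edp
  em <- gp_fit(X, y, log_cols = "a", restarts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  gp_save(em, path)
  back <- gp_load(path)
  Xs <- data.frame(a = c(0.5, 2), edp = c(8, 22))
  expect_equal(gp_predict(back, Xs)$mean, gp_predict(em, Xs)$mean,
               tolerance = 1e-6)
  expect_equal(back$hyp, em$hyp, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(gp_load(bad), class = "myouq_validation_error")
})

test_that("Q-squared matches its defining arithmetic", {
  expect_equal(q2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(q2(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(q2(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(q2(rep(1, 5), rnorm(5)), class = "myouq_degenerate_error")
  expect_error(q2(1, 1), class = "myouq_validation_error")
})
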