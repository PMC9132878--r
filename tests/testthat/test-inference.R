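test_that("PSRF matches direct substitution and limiting behaviour", {
  set.seed(4)
  n <- 200
  x <- stats::rnorm(n)
  ## identical chains: B = 0 so PSRF = sqrt((n-1)/n)
  expect_equal(psrf(cbind(x, x, x)), sqrt((n - 1) / n))
  ## iid chains from the same distribution converge to 1
  big <- matrix(stats::rnorm(4 * 10000), ncol = 4)
  expect_gt(psrf(big), 0.99)
  expect_lt(psrf(big), 1.01)
  ## separated chains are flagged
  expect_gt(psrf(cbind(stats::rnorm(500), stats::rnorm(500, 10))), 2)
  expect_error(psrf(cbind(rep(1, 50), rep(1, 50))), class = "myouq_degenerate_error")
  expect_error(psrf(matrix(1:5)), class = "myouq_validation_error")
  ## split-chain variant flags a trend that the classic statistic misses
  trending <- cbind(seq(0, 1, length.out = 400) + stats::rnorm(400, 0, 0.05),
                    seq(0, 1, length.out = 400) + stats::rnorm(400, 0, 0.05))
  expect_lt(psrf(trending), 1.05)
  expect_gt(psrf(trending, split = TRUE), 1.5)
})

test_that("I-IQR matches quantile arithmetic", {
  set.seed(5)
  u <- stats::runif(2e5)
  expect_lt(abs(iiqr(u) - 2), 0.02)
  expect_equal(iiqr(10 * u), iiqr(u) / 10, tolerance = 1e-10)
  z <- stats::rnorm(2e5)
  expect_lt(abs(iiqr(z) - 1 / 1.349), 0.01)
  expect_error(iiqr(rep(2, 10)), class = "myouq_degenerate_error")
  expect_error(iiqr(c(1, 2)), class = "myouq_validation_error")
})

test_that("log-likelihood follows the two-component Gaussian form", {
  fit <- small_iuq_fit()
  stack <- fit$stack
  th <- c(a = 1.5, b = 4, a_f = 2.5, b_f = 3)
  u <- c(log(th), 10)
  pred <- myouq:::stack_predict_point(stack, u)$mean
  ## observation equal to the predictions: only the log-variance terms remain
  y <- lv_observation(pred[1], pred[-1])
  s2 <- 0.0009
  expect_equal(log_likelihood(y, th, s2, stack, edp = 10, sigma0_sq = 25),
               -0.5 * log(25) - 12 * log(s2))
  ## doubling one strain residual changes the value by -3 r^2 / (2 s2)
  y1 <- y; y1$y_tilde[5] <- y1$y_tilde[5] + 0.02
  y2 <- y; y2$y_tilde[5] <- y2$y_tilde[5] + 0.04
  l0 <- log_likelihood(y, th, s2, stack, 10)
  l1 <- log_likelihood(y1, th, s2, stack, 10)
  l2 <- log_likelihood(y2, th, s2, stack, 10)
  expect_equal(l2 - l1, -3 * 0.02^2 / (2 * s2), tolerance = 1e-8)
  expect_equal(l1 - l0, -0.02^2 / (2 * s2), tolerance = 1e-8)
  expect_error(log_likelihood(y, th, -1, stack, 10), class = "myouq_validation_error")
})

test_that("log-posterior has uniform-prior support and correct gradients", {
  fit <- small_iuq_fit()
  obs <- fix_observation()
  lp <- myouq:::make_log_posterior(obs$obs, fit$stack, edp = 10)
  ## outside the material bounds the density vanishes
  expect_identical(lp(c(log(0.05), log(2), log(2), log(2), log(1e-3)))$value, -Inf)
  expect_identical(lp(c(log(2), log(2), log(2), log(11), log(1e-3)))$value, -Inf)
  ## inside the support, the posterior differs from the likelihood by the
  ## (constant + Jacobian) prior term
  q1 <- c(log(c(1.1, 3.3, 2.2, 2.8)), log(8e-4))
  q2 <- c(log(c(0.6, 5.1, 1.4, 1.9)), log(8e-4))
  ll <- function(q) log_likelihood(obs$obs, exp(q[1:4]), exp(q[5]), fit$stack, 10)
  expect_equal(lp(q1)$value - lp(q2)$value,
               (ll(q1) + sum(q1[1:4])) - (ll(q2) + sum(q2[1:4])),
               tolerance = 1e-9)
  ## gradient against central finite differences
  g <- lp(q1, grad = TRUE)$grad
  gfd <- vapply(1:5, function(j) {
    h <- 1e-6
    qp <- q1; qp[j] <- qp[j] + h
    qm <- q1; qm[j] <- qm[j] - h
    (lp(qp)$value - lp(qm)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - gfd) / pmax(abs(gfd), 1)), 1e-5)
  ## unconstrained sampling parameterization agrees up to its Jacobian:
  ## gradient check there too
  lpt <- myouq:::make_log_posterior_t(obs$obs, fit$stack, edp = 10)
  t1 <- c(0.3, -0.5, 1.1, -0.2, 0.4)
  gt <- lpt(t1, grad = TRUE)$grad
  gtfd <- vapply(1:5, function(j) {
    h <- 1e-6
    tp <- t1; tp[j] <- tp[j] + h
    tm <- t1; tm[j] <- tm[j] - h
    (lpt(tp)$value - lpt(tm)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gt - gtfd) / pmax(abs(gtfd), 1)), 1e-5)
})

test_that("reference NUTS sampler recovers a correlated Gaussian", {
  set.seed(9)
  S <- crossprod(matrix(stats::rnorm(25), 5)) + diag(5) * 0.5
  P <- solve(S)
  lp <- function(q, grad = FALSE) {
    v <- -0.5 * drop(q %*% P %*% q)
    if (!grad) return(list(value = v))
    list(value = v, grad = -drop(P %*% q))
  }
  chains <- lapply(1:4, function(c) {
    myouq:::nuts_chain(lp, stats::rnorm(5, 0, 3), 500, 1000, seed = c)$draws
  })
  d <- do.call(rbind, chains)
  expect_lt(max(abs(colMeans(d))), 3 * sqrt(max(diag(S)) / nrow(d)) * 5)
  expect_lt(max(abs(stats::cov(d) - S)) / max(S), 0.1)
  for (j in 1:5) {
    expect_lt(psrf(sapply(chains, function(ch) ch[, j])), 1.02)
  }
})

test_that("posterior sampling is reproducible and matches the reference sampler", {
  fit <- small_iuq_fit()
  obs <- fix_observation()
  f1 <- run_mcmc(obs$obs, fit$stack, 10, n_chains = 2, n_warmup = 300,
                 n_draws = 500, seed = 21)
  f2 <- run_mcmc(obs$obs, fit$stack, 10, n_chains = 2, n_warmup = 300,
                 n_draws = 500, seed = 21)
  expect_identical(f1$draws, f2$draws)
  expect_named(f1$psrf, c("log_a", "log_b", "log_a_f", "log_b_f",
                          "log_sigma_tilde_sq"))
  ## cross-validate the compiled sampler against the R reference NUTS on the
  ## same posterior (agreement in distribution)
  lpt <- myouq:::make_log_posterior_t(obs$obs, fit$stack, edp = 10)
  ref <- myouq:::nuts_chain(lpt, rep(0, 5), 500, 1500, seed = 3)$draws
  ql <- log(0.1); qu <- log(10)
  ref_a <- exp(ql + (qu - ql) / (1 + exp(-ref[, 1])))
  cpp_a <- posterior_theta(f1)[, "a"]
  expect_lt(abs(median(ref_a) - stats::median(cpp_a)),
            0.25 * stats::IQR(cpp_a) + 0.05)
  ## marginal posterior mass concentrated near the generating value
  expect_true(stats::quantile(cpp_a, 0.025) < obs$theta["a"] &
                stats::quantile(cpp_a, 0.975) > obs$theta["a"])
})

test_that("posterior draws and convergence reports export cleanly", {
  fit <- small_iuq_fit()
  obs <- fix_observation()
  f <- run_mcmc(obs$obs, fit$stack, 10, n_chains = 2, n_warmup = 150,
                n_draws = 200, seed = 33)
  csv <- withr::local_tempfile(fileext = ".csv")
  rep <- withr::local_tempfile(fileext = ".json")
  write_posterior_draws(f, csv, rep)
  d <- utils::read.csv(csv)
  expect_equal(nrow(d), 2 * 200)
  expect_true(all(c("chain", "draw", "log_a", "log_sigma_tilde_sq") %in% names(d)))
  expect_equal(d$log_a[d$chain == 2 & d$draw == 7], unname(f$draws[7, 2, 1]))
  r <- jsonlite::read_json(rep, simplifyVector = TRUE)
  expect_named(r$psrf, names(f$psrf))
  expect_equal(r$n_chains, 2)
})

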