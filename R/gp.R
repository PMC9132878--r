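## Gaussian-process regression with an anisotropic (ARD) squared-exponential
## kernel and nugget, zero prior mean on standardized outputs.
##
##   k(x, x') = sigma_f^2 exp(-1/2 sum_k (x_k - x'_k)^2 / lambda_k^2)
##              + eta^2 delta_{xx'}
##
## Inputs are transformed (log on designated columns, then per-dimension
## affine standardization) and outputs standardized to mean 0 / variance 1
## before fitting; hyperparameters maximize the log marginal likelihood.

#' ARD squared-exponential kernel
#'
#' @param X1,X2 input matrices (rows = points) on the kernel's input scale.
#' @param hyp list with `sigma_f`, `lengthscales` (length D), `eta`.
#' @param nugget add `eta^2` on the diagonal (only meaningful when
#'   `X1` and `X2` index the same points).
#' @return covariance matrix `nrow(X1) x nrow(X2)`.
#' @export
ard_kernel <- function(X1, X2, hyp, nugget = FALSE) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != length(hyp$lengthscales) || ncol(X2) != ncol(X1)) {
    abort_validation("ard_kernel: input dimension does not match lengthscales")
  }
  if (any(c(hyp$sigma_f, hyp$lengthscales, hyp$eta) <= 0)) {
    abort_validation("ard_kernel: hyperparameters must be strictly positive")
  }
  Z1 <- sweep(X1, 2, hyp$lengthscales, "/")
  Z2 <- sweep(X2, 2, hyp$lengthscales, "/")
  d2 <- outer(rowSums(Z1^2), rowSums(Z2^2), "+") - 2 * tcrossprod(Z1, Z2)
  d2[d2 < 0] <- 0
  K <- hyp$sigma_f^2 * exp(-0.5 * d2)
  if (nugget) {
    if (nrow(X1) != nrow(X2)) abort_validation("ard_kernel: nugget needs square K")
    K <- K + hyp$eta^2 * diag(nrow(X1))
  }
  K
}

## Cholesky with escalating jitter; structured error when the budget runs out.
chol_jitter <- function(K, max_tries = 6) {
  jit <- 0
  for (t in seq_len(max_tries)) {
    L <- tryCatch(chol(K + jit * diag(nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- if (jit == 0) 1e-10 * mean(diag(K)) else jit * 100
  }
  abort_numeric("Cholesky factorization failed after jitter escalation")
}

## Transform raw inputs to the kernel input scale.
gp_transform <- function(X, tr) {
  X <- as.matrix(X)
  for (j in tr$log_cols) X[, j] <- log(X[, j])
  sweep(sweep(X, 2, tr$center, "-"), 2, tr$scale, "/")
}

## negative LML and gradient in phi = log(sigma_f, lengthscales..., eta).
## D2 optionally carries precomputed per-dimension squared-difference
## matrices (reused across optimizer iterations).
gp_nlml <- function(phi, Xs, y, D, D2 = NULL) {
  sf <- exp(phi[1]); ls <- exp(phi[2:(D + 1)]); eta <- exp(phi[D + 2])
  n <- length(y)
  if (is.null(D2)) D2 <- lapply(seq_len(D), function(k) outer(Xs[, k], Xs[, k], "-")^2)
  d2 <- matrix(0, n, n)
  for (k in seq_len(D)) d2 <- d2 + D2[[k]] / ls[k]^2
  Kse <- sf^2 * exp(-0.5 * d2)
  K <- Kse + eta^2 * diag(n)
  ch <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, D + 2)))
  L <- ch$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nlml <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv # d lml / dK multiplies 0.5*dK
  WK <- W * Kse
  g <- numeric(D + 2)
  g[1] <- -sum(WK)                                       # d/dlog sigma_f
  for (k in seq_len(D)) {
    g[k + 1] <- -0.5 * sum(WK * D2[[k]]) / ls[k]^2       # d/dlog lambda_k
  }
  g[D + 2] <- -0.5 * sum(diag(W)) * 2 * eta^2            # d/dlog eta
  list(value = nlml, grad = g)
}

#' Fit a Gaussian-process emulator
#'
#' Log-transforms the designated input columns (by default the material
#' parameters present among the column names), standardizes inputs and
#' outputs, and maximizes the log marginal likelihood over the kernel
#' hyperparameters with L-BFGS-B and analytic gradients, using multiple
#' seeded restarts.  The nugget is optimized jointly with a floor of
#' `1e-6`.
#'
#' @param X training inputs (data.frame or matrix with named columns).
#' @param y training outputs (numeric vector).
#' @param log_cols names of columns to log-transform (default: any of the
#'   eight material-parameter names present).
#' @param restarts number of optimizer restarts (first start is
#'   deterministic: unit amplitude/lengthscales, nugget 0.05).
#' @param init optional named list of starting hyperparameters
#'   (`sigma_f`, `lengthscales`, `eta`) overriding the default first start.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param seed seed for the randomized restarts.
#' @return an object of class `gp_emulator`.
#' @export
gp_fit <- function(X, y, log_cols = NULL, restarts = 3, init = NULL,
                   maxit = 100, seed = 1) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  n <- nrow(X); D <- ncol(X)
  if (n < 10) abort_validation("gp_fit: need at least 10 training points")
  if (n != length(y)) abort_validation("gp_fit: X and y lengths differ")
  if (is.null(log_cols)) log_cols <- intersect(MATERIAL_NAMES, names(X))
  Xl <- as.matrix(X)
  for (j in log_cols) Xl[, j] <- log(Xl[, j])
  if (any(!is.finite(Xl))) abort_validation("gp_fit: inputs non-finite after log transform")
  center <- colMeans(Xl)
  scale <- apply(Xl, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  tr <- list(log_cols = log_cols, center = center, scale = scale)
  Xs <- gp_transform(X, tr)
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd < 1e-12) abort_validation("gp_fit: training outputs are constant")
  ys <- (y - y_mean) / y_sd

  lower <- c(log(1e-3), rep(log(1e-3), D), log(1e-6))
  upper <- c(log(1e3), rep(log(1e3), D), log(2))
  phi0 <- if (is.null(init)) {
    c(0, rep(0, D), log(0.05))
  } else {
    log(c(init$sigma_f, init$lengthscales, init$eta))
  }
  starts <- list(phi0)
  if (restarts > 1) {
    extra <- with_seed(derive_seed(seed, 5L), {
      lapply(seq_len(restarts - 1), function(i) {
        phi0 + c(stats::rnorm(1, 0, 0.3), stats::rnorm(D, 0, 0.7), stats::rnorm(1, 0, 0.5))
      })
    })
    starts <- c(starts, extra)
  }
  ## optim calls fn and gr separately at the same point: cache the last
  ## evaluation so each L-BFGS-B step costs one Cholesky, not two
  memo <- new.env(parent = emptyenv())
  D2 <- lapply(seq_len(D), function(k) outer(Xs[, k], Xs[, k], "-")^2)
  nlml_at <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(memo$key, key)) {
      memo$key <- key
      memo$val <- gp_nlml(p, Xs, ys, D, D2)
    }
    memo$val
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper),
                   fn = function(p) nlml_at(p)$value,
                   gr = function(p) nlml_at(p)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort_numeric("gp_fit: all optimizer restarts failed")
  phi <- best$par
  hyp <- list(sigma_f = exp(phi[1]),
              lengthscales = stats::setNames(exp(phi[2:(D + 1)]), colnames(Xs)),
              eta = max(exp(phi[D + 2]), 1e-6))
  K <- ard_kernel(Xs, Xs, hyp, nugget = TRUE)
  ch <- chol_jitter(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), ys))
  structure(list(
    transform = tr, y_mean = y_mean, y_sd = y_sd,
    hyp = hyp, X_train = Xs, y_train = ys,
    L = ch$L, alpha = alpha, jitter = ch$jitter,
    lml = -best$value, n = n, D = D,
    col_names = names(X)
  ), class = "gp_emulator")
}

#' GP posterior prediction
#'
#' Posterior mean and (co)variance at new inputs,
#' `mu = K_*' K^-1 y`, `Sigma = K_** - K_*' K^-1 K_*` (zero prior mean on
#' the standardized scale).
#'
#' @param em a `gp_emulator`.
#' @param Xstar new inputs on the raw scale (same columns as training).
#' @param full_cov return the full posterior covariance matrix.
#' @return list with `mean`, `sd` (destandardized), `mean_std`, and
#'   `cov_std`/`sd_std` on the standardized output scale (plus `cov` when
#'   `full_cov`).
#' @export
gp_predict <- function(em, Xstar, full_cov = FALSE) {
  Xs <- gp_transform(as.data.frame(Xstar), em$transform)
  Kx <- ard_kernel(em$X_train, Xs, em$hyp) # n x T
  mu <- drop(crossprod(Kx, em$alpha))
  V <- forwardsolve(t(em$L), Kx)
  if (full_cov) {
    Kss <- ard_kernel(Xs, Xs, em$hyp, nugget = TRUE)
    S <- Kss - crossprod(V)
    S <- (S + t(S)) / 2
    list(mean = em$y_mean + em$y_sd * mu, mean_std = mu,
         cov_std = S, cov = em$y_sd^2 * S,
         sd = em$y_sd * sqrt(pmax(diag(S), 0)),
         sd_std = sqrt(pmax(diag(S), 0)))
  } else {
    var_std <- pmax(em$hyp$sigma_f^2 + em$hyp$eta^2 - colSums(V^2), 0)
    list(mean = em$y_mean + em$y_sd * mu, mean_std = mu,
         sd = em$y_sd * sqrt(var_std), sd_std = sqrt(var_std))
  }
}

#' Draw joint samples from the GP posterior
#'
#' Exact draws from the dense posterior Gaussian at the requested points,
#' via an eigendecomposition with clipping of small negative eigenvalues.
#'
#' @param em a `gp_emulator`.
#' @param Xstar new inputs (raw scale).
#' @param n_samples number of function draws (default 250).
#' @param seed integer seed.
#' @return matrix `nrow(Xstar) x n_samples` of destandardized draws.
#' @export
gp_sample <- function(em, Xstar, n_samples = 250, seed = 1) {
  if (n_samples < 1) abort_validation("gp_sample: n_samples must be >= 1")
  pr <- gp_predict(em, Xstar, full_cov = TRUE)
  e <- eigen(pr$cov_std, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    abort_numeric("gp_sample: posterior covariance indefinite beyond tolerance")
  }
  Lhalf <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(e$values))
  Z <- with_seed(derive_seed(seed, 3L),
                 matrix(stats::rnorm(length(e$values) * n_samples), ncol = n_samples))
  em$y_mean + em$y_sd * (pr$mean_std + Lhalf %*% Z)
}

#' Pathwise joint GP posterior draws (random Fourier features)
#'
#' Approximate joint posterior function draws over arbitrarily many test
#' points using Matheron's rule: a random-Fourier-feature draw from the
#' prior is corrected by the exact conditioning update,
#' `f*(x) = f0(x) + k(x, X) K^-1 (y - f0(X) - eps)`.
#' Cost is linear in the number of test points, so draws remain jointly
#' coherent on designs far beyond dense-covariance sizes.
#'
#' @param em a `gp_emulator`.
#' @param Xstar new inputs (raw scale).
#' @param n_samples number of draws.
#' @param n_features number of random Fourier features for the prior.
#' @param seed integer seed.
#' @return matrix `nrow(Xstar) x n_samples` (destandardized).
#' @export
gp_sample_pathwise <- function(em, Xstar, n_samples = 250, n_features = 768, seed = 1) {
  Xs <- gp_transform(as.data.frame(Xstar), em$transform)
  D <- ncol(Xs); n <- em$n; m <- n_features
  rng <- with_seed(derive_seed(seed, 7L), {
    list(Om = matrix(stats::rnorm(m * D), m, D) / matrix(em$hyp$lengthscales, m, D, byrow = TRUE),
         b = stats::runif(m, 0, 2 * pi),
         W = matrix(stats::rnorm(m * n_samples), m, n_samples),
         E = matrix(stats::rnorm(n * n_samples), n, n_samples))
  })
  featurize <- function(Xin) {
    sqrt(2 / m) * em$hyp$sigma_f * cos(sweep(Xin %*% t(rng$Om), 2, rng$b, "+"))
  }
  Phi_star <- featurize(Xs)          # T x m
  Phi_tr <- featurize(em$X_train)    # n x m
  F0_star <- Phi_star %*% rng$W      # T x S prior draws at test points
  F0_tr <- Phi_tr %*% rng$W + em$hyp$eta * rng$E
  resid <- matrix(em$y_train, n, n_samples) - F0_tr
  U <- backsolve(em$L, forwardsolve(t(em$L), resid)) # K^-1 resid, n x S
  Kx <- ard_kernel(Xs, em$X_train, em$hyp)           # T x n
  em$y_mean + em$y_sd * (F0_star + Kx %*% U)
}

#' Save / load a fitted emulator
#'
#' Serializes a `gp_emulator` (input transform, output standardization,
#' hyperparameters and training data) to a single versioned JSON archive;
#' the training-kernel factorization is rebuilt on load.
#'
#' @param em a `gp_emulator`.
#' @param path file path (JSON).
#' @return `gp_save` returns `path` invisibly; `gp_load` returns the
#'   restored `gp_emulator`.
#' @export
gp_save <- function(em, path) {
  if (!inherits(em, "gp_emulator")) abort_validation("gp_save: not a gp_emulator")
  payload <- list(
    format = "myouq-gp", version = 1L,
    transform = list(log_cols = em$transform$log_cols,
                     center = unname(em$transform$center),
                     scale = unname(em$transform$scale)),
    y_mean = em$y_mean, y_sd = em$y_sd,
    hyp = list(sigma_f = em$hyp$sigma_f,
               lengthscales = unname(em$hyp$lengthscales),
               eta = em$hyp$eta),
    col_names = em$col_names,
    X_train = unname(em$X_train), y_train = em$y_train,
    lml = em$lml
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gp_save
#' @export
gp_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "myouq-gp")) {
    abort_validation("gp_load: not a myouq emulator archive")
  }
  if (p$version != 1L) {
    abort_validation(sprintf("gp_load: unsupported archive version %s", p$version))
  }
  X <- as.matrix(p$X_train)
  colnames(X) <- p$col_names
  hyp <- list(sigma_f = p$hyp$sigma_f,
              lengthscales = stats::setNames(p$hyp$lengthscales, p$col_names),
              eta = p$hyp$eta)
  K <- ard_kernel(X, X, hyp, nugget = TRUE)
  ch <- chol_jitter(K)
  y <- as.numeric(p$y_train)
  structure(list(
    transform = list(log_cols = as.character(p$transform$log_cols),
                     center = stats::setNames(p$transform$center, p$col_names),
                     scale = stats::setNames(p$transform$scale, p$col_names)),
    y_mean = p$y_mean, y_sd = p$y_sd, hyp = hyp,
    X_train = X, y_train = y,
    L = ch$L, alpha = backsolve(ch$L, forwardsolve(t(ch$L), y)),
    jitter = ch$jitter, lml = p$lml,
    n = nrow(X), D = ncol(X), col_names = p$col_names
  ), class = "gp_emulator")
}

#' Out-of-sample predictive coefficient Q-squared
#'
#' `Q2 = 1 - SSE/SST` on held-out data, with SST taken about the test-set
#' mean: the proportion of test-output variance captured by the emulator.
#'
#' @param f_true held-out simulator outputs.
#' @param f_pred emulator predictions at the same points.
#' @return scalar Q-squared (1 = perfect, 0 = no better than the mean).
#' @export
q2 <- function(f_true, f_pred) {
  if (length(f_true) != length(f_pred) || length(f_true) < 2) {
    abort_validation("q2: need equal-length vectors of length >= 2")
  }
  sst <- sum((f_true - mean(f_true))^2)
  if (sst == 0) abort_degenerate("q2: test outputs are constant; Q2 undefined")
  1 - sum((f_true - f_pred)^2) / sst
}
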