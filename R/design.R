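## Experimental designs and synthetic datasets from the forward model.

#' Default model-input bounds
#'
#' Bounds of the eleven forward-model inputs used throughout the
#' sensitivity and inference studies: the eight material constants on
#' `[0.1, 10]` (kPa or dimensionless), EDP on `[4, 30]` mmHg and fibre
#' helix angles on `[0, 90]` / `[-90, 0]` degrees.
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_input_bounds <- function() {
  list(
    a = c(0.1, 10), b = c(0.1, 10), a_f = c(0.1, 10), b_f = c(0.1, 10),
    a_s = c(0.1, 10), b_s = c(0.1, 10), a_fs = c(0.1, 10), b_fs = c(0.1, 10),
    edp = c(4, 30), alpha_endo = c(0, 90), alpha_epi = c(-90, 0)
  )
}

MATERIAL_NAMES <- c("a", "b", "a_f", "b_f", "a_s", "b_s", "a_fs", "b_fs")
REDUCED_NAMES <- c("a", "b", "a_f", "b_f")

#' Low-discrepancy design over bounded inputs
#'
#' Maps a Sobol sequence onto per-dimension intervals, either linearly or
#' uniformly in log space ("uniform in log(x)").
#'
#' @param n number of design points.
#' @param bounds named list of `c(lower, upper)` intervals.
#' @param space character vector, one of `"linear"`/`"log"` per dimension
#'   (recycled if length 1).
#' @param skip number of initial Sobol points to skip.
#' @return an `n x D` data.frame of design points within the bounds.
#' @export
sobol_design <- function(n, bounds = default_input_bounds(),
                         space = "linear", skip = 0) {
  d <- length(bounds)
  if (n < 1) abort_validation("sobol_design: n must be >= 1")
  space <- rep_len(space, d)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(space == "log" & lo <= 0)) {
    abort_validation("sobol_design: log-space dimensions need strictly positive bounds")
  }
  u <- sobol_sequence(n, d, skip = skip)
  out <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) {
    out[, j] <- if (space[j] == "log") {
      exp(log(lo[j]) + u[, j] * (log(hi[j]) - log(lo[j])))
    } else {
      lo[j] + u[, j] * (hi[j] - lo[j])
    }
  }
  out <- as.data.frame(out)
  names(out) <- names(bounds)
  out
}

#' Two-block training design for the sensitivity emulators
#'
#' The training design used for the sensitivity study: a single Sobol
#' stream of length `n` over the eleven inputs in which the first half of
#' the material-parameter samples is mapped linearly onto the bounds and
#' the second half uniformly in log space (covering both the uniform and
#' log-uniform priors); EDP and the fibre angles are always mapped
#' linearly.
#'
#' @param n total number of design points (split into two equal blocks).
#' @param bounds named list of input bounds.
#' @param skip Sobol points to skip (used to extend the stream, e.g. for
#'   an independent test block).
#' @return an `n x 11` data.frame.
#' @export
sa_training_design <- function(n = 2000, bounds = default_input_bounds(), skip = 0) {
  d <- length(bounds)
  u <- sobol_sequence(n, d, skip = skip)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  out <- matrix(NA_real_, n, d)
  is_mat <- names(bounds) %in% MATERIAL_NAMES
  n1 <- floor(n / 2)
  for (j in seq_len(d)) {
    lin <- lo[j] + u[, j] * (hi[j] - lo[j])
    if (is_mat[j]) {
      lg <- exp(log(lo[j]) + u[, j] * (log(hi[j]) - log(lo[j])))
      out[, j] <- c(lin[seq_len(n1)], lg[seq.int(n1 + 1, n)])
    } else {
      out[, j] <- lin
    }
  }
  out <- as.data.frame(out)
  names(out) <- names(bounds)
  out
}

row_to_input <- function(row, check = FALSE) {
  pars <- do.call(ho_params, as.list(row[MATERIAL_NAMES]))
  lv_input(pars, edp = row[["edp"]],
           alpha_endo = row[["alpha_endo"]] %||% 60,
           alpha_epi = row[["alpha_epi"]] %||% -90,
           check = check)
}

#' Run the forward model over a design
#'
#' Solves the inflation problem and extracts the quantities of interest
#' for every design row.  Rows whose equilibrium solve fails are dropped
#' and recorded (status flag), mirroring how unconverged finite-element
#' runs are discarded; a failure rate above `max_fail` aborts.
#'
#' @param design data.frame with columns for the eight material constants
#'   plus `edp` and optionally `alpha_endo`, `alpha_epi`.
#' @param spec an [lv_geometry()].
#' @param layout a [segment_layout()].
#' @param max_fail maximum tolerated failure fraction.
#' @return a list with `inputs` (the successful design rows), `qois`
#'   (matrix, one row per success, 73 columns), `status` (character vector
#'   over all design rows), `n_failed`.
#' @export
generate_training_set <- function(design, spec = lv_geometry(),
                                  layout = segment_layout(), max_fail = 0.1) {
  n <- nrow(design)
  status <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      cfg <- solve_inflation(row_to_input(unlist(design[i, ])), spec)
      qoi_vector(compute_qois(cfg, layout))
    }, myouq_error = function(e) e)
    if (inherits(res, "myouq_error")) {
      status[i] <- "failed"
    } else {
      status[i] <- "ok"
      rows[[i]] <- res
    }
  }
  n_failed <- sum(status == "failed")
  if (n_failed > max_fail * n) {
    abort_solver(sprintf(
      "generate_training_set: %d/%d forward solves failed (limit %.0f%%)",
      n_failed, n, 100 * max_fail))
  }
  ok <- status == "ok"
  list(inputs = design[ok, , drop = FALSE],
       qois = do.call(rbind, rows[ok]),
       status = status, n_failed = n_failed)
}

#' Corrupt quantities of interest with observation noise
#'
#' Applies the two-component Gaussian observation model: the cavity volume
#' receives independent noise with standard deviation `sigma0` (ml,
#' default 5) and each of the 24 circumferential strains receives iid
#' noise with standard deviation `sigma_strain` (default 0.03).
#' Longitudinal and radial strains are not part of the observation,
#' matching what can be measured reliably in vivo.
#'
#' @param q an `lv_qoi` from [compute_qois()].
#' @param sigma0 volume noise SD, ml.
#' @param sigma_strain strain noise SD, dimensionless.
#' @param seed integer seed.
#' @return a list of class `lv_observation` with `y0` (volume, ml) and
#'   `y_tilde` (24 circumferential strains).
#' @export
add_observation_noise <- function(q, sigma0 = 5, sigma_strain = 0.03, seed = 1) {
  if (sigma0 < 0 || sigma_strain < 0) {
    abort_validation("add_observation_noise: noise SDs must be >= 0")
  }
  noise <- with_seed(derive_seed(seed, 101L), stats::rnorm(25))
  structure(list(
    y0 = q$lvv + sigma0 * noise[1],
    y_tilde = as.numeric(q$eps_cc) + sigma_strain * noise[2:25]
  ), class = "lv_observation")
}

#' Synthetic test battery for the inverse study
#'
#' Generates `n_cases` ground-truth reduced material-parameter
#' configurations (log-uniform on `[0.1, 10]`), runs the forward model for
#' every case at every pressure in `edp_list` with fibre angles fixed at
#' 60 / -90 degrees, and corrupts each result with the observation noise
#' model.  The same material configurations are reused across all
#' pressures.  Solver failures are logged per case/pressure and the
#' affected case is dropped.
#'
#' @param n_cases number of ground-truth configurations.
#' @param edp_list pressures, mmHg.
#' @param bounds `c(lower, upper)` for the log-uniform truth distribution.
#' @param seed integer seed (truth draw and observation noise).
#' @param spec,layout forward-model geometry and segment layout.
#' @param sigma0,sigma_strain observation noise SDs.
#' @return a list of class `iuq_battery`: per retained case a list with
#'   `theta` (named truth vector), `lvv10` (noiseless volume at 10 mmHg if
#'   computed), `obs` (named by EDP: `lv_observation` plus the noiseless
#'   `qoi`); attributes record failures and settings.
#' @export
generate_test_battery <- function(n_cases = 100, edp_list = c(5, 10, 15, 20, 25),
                                  bounds = c(0.1, 10), seed = 1,
                                  spec = lv_geometry(), layout = segment_layout(),
                                  sigma0 = 5, sigma_strain = 0.03) {
  if (n_cases < 1) abort_validation("generate_test_battery: n_cases must be >= 1")
  theta <- with_seed(derive_seed(seed, 11L), {
    matrix(exp(stats::runif(4 * n_cases, log(bounds[1]), log(bounds[2]))),
           ncol = 4, dimnames = list(NULL, REDUCED_NAMES))
  })
  cases <- vector("list", n_cases)
  failures <- character(0)
  for (i in seq_len(n_cases)) {
    th <- theta[i, ]
    pars <- do.call(ho_params_reduced, as.list(th))
    obs <- list()
    ok <- TRUE
    for (edp in edp_list) {
      res <- tryCatch({
        cfg <- solve_inflation(lv_input(pars, edp), spec)
        q <- compute_qois(cfg, layout)
        list(qoi = q,
             obs = add_observation_noise(q, sigma0, sigma_strain,
                                         seed = derive_seed(seed, i * 1000L + as.integer(edp))))
      }, myouq_error = function(e) e)
      if (inherits(res, "myouq_error")) {
        failures <- c(failures, sprintf("case %d edp %g: %s", i, edp, conditionMessage(res)))
        ok <- FALSE
        break
      }
      obs[[as.character(edp)]] <- res
    }
    if (ok) {
      lvv10 <- if ("10" %in% names(obs)) obs[["10"]]$qoi$lvv else NA_real_
      cases[[i]] <- list(id = i, theta = th, lvv10 = lvv10, obs = obs)
    }
  }
  cases <- Filter(Negate(is.null), cases)
  structure(cases, class = "iuq_battery",
            edp_list = edp_list, seed = seed, failures = failures,
            sigma0 = sigma0, sigma_strain = sigma_strain,
            n_requested = n_cases)
}
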