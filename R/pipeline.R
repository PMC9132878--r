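## End-to-end drivers tying the modules into the two studies (sensitivity
## analysis and inverse UQ), with declarative YAML configuration and
## CSV/JSON report bundles.

#' Default run configuration
#'
#' Returns the full set of tunable settings of the two study drivers with
#' desk-scale defaults; any subset can be overridden via `...` or a YAML
#' file ([read_run_config()]).  Seeds are split by purpose (design, noise,
#' GP sampling, MCMC) so stages are independently reproducible.
#'
#' @param ... named overrides.
#' @return a list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    geometry = list(R_i = 25, R_o = 35, L = 80, alpha_endo = 60,
                    alpha_epi = -90, n_quad = 16),
    layout_seed = 1234,
    sa = list(n_train = 400, n_test = 50, N = 512, n_gp_samples = 250,
              q2_gate = 0.9, edp_grid = seq(5, 25, by = 2.5),
              gp_restarts = 2),
    iuq = list(n_train = 2000, n_cases = 20, edp_list = c(5, 10, 15, 20, 25),
               sigma0 = 5, sigma_strain = 0.03,
               n_chains = 5, n_warmup = 500, n_draws = 1000,
               gp_restarts = 1),
    stress = list(grid = c(1.02, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3), thin = 500)
  )
  utils::modifyList(cfg, list(...))
}

#' Read/write run configurations (YAML)
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  utils::modifyList(default_config(), raw)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_geometry <- function(cfg) do.call(lv_geometry, cfg$geometry)

## Fit the four SA emulators (lvv + starred strains) on the two-block
## design; returns list(emulators, q2, test info).
fit_sa_emulators <- function(cfg, progress = FALSE) {
  spec <- config_geometry(cfg)
  layout <- segment_layout(cfg$layout_seed)
  star <- star_segment_index(layout)
  design <- sa_training_design(cfg$sa$n_train)
  ds <- generate_training_set(design, spec, layout)
  ## held-out test block: continue the Sobol stream, log-space materials
  test_design <- sobol_design(cfg$sa$n_test,
                              space = ifelse(names(default_input_bounds()) %in% MATERIAL_NAMES,
                                             "log", "linear"),
                              skip = cfg$sa$n_train)
  ## the log-space test block concentrates on soft configurations, where
  ## simulation failures are most common; tolerate a higher drop rate
  ts <- generate_training_set(test_design, spec, layout, max_fail = 0.25)
  cols <- c(lvv = "lvv", eps_cc_star = paste0("eps_cc_", star),
            eps_ll_star = paste0("eps_ll_", star),
            eps_rr_star = paste0("eps_rr_", star))
  emulators <- list()
  q2s <- numeric(0)
  for (nm in names(cols)) {
    if (progress) message("fitting SA emulator: ", nm)
    em <- gp_fit(ds$inputs, ds$qois[, cols[[nm]]],
                 restarts = cfg$sa$gp_restarts, seed = derive_seed(cfg$seed, 20L))
    emulators[[nm]] <- em
    q2s[nm] <- q2(ts$qois[, cols[[nm]]], gp_predict(em, ts$inputs)$mean)
  }
  list(emulators = emulators, q2 = q2s, n_train = nrow(ds$inputs),
       n_test = nrow(ts$inputs))
}

## Emulators for the reduced 5-input space (log-material x pressure) used
## by SA2 and the inverse study; outputs = lvv + all 24 eps_cc (+ starred
## cc for SA2).  Hyperparameter fits are warm-started from the first
## strain emulator since the 24 strain outputs are closely related.
fit_iuq_emulators <- function(cfg, outputs = c("lvv", "eps_cc"), progress = FALSE) {
  spec <- config_geometry(cfg)
  layout <- segment_layout(cfg$layout_seed)
  bounds <- default_input_bounds()[c(REDUCED_NAMES, "edp")]
  design <- sobol_design(cfg$iuq$n_train, bounds,
                         space = c(rep("log", 4), "linear"))
  fixed <- as.list(HO_FIXED_SHEET_SHEAR)
  full <- cbind(design[REDUCED_NAMES],
                as.data.frame(fixed)[rep(1, nrow(design)), ],
                design["edp"],
                alpha_endo = 60, alpha_epi = -90)
  ds <- generate_training_set(full, spec, layout)
  X <- ds$inputs[, c(REDUCED_NAMES, "edp")]
  fit1 <- function(y, init = NULL, restarts = cfg$iuq$gp_restarts) {
    gp_fit(X, y, restarts = restarts, init = init,
           seed = derive_seed(cfg$seed, 30L))
  }
  ems <- list()
  if ("lvv" %in% outputs) {
    if (progress) message("fitting volume emulator")
    ems$lvv <- fit1(ds$qois[, "lvv"])
  }
  if ("eps_cc" %in% outputs) {
    if (progress) message("fitting strain emulators")
    first <- fit1(ds$qois[, "eps_cc_1"])
    ems$eps_cc <- vector("list", 24)
    ems$eps_cc[[1]] <- first
    warm <- first$hyp
    for (k in 2:24) {
      ems$eps_cc[[k]] <- fit1(ds$qois[, paste0("eps_cc_", k)],
                              init = warm, restarts = 1)
    }
  }
  ems$design <- ds
  ems
}

#' Full sensitivity-analysis study
#'
#' Generates the training design, runs the forward model, fits and
#' validates the four output emulators (refusing to proceed when held-out
#' predictive accuracy falls below the gate), then runs both sensitivity
#' experiments and writes tidy CSV reports plus a JSON manifest.
#'
#' @param cfg a [default_config()] list.
#' @param outdir output directory (created; default `tempdir()` subdir).
#' @param progress print stage messages.
#' @return list with `sa1`, `sa2` (tidy data.frames), `q2`, paths.
#' @export
run_full_sa <- function(cfg = default_config(), outdir = NULL, progress = FALSE) {
  outdir <- outdir %||% file.path(tempdir(), "myouq_sa")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(msg) if (progress) message("[sa] ", msg)
  stage("fitting emulators (11-input space)")
  fit <- fit_sa_emulators(cfg, progress = progress)
  if (any(fit$q2 < cfg$sa$q2_gate)) {
    abort_validation(sprintf(
      "run_full_sa: emulator validation failed, min Q2 = %.3f < gate %.2f",
      min(fit$q2), cfg$sa$q2_gate))
  }
  stage("sensitivity analysis one")
  sa1 <- run_sa1(fit$emulators, N = cfg$sa$N, n_gp_samples = cfg$sa$n_gp_samples,
                 seed = derive_seed(cfg$seed, 41L))
  stage("sensitivity analysis two (per-pressure, reduced model)")
  iuq_ems <- fit_iuq_emulators(cfg, outputs = c("lvv", "eps_cc"), progress = progress)
  layout <- segment_layout(cfg$layout_seed)
  star <- star_segment_index(layout)
  sa2 <- run_sa2(list(lvv = iuq_ems$lvv, eps_cc_star = iuq_ems$eps_cc[[star]]),
                 edp_grid = cfg$sa$edp_grid,
                 N = cfg$sa$N, n_gp_samples = cfg$sa$n_gp_samples,
                 seed = derive_seed(cfg$seed, 42L))
  utils::write.csv(sa1, file.path(outdir, "sa1_indices.csv"), row.names = FALSE)
  utils::write.csv(sa2, file.path(outdir, "sa2_indices.csv"), row.names = FALSE)
  jsonlite::write_json(list(q2 = as.list(fit$q2), config = cfg),
                       file.path(outdir, "sa_manifest.json"), auto_unbox = TRUE)
  write_run_config(cfg, file.path(outdir, "config.yaml"))
  list(sa1 = sa1, sa2 = sa2, q2 = fit$q2, outdir = outdir)
}

#' Full inverse-UQ study
#'
#' Builds the synthetic test battery, fits the 25-output emulator stack
#' over the joint (log-material, pressure) space, runs the per-case MCMC
#' battery with convergence flags, and summarizes identifiability in
#' parameter space (I-IQR, volume-binned) and stress-stretch space.
#'
#' @param cfg a [default_config()] list.
#' @param outdir output directory.
#' @param progress print stage messages.
#' @return list with `battery_table`, `stress_table`, `lvv_cuts`, `stack`,
#'   paths.
#' @export
run_full_iuq <- function(cfg = default_config(), outdir = NULL, progress = FALSE) {
  outdir <- outdir %||% file.path(tempdir(), "myouq_iuq")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(msg) if (progress) message("[iuq] ", msg)
  stage("fitting 25-output emulator stack")
  ems <- fit_iuq_emulators(cfg, progress = progress)
  stack <- emulator_stack(c(list(ems$lvv), ems$eps_cc))
  stage("generating test battery")
  battery <- generate_test_battery(cfg$iuq$n_cases, cfg$iuq$edp_list,
                                   seed = derive_seed(cfg$seed, 50L),
                                   spec = config_geometry(cfg),
                                   layout = segment_layout(cfg$layout_seed),
                                   sigma0 = cfg$iuq$sigma0,
                                   sigma_strain = cfg$iuq$sigma_strain)
  stage("running MCMC battery")
  res <- run_iuq_battery(battery, stack,
                         n_chains = cfg$iuq$n_chains,
                         n_warmup = cfg$iuq$n_warmup,
                         n_draws = cfg$iuq$n_draws,
                         seed = derive_seed(cfg$seed, 51L),
                         sigma0_sq = cfg$iuq$sigma0^2,
                         progress = progress)
  stage("stress-stretch push-forward")
  stress_rows <- list()
  for (case in battery) {
    truth_pars <- do.call(ho_params_reduced, as.list(case$theta))
    truth <- stress_stretch_curve(truth_pars, "fibre", cfg$stress$grid)
    for (edp in names(case$obs)) {
      fit <- tryCatch(
        run_mcmc(case$obs[[edp]]$obs, stack, edp = as.numeric(edp),
                 n_chains = cfg$iuq$n_chains, n_warmup = cfg$iuq$n_warmup,
                 n_draws = cfg$iuq$n_draws,
                 seed = derive_seed(cfg$seed, case$id * 100L + as.integer(as.numeric(edp))),
                 sigma0_sq = cfg$iuq$sigma0^2),
        myouq_error = function(e) NULL)
      if (is.null(fit)) next
      dist <- posterior_stress_curves(posterior_theta(fit), "fibre",
                                      cfg$stress$grid, thin = cfg$stress$thin)
      stress_rows[[paste(case$id, edp)]] <- data.frame(
        case = case$id, edp = as.numeric(edp), stretch = cfg$stress$grid,
        iiqr = vapply(cfg$stress$grid, function(l) stress_iiqr(dist, l), numeric(1)),
        inv_abs_err = vapply(cfg$stress$grid, function(l)
          as.numeric(median_inverse_abs_error(dist, truth, l)), numeric(1)),
        row.names = NULL)
    }
  }
  stress_table <- do.call(rbind, stress_rows)
  utils::write.csv(res$table, file.path(outdir, "iuq_iiqr.csv"), row.names = FALSE)
  utils::write.csv(stress_table, file.path(outdir, "stress_stretch.csv"), row.names = FALSE)
  jsonlite::write_json(list(lvv_cuts = res$lvv_cuts,
                            n_cases = length(battery),
                            failures = attr(battery, "failures"),
                            config = cfg),
                       file.path(outdir, "iuq_manifest.json"), auto_unbox = TRUE)
  write_run_config(cfg, file.path(outdir, "config.yaml"))
  list(battery_table = res$table, stress_table = stress_table,
       lvv_cuts = res$lvv_cuts, stack = stack, outdir = outdir)
}
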