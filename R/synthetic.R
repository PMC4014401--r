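# Synthetic titration data emulating the two published dataset shapes:
# phosphorylated regulator vs total regulator (robustness titrations, in both
# the plateau and the hyperbolic regime) and phosphorylated regulator vs
# effector (graded, ultrasensitive and autodephosphorylation-damped regimes).

#' Measurement-noise model for synthetic titrations
#'
#' Multiplicative Gaussian noise with fixed coefficient of variation:
#' `y = prediction * (1 + cv * z)`, truncated at `floor`.  Gel/Phos-tag
#' quantifications have roughly proportional error, which this emulates.
#'
#' @param cv coefficient of variation (>= 0, default 0.05)
#' @param floor truncation floor (uM, default 0)
#' @param seed integer seed; required whenever `cv > 0`
#' @return an object of class `noise_model`
#' @export
noise_model <- function(cv = 0.05, floor = 0, seed = NULL) {
  cv <- check_scalar(cv, "cv")
  floor <- check_scalar(floor, "floor")
  if (cv > 0 && is.null(seed))
    stop_validation("a seed is required for any nonzero cv")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(kind = "additive_gaussian_cv", cv = cv, floor = floor,
                 seed = seed), class = "noise_model")
}

#' Catalog of regime presets
#'
#' Named parameter sets realizing the operating regimes of the theory, each
#' with a default sweep and solver:
#' \describe{
#'   \item{plateau_robust}{Batchelor-Goulian constants with `K1 >> K2`: the
#'     response rises linearly with total regulator and plateaus at `K1`,
#'     threshold and plateau coincide.}
#'   \item{hyperbolic_robust}{`K1 << K2`: hyperbolic approach, threshold far
#'     above the asymptotic level.}
#'   \item{graded_low_affinity}{two-component system with `lambda = 1e3` and a
#'     non-saturated transfer side: hyperbolic (Hill ~ 1) effector response.}
#'   \item{ultrasensitive_high_affinity}{`lambda = 1e-3` with both apparent
#'     Michaelis constants at 1% of `R_T`: zero-order switch in the effector.}
#'   \item{nri_like_autodephos}{high-affinity system with regulator
#'     autodephosphorylation at `k_auto = ln(2)/5` per minute (5-minute
#'     half-life), damping the switch as observed for NRII/NRI.}
#' }
#' Every preset is checked against its own regime label at construction.
#'
#' @return a named list of `regime_preset` objects
#' @export
preset_catalog <- function() {
  presets <- list(
    plateau_robust = regime_preset(
      name = "plateau_robust",
      params = bg_params(K1 = 1, K2 = 0.005, R_T = 1),
      sweep = list(variable = "R_T", grid = lseq(0.01, 31.6, 40)),
      solver = "bg",
      label = NA_character_),
    hyperbolic_robust = regime_preset(
      name = "hyperbolic_robust",
      params = bg_params(K1 = 0.2, K2 = 5, R_T = 1),
      sweep = list(variable = "R_T", grid = lseq(0.05, 1000, 40)),
      solver = "bg",
      label = NA_character_),
    graded_low_affinity = regime_preset(
      name = "graded_low_affinity",
      params = tcs_params(k_ap = 50, k_ad = 50,
                          pt_on = 0.1, pt_off = 50, pt_cat = 50,
                          ph_on = 1, ph_off = 50, ph_cat = 50,
                          eff_on = 10, eff_off = 100,
                          R_T = 10, H_T = 0.01, L_T = 1),
      sweep = list(variable = "L_T", grid = lseq(1e-3, 1e3, 33)),
      solver = "ode",
      label = "low_affinity_graded"),
    ultrasensitive_high_affinity = regime_preset(
      name = "ultrasensitive_high_affinity",
      params = tcs_params(k_ap = 50, k_ad = 50,
                          pt_on = 1000, pt_off = 50, pt_cat = 50,
                          ph_on = 1000, ph_off = 50, ph_cat = 50,
                          eff_on = 5e5, eff_off = 50,
                          R_T = 10, H_T = 0.1, L_T = 0.02),
      sweep = list(variable = "L_T", grid = lseq(0.002, 0.09, 33)),
      solver = "ode",
      label = "high_affinity_ultrasensitive"),
    nri_like_autodephos = regime_preset(
      name = "nri_like_autodephos",
      params = tcs_params(k_ap = 100, k_ad = 100,
                          pt_on = 50, pt_off = 100, pt_cat = 100,
                          ph_on = 50, ph_off = 100, ph_cat = 100,
                          eff_on = 1e5, eff_off = 100,
                          k_auto = log(2) / 5,
                          R_T = 50, H_T = 0.1, L_T = 0.02),
      sweep = list(variable = "L_T", grid = lseq(5e-4, 0.09, 25)),
      solver = "ode",
      label = "high_affinity_ultrasensitive"))
  presets
}

regime_preset <- function(name, params, sweep, solver, label) {
  if (!is.na(label)) {
    got <- classify_regime(params)$regime
    if (!identical(got, label))
      stop_validation(sprintf("preset '%s' classifies as '%s', expected '%s'",
                              name, got, label))
  }
  structure(list(name = name, params = params, sweep = sweep,
                 solver = solver, label = label),
            class = "regime_preset")
}

#' Fetch one preset by name
#' @param name a preset name, see [preset_catalog()]
#' @return a `regime_preset`
#' @export
get_preset <- function(name) {
  cat <- preset_catalog()
  if (!name %in% names(cat))
    stop_validation(sprintf("unknown preset '%s' (available: %s)",
                            name, paste(names(cat), collapse = ", ")))
  cat[[name]]
}

#' Generate a synthetic titration dataset
#'
#' Computes the steady-state response over the sweep and perturbs it with the
#' noise model: `y = prediction * (1 + cv * z)`, truncated at the floor.
#' Deterministic for a fixed seed; the ground-truth parameters and the seed
#' are attached to the returned dataset for recovery scoring.
#'
#' @param x a `regime_preset` (its sweep and solver are the defaults) or a
#'   parameter object
#' @param noise a [noise_model()]
#' @param sweep list with `variable` and `grid` (required when `x` is a
#'   parameter object)
#' @param solver passed to [build_response_curve()]
#' @param control [ss_control()] settings for ODE sweeps
#' @return a [titration_dataset()] with attributes `ground_truth`, `seed`,
#'   `solver`
#' @export
generate_titration <- function(x, noise = noise_model(cv = 0), sweep = NULL,
                               solver = NULL, control = ss_control()) {
  if (inherits(x, "regime_preset")) {
    params <- x$params
    sweep <- sweep %||% x$sweep
    solver <- solver %||% x$solver
  } else {
    params <- x
    if (is.null(sweep)) stop_validation("a sweep spec is required")
    solver <- solver %||% "ode"
  }
  curve <- build_response_curve(params, sweep$variable, sweep$grid,
                                solver = solver, control = control)
  pred <- curve$values
  y <- if (noise$cv > 0) {
    z <- with_seed(noise$seed, stats::rnorm(length(pred)))
    pmax(pred * (1 + noise$cv * z), noise$floor)
  } else pred
  ds <- titration_dataset(
    x = sweep$grid, y = y,
    x_meaning = if (sweep$variable == "L_T") "effector" else "total_regulator")
  attr(ds, "ground_truth") <- params
  attr(ds, "seed") <- noise$seed
  attr(ds, "solver") <- solver
  ds
}
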