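#' Steady-state response curves
#'
#' A response curve is a monotone sweep of one total concentration against the
#' steady-state phosphorylated output, with the parameter snapshot and solver
#' tag attached.
#'
#' @param variable swept total: `"L_T"`, `"R_T"` or `"S_T"`
#' @param grid strictly increasing sweep values (uM)
#' @param values steady-state outputs (uM), same length as `grid`
#' @param params parameter snapshot the curve was computed from
#' @param solver solver tag (`"ode"`, `"low_affinity"`, `"high_affinity"`,
#'   `"bg"`, ...)
#' @return an object of class `response_curve`
#' @export
response_curve <- function(variable, grid, values, params = NULL,
                           solver = "unknown") {
  if (!variable %in% c("L_T", "R_T", "S_T"))
    stop_validation("sweep variable must be one of L_T, R_T, S_T")
  if (length(grid) != length(values))
    stop_validation("grid and values must have equal length")
  if (length(grid) >= 2L && any(diff(grid) <= 0))
    stop_validation("grid must be strictly increasing")
  if (any(!is.finite(values)) || any(values < -1e-12))
    stop_validation("curve values must be finite and non-negative")
  structure(list(variable = variable, grid = as.numeric(grid),
                 values = pmax(as.numeric(values), 0), params = params,
                 solver = solver),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Response curve: output vs %s, %d points [%.3g, %.3g], solver '%s'\n",
              x$variable, length(x$grid), min(x$grid), max(x$grid), x$solver))
  invisible(x)
}

set_swept_total <- function(params, variable, value) {
  if (!variable %in% names(unclass(params)))
    stop_validation(sprintf("parameter object has no total '%s'", variable))
  params[[variable]] <- value
  params
}

#' Build a response curve by sweeping one total concentration
#'
#' Computes one steady state per grid point.  With `solver = "ode"` each point
#' is obtained from [integrate_to_steady_state()] (any model variant); the
#' algebraic solvers dispatch to the matching reduction
#' ([solve_cycle_low_affinity()], [solve_tcs_high_affinity()], ... -- for
#' `bg_params` the quadratic is used directly).  A grid point that fails to
#' converge raises an error naming the point.
#'
#' @param params parameter object (`cycle_params`, `tcs_params`,
#'   `basal_tcs_params` or `bg_params`)
#' @param variable swept total (`"L_T"`, `"R_T"`, `"S_T"`)
#' @param grid strictly increasing sweep values
#' @param solver `"ode"`, `"low_affinity"`, `"high_affinity"` or `"bg"`
#' @param control [ss_control()] settings for the ODE solver
#' @param ... passed to the algebraic solvers (e.g. `strict`)
#' @return a [response_curve()]
#' @export
build_response_curve <- function(params, variable, grid,
                                 solver = c("ode", "low_affinity",
                                            "high_affinity", "bg"),
                                 control = ss_control(), ...) {
  solver <- match.arg(solver)
  if (inherits(params, "bg_params")) {
    if (variable != "R_T")
      stop_validation("bg_params curves sweep R_T")
    return(response_curve("R_T", grid, solve_bg_quadratic(params, R_T = grid),
                          params, "bg"))
  }
  variant <- variant_of(params)
  values <- if (solver == "ode") {
    vapply(seq_along(grid), function(i) {
      p_i <- set_swept_total(params, variable, grid[i])
      out <- tryCatch(steady_state_output(p_i, control = control),
                      error = function(e) stop_validation(sprintf(
                        "steady state failed at %s = %g (point %d): %s",
                        variable, grid[i], i, conditionMessage(e))))
      out
    }, numeric(1))
  } else {
    if (variant == "basal_tcs")
      stop_validation("no algebraic reduction for the basal model; use solver = 'ode'")
    if (variable != "L_T")
      stop_validation("algebraic reductions sweep L_T; use solver = 'ode' for other sweeps")
    switch(paste(variant, solver, sep = "."),
      cycle.low_affinity = params$S_T * solve_cycle_low_affinity(params, L_T = grid, ...),
      cycle.high_affinity = params$S_T * solve_cycle_high_affinity(params, L_T = grid, ...),
      tcs.low_affinity = solve_tcs_low_affinity(params, L_T = grid, ...),
      tcs.high_affinity = solve_tcs_high_affinity(params, L_T = grid, ...),
      stop_validation(sprintf("solver '%s' unavailable for variant '%s'",
                              solver, variant)))
  }
  response_curve(variable, grid, values, params, solver)
}

#' Effective Hill coefficient of a monotone response curve
#'
#' Operationalized through the 10%/90% points of the dynamic range:
#' `n_H = ln(81) / |ln(x90 / x10)|`, where `x10` and `x90` are the sweep
#' values at which the output crosses 10% and 90% of its dynamic range,
#' obtained by monotone interpolation on the logarithmic sweep axis.  An
#' exact Hill curve of exponent `n` yields `n_H = n`; decreasing curves are
#' handled through the reciprocal ratio.
#'
#' @param curve a [response_curve()] with at least 8 points, monotone over its
#'   span, positive dynamic range, and 10%/90% levels bracketed by the grid
#' @param monotone_tol relative tolerance on monotonicity violations
#' @return an object of class `hill_estimate`: list with `n_H`, `x10`, `x90`,
#'   `direction`
#' @export
hill_coefficient <- function(curve, monotone_tol = 1e-6) {
  stopifnot(inherits(curve, "response_curve"))
  x <- curve$grid
  y <- curve$values
  if (length(x) < 8L)
    stop_validation("Hill estimation requires at least 8 grid points")
  if (any(x <= 0))
    stop_validation("Hill estimation requires a positive sweep grid")
  rng <- max(y) - min(y)
  if (rng <= 0) stop_validation("curve has no dynamic range")
  d <- diff(y)
  tol <- monotone_tol * rng
  if (all(d >= -tol)) direction <- "increasing"
  else if (all(d <= tol)) direction <- "decreasing"
  else stop_validation("curve is not monotone; refusing to estimate a Hill coefficient")
  ys <- if (direction == "increasing") y else rev(y)
  xs <- if (direction == "increasing") log(x) else rev(log(x))
  ys <- cummax(ys)  # flatten round-off wiggles within tolerance
  lv10 <- min(y) + 0.1 * rng
  lv90 <- min(y) + 0.9 * rng
  x_at <- function(level) {
    if (level < ys[1L] || level > ys[length(ys)])
      stop_validation("10%/90% levels not bracketed by the grid")
    exp(stats::approx(ys, xs, xout = level, ties = "ordered")$y)
  }
  x10 <- x_at(lv10)
  x90 <- x_at(lv90)
  if (x10 == x90) stop_validation("degenerate dynamic range: x10 == x90")
  structure(list(n_H = log(81) / abs(log(x90 / x10)),
                 x10 = x10, x90 = x90, direction = direction),
            class = "hill_estimate")
}

#' @export
print.hill_estimate <- function(x, ...) {
  cat(sprintf("Effective Hill coefficient n_H = %.3g (%s; x10 = %.4g, x90 = %.4g)\n",
              x$n_H, x$direction, x$x10, x$x90))
  invisible(x)
}

#' Half-maximal sweep value of a monotone response curve
#'
#' Location at which the output crosses 50% of its dynamic range (log-axis
#' interpolation), e.g. the observed transition point of a switch-like curve.
#'
#' @param curve a monotone [response_curve()]
#' @return sweep value (uM)
#' @export
half_max_point <- function(curve) {
  x <- curve$grid
  y <- curve$values
  rng <- max(y) - min(y)
  if (rng <= 0) stop_validation("curve has no dynamic range")
  inc <- y[length(y)] >= y[1L]
  ys <- if (inc) y else rev(y)
  xs <- if (inc) log(x) else rev(log(x))
  exp(stats::approx(cummax(ys), xs, xout = min(y) + 0.5 * rng,
                    ties = "ordered")$y)
}

#' Concentration-robustness report of a total-protein sweep
#'
#' Quantifies the plateau of a saturating sweep (e.g. phosphorylated regulator
#' vs total regulator): the plateau is the mean output over the top decade of
#' the sweep, the threshold is the first crossing of 95% of the plateau
#' (log-axis interpolation), and the maximal log-log slope over the top decade
#' -- which must lie beyond the threshold -- measures how flat the robust
#' branch is.  If that slope exceeds `slope_tol` the curve has not flattened
#' and an error is raised; sweeps should therefore extend well past the
#' expected threshold.
#'
#' @param curve a [response_curve()] over a total-protein sweep (>= 8 points)
#' @param level plateau fraction defining the threshold (default 0.95)
#' @param slope_tol maximal admissible log-log slope beyond the threshold
#' @return an object of class `robustness_report`: list with `plateau` (uM),
#'   `threshold` (uM) and `max_loglog_slope`
#' @export
robustness_report <- function(curve, level = 0.95, slope_tol = 0.05) {
  stopifnot(inherits(curve, "response_curve"))
  x <- curve$grid
  y <- curve$values
  if (length(x) < 8L) stop_validation("robustness report requires at least 8 points")
  if (any(x <= 0) || any(y <= 0))
    stop_validation("robustness report requires positive grid and outputs")
  top <- x >= max(x) / 10
  plateau <- mean(y[top])
  target <- level * plateau
  if (max(y) < target)
    stop_validation("no plateau detected: curve never reaches the plateau level")
  idx <- which(y >= target)[1L]
  threshold <- if (idx == 1L) x[1L]
  else exp(stats::approx(y[(idx - 1L):idx], log(x[(idx - 1L):idx]),
                         xout = target, ties = "ordered")$y)
  slopes <- diff(log(y)) / diff(log(x))
  mid <- exp((log(x[-1L]) + log(x[-length(x)])) / 2)
  beyond <- mid > max(threshold, max(x) / 10)
  max_slope <- if (any(beyond)) max(abs(slopes[beyond])) else 0
  if (max_slope > slope_tol)
    stop_validation(sprintf(
      "no plateau detected: max log-log slope beyond threshold is %.3g > %g",
      max_slope, slope_tol))
  structure(list(plateau = plateau, threshold = threshold,
                 max_loglog_slope = max_slope),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("Robustness: plateau %.4g uM, 95%% threshold %.4g uM, max log-log slope %.3g\n",
              x$plateau, x$threshold, x$max_loglog_slope))
  invisible(x)
}

#' Stimulus dependence of concentration robustness
#'
#' For a low-affinity two-component system, sweeps the total regulator at each
#' requested effector concentration (Batchelor-Goulian quadratic with the
#' effective constant [effective_k1()]) and reports plateau and threshold per
#' effector level.  In the plateau regime (`K1 >> K2`) threshold and plateau
#' move together with the stimulus; in the hyperbolic regime (`K1 << K2`) the
#' stimulus rescales the plateau while the threshold, set by `K2`, stays put.
#'
#' @param params a low-affinity [tcs_params()] object
#' @param L_T_set effector concentrations (uM)
#' @param R_T_grid strictly increasing total-regulator sweep (uM)
#' @param ... passed to [robustness_report()]
#' @return a data frame with columns `L_T`, `plateau`, `threshold`,
#'   `max_loglog_slope`; the individual reports are attached as attribute
#'   `"reports"`
#' @export
stimulus_dependent_robustness <- function(params, L_T_set, R_T_grid, ...) {
  stopifnot(inherits(params, "tcs_params"))
  check_regime(relative_affinity(params) >= 100,
               "stimulus-dependent robustness is a low-affinity analysis",
               strict = FALSE)
  reports <- lapply(L_T_set, function(l) {
    curve <- build_response_curve(as_bg_params(params, L_T = l), "R_T", R_T_grid)
    robustness_report(curve, ...)
  })
  out <- data.frame(L_T = L_T_set,
                    plateau = vapply(reports, `[[`, numeric(1), "plateau"),
                    threshold = vapply(reports, `[[`, numeric(1), "threshold"),
                    max_loglog_slope = vapply(reports, `[[`, numeric(1),
                                              "max_loglog_slope"))
  attr(out, "reports") <- reports
  out
}

#' Read and write response curves as CSV with a JSON sidecar
#'
#' The CSV holds the sweep (`x`) and output (`value`) columns; the sidecar
#' `<path>.json` stores the sweep variable, solver tag and parameter snapshot.
#'
#' @param curve a [response_curve()]
#' @param path CSV file path
#' @return `read_response_curve()` returns a [response_curve()];
#'   `write_response_curve()` returns `path` invisibly.
#' @export
write_response_curve <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$grid, value = curve$values),
                   path, row.names = FALSE)
  meta <- list(variable = curve$variable, solver = curve$solver,
               params = if (!is.null(curve$params)) params_to_list(curve$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_response_curve
#' @export
read_response_curve <- function(path) {
  d <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(variable = "L_T", solver = "unknown")
  params <- NULL
  if (!is.null(meta$params)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(meta$params, tmp, auto_unbox = TRUE, digits = NA)
    params <- read_params(tmp)
  }
  response_curve(meta$variable, d$x, d$value, params, meta$solver %||% "unknown")
}
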