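#' Controls for steady-state integration
#'
#' Steady states are located by stiff adaptive time integration with a
#' doubling horizon: the system is integrated over successive chunks, the
#' total integrated time doubling from chunk to chunk, until (i) the
#' infinity-norm of the right-hand side falls below
#' `rhs_tol * max(1, max(state))` and (ii) the state changes by less than
#' `change_tol` (relative) over a doubling of the integration time.
#'
#' @param rtol,atol relative/absolute tolerances of the ODE solver
#' @param rhs_tol relative residual tolerance declaring a steady state
#' @param change_tol relative state-change tolerance over a time doubling
#' @param t0 first integration horizon (model minutes)
#' @param max_time integration horizon after which non-convergence is an error
#' @param method a [deSolve::ode()] method; the default `"bdf"` (backward
#'   differentiation formulas) suits the stiff binding/catalysis timescale
#'   separation of these models
#' @return a list of control settings
#' @export
ss_control <- function(rtol = 1e-10, atol = 1e-12, rhs_tol = 1e-10,
                       change_tol = 1e-8, t0 = 1, max_time = 1e9,
                       method = "bdf") {
  list(rtol = rtol, atol = atol, rhs_tol = rhs_tol, change_tol = change_tol,
       t0 = t0, max_time = max_time, method = method)
}

#' Integrate a model variant to steady state
#'
#' The reference ("oracle") steady-state solver: stiff time integration of the
#' full mass-action system until the residual and state-change criteria of
#' [ss_control()] are met.  Deterministic for fixed inputs.
#'
#' @param params a `cycle_params`, `tcs_params` or `basal_tcs_params` object
#' @param init initial state; defaults to [default_initial_state()] (all
#'   protein free and unmodified).  Must satisfy the parameter conservation
#'   totals.
#' @param control see [ss_control()]
#' @return an object of class `steady_state_result`: list with elements
#'   `state`, `residual_norm` (uM/min), `time_to_converge` (model minutes),
#'   `method`, `variant`
#' @export
integrate_to_steady_state <- function(params, init = NULL,
                                      control = ss_control()) {
  variant <- variant_of(params)
  if (is.null(init)) init <- default_initial_state(params)
  init <- validate_state(init, variant)
  want <- c(substrate = switch(variant, cycle = params$S_T, params$R_T),
            enzyme = total_enzyme(params),
            effector = params$L_T)
  have <- conservation_totals(init, variant)
  if (any(abs(have - want) > 1e-8 * pmax(1, want)))
    stop_validation("initial state does not satisfy the parameter conservation totals")

  raw <- rhs_raw_fn(variant)
  deriv <- function(t, y, p) list(raw(y, p))
  state <- init
  t_acc <- 0
  t_chunk <- control$t0
  repeat {
    # convergence is verified below from the residual itself, so the
    # integrator's own step-budget warnings are not informative here
    out <- suppressWarnings(
      deSolve::ode(y = state, times = c(0, t_chunk), func = deriv,
                   parms = params, method = control$method,
                   rtol = control$rtol, atol = control$atol,
                   maxsteps = 500000))
    if (nrow(out) < 2L || any(!is.finite(out[2L, -1L])))
      stop_validation("ODE integration failed before reaching a steady state")
    prev <- state
    state <- pmax(out[2L, -1L], 0)
    t_acc <- t_acc + t_chunk
    rhs <- raw(state, params)
    res <- max(abs(rhs))
    change <- max(abs(state - prev)) / max(1, max(abs(state)))
    if (res < control$rhs_tol * max(1, max(abs(state))) &&
        change < control$change_tol) {
      return(structure(list(state = state, residual_norm = res,
                            time_to_converge = t_acc, method = "ode",
                            variant = variant),
                       class = "steady_state_result"))
    }
    if (t_acc >= control$max_time)
      stop_validation(sprintf(
        "no steady state within %g model minutes (residual %.3g)",
        control$max_time, res))
    t_chunk <- t_acc  # double the total integrated time
  }
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Steady state (%s, %s): residual %.3g uM/min after %.3g min\n",
              x$variant, x$method, x$residual_norm, x$time_to_converge))
  print(signif(x$state, 6))
  invisible(x)
}

# convenience: steady-state phosphorylated output for given parameters
steady_state_output <- function(params, control = ss_control()) {
  res <- integrate_to_steady_state(params, control = control)
  phosphorylated_output(res$state, res$variant)
}
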