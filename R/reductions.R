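# Closed-form steady-state reductions, apparent parameters, regime
# diagnostics.  All reductions are validated against the ODE oracle in the
# test suite; each carries an explicit validity regime and warns (or errors,
# with strict = TRUE) outside it.

regime_thresholds <- function(low = 100, high = 0.01) list(low = low, high = high)

check_regime <- function(ok, msg, strict) {
  if (!ok) {
    if (strict) stop_validation(msg) else warning(msg, call. = FALSE)
  }
  invisible(ok)
}

#' Low-affinity (graded) limit of the modification cycle
#'
#' When the effector affinity is low relative to the enzyme concentration
#' (`lambda = K_d/E_T` large), effector sequestration by the enzyme is
#' negligible and the steady-state modified fraction is exactly hyperbolic in
#' the total effector concentration:
#' \deqn{\phi = 1 / (1 + L_T\, k_{cat}^{pho} K_{m}^{kin} / (K_d\, k_{cat}^{kin} K_m^{pho})).}
#'
#' @param params a [cycle_params()] object
#' @param L_T optional effector concentration(s) overriding `params$L_T`
#' @param threshold minimal `lambda` for the regime (default 100)
#' @param strict error (rather than warn) on regime violation
#' @return modified fraction(s) in `[0, 1]`
#' @export
solve_cycle_low_affinity <- function(params, L_T = NULL, threshold = 100,
                                     strict = FALSE) {
  stopifnot(inherits(params, "cycle_params"))
  check_regime(relative_affinity(params) >= threshold,
               sprintf("low-affinity reduction outside regime: lambda = %.3g < %g",
                       relative_affinity(params), threshold), strict)
  lt <- if (is.null(L_T)) params$L_T else L_T
  if (any(lt < 0)) stop_validation("L_T must be non-negative")
  if (params$kin_cat == 0) return(rep(0, length(lt)))
  w <- (params$pho_cat * km_kinase(params)) /
    (params$kin_cat * km_phosphatase(params) * kd_effector(params))
  1 / (1 + w * lt)
}

#' High-affinity (zero-order) limit of the modification cycle
#'
#' A high-affinity effector (`lambda = K_d/E_T` small) is almost completely
#' sequestered by the enzyme, partitioning the enzyme into a phosphatase pool
#' of size `L_T` and a kinase pool `E_T - L_T` (see [enzyme_partition()]).
#' The modified fraction then satisfies the Goldbeter-Koshland relation with
#' `Vmax_kin = kin_cat (E_T - L_T)` and `Vmax_pho = pho_cat L_T`, so the
#' response in `L_T` becomes ultrasensitive when both activities are
#' saturated.
#'
#' Near the transition the zero-order balance amplifies the small free
#' effector concentration, which at steady state is pinned by the flux
#' balance to
#' \eqn{L = K_d\, k_{cat}^{kin} K_m^{pho} (1-\phi) / (k_{cat}^{pho} K_m^{kin} \phi)}.
#' The solver therefore iterates the Goldbeter-Koshland root with the
#' effector-corrected pools `(L_T - L, E_T - L_T + L)` to self-consistency
#' (the lowest-order free-effector correction of the reduction).
#'
#' @param params a [cycle_params()] object
#' @param L_T optional effector concentration(s) overriding `params$L_T`;
#'   must satisfy `L_T < E_T`
#' @param threshold maximal `lambda` for the regime (default 0.01)
#' @param strict error (rather than warn) on regime violation
#' @return modified fraction(s) in `[0, 1]`
#' @export
solve_cycle_high_affinity <- function(params, L_T = NULL, threshold = 0.01,
                                      strict = FALSE) {
  stopifnot(inherits(params, "cycle_params"))
  check_regime(relative_affinity(params) <= threshold,
               sprintf("high-affinity reduction outside regime: lambda = %.3g > %g",
                       relative_affinity(params), threshold), strict)
  lt <- if (is.null(L_T)) params$L_T else L_T
  if (any(lt < 0)) stop_validation("L_T must be non-negative")
  if (any(lt >= params$E_T))
    stop_validation("high-affinity reduction requires L_T < E_T (effector-limited enzyme)")
  J <- km_kinase(params) / params$S_T
  K <- km_phosphatase(params) / params$S_T
  # free effector pinned by the steady-state flux balance
  w <- kd_effector(params) * params$kin_cat * km_phosphatase(params) /
    (params$pho_cat * km_kinase(params))
  vapply(lt, function(l) {
    phi <- gk_fraction(params$kin_cat * (params$E_T - l),
                       params$pho_cat * l, J, K)
    for (i in 1:50) {
      lfree <- if (phi >= 1) 0 else min(w * (1 - phi) / max(phi, 1e-12), 0.5 * l)
      phi_new <- gk_fraction(params$kin_cat * (params$E_T - l + lfree),
                             params$pho_cat * (l - lfree), J, K)
      if (abs(phi_new - phi) < 1e-12) {
        phi <- phi_new
        break
      }
      phi <- 0.5 * (phi + phi_new)  # damped fixed point
    }
    phi
  }, numeric(1))
}

#' Effector-dependent effective phosphatase-side constant
#'
#' In the low-affinity regime the two-component steady state obeys the
#' Batchelor-Goulian quadratic with the phosphatase-side constant replaced by
#' the effective parameter
#' \deqn{K_1(L_T) = k_{ap} K_d K_m^{p} / (k_{cat}^{p} L_T),}
#' strictly decreasing and asymptotically proportional to `1/L_T` (it diverges
#' as `L_T -> 0`, where the observable response saturates at `R_T` instead).
#' This inverse law underlies stimulus-dependent concentration robustness.
#'
#' @param L_T total effector concentration(s), uM (>= 0)
#' @param params a [tcs_params()] object
#' @return effective `K1` value(s), uM (`Inf` at `L_T = 0`)
#' @export
effective_k1 <- function(L_T, params) {
  stopifnot(inherits(params, "tcs_params"))
  if (any(L_T < 0)) stop_validation("L_T must be non-negative")
  if (params$ph_cat == 0) return(rep(Inf, length(L_T)))
  ifelse(L_T == 0, Inf,
         params$k_ap * kd_effector(params) * km_phosphatase(params) /
           (params$ph_cat * L_T))
}

# phosphotransfer-side lumped constant K2 of the BG quadratic
transfer_k2 <- function(params) {
  if (params$pt_cat == 0)
    stop_validation("K2 undefined: pt_cat = 0 (no phosphotransfer)")
  params$k_ad * km_transfer(params) / params$pt_cat
}

#' Map two-component parameters onto Batchelor-Goulian lumped constants
#'
#' `K1 = effective_k1(L_T, params)`, `K2 = k_ad * Km_t / pt_cat`.
#'
#' @param params a [tcs_params()] object
#' @param L_T effector concentration (defaults to `params$L_T`)
#' @return a [bg_params()] object
#' @export
as_bg_params <- function(params, L_T = NULL) {
  lt <- L_T %||% params$L_T
  bg_params(effective_k1(lt, params), transfer_k2(params), params$R_T)
}

#' Low-affinity limit of the two-component system
#'
#' For `lambda = K_d/H_T` large the free effector equals the total effector
#' and the steady state solves the Batchelor-Goulian quadratic with the
#' effective constant of [effective_k1()]:
#' graded in `L_T`, with stimulus-dependent concentration robustness in `R_T`.
#'
#' @param params a [tcs_params()] object (`k_auto` must be 0; the reduction is
#'   derived without autodephosphorylation)
#' @param L_T optional effector concentration(s) overriding `params$L_T`
#' @param R_T optional total regulator overriding `params$R_T`
#' @param threshold minimal `lambda` (default 100)
#' @param strict error (rather than warn) on regime violation
#' @return phosphorylated regulator concentration(s), uM
#' @export
solve_tcs_low_affinity <- function(params, L_T = NULL, R_T = NULL,
                                   threshold = 100, strict = FALSE) {
  stopifnot(inherits(params, "tcs_params"))
  check_regime(relative_affinity(params) >= threshold,
               sprintf("low-affinity reduction outside regime: lambda = %.3g < %g",
                       relative_affinity(params), threshold), strict)
  if (params$k_auto != 0)
    warning("reduction ignores k_auto > 0", call. = FALSE)
  lt <- if (is.null(L_T)) params$L_T else L_T
  rt <- R_T %||% params$R_T
  if (length(lt) > 1L && length(rt) > 1L)
    stop_validation("only one of L_T, R_T may be a vector")
  k2 <- transfer_k2(params)
  if (length(lt) == 1L) {
    solve_bg_quadratic(bg_params(effective_k1(lt, params), k2, 1), R_T = rt)
  } else {
    vapply(lt, function(l) {
      solve_bg_quadratic(bg_params(effective_k1(l, params), k2, 1), R_T = rt)
    }, numeric(1))
  }
}

#' Apparent phosphotransfer parameters
#'
#' Eliminating the autophosphorylation step (H <-> Hp, rates `k_ap`, `k_ad`)
#' at steady state turns the kinase branch of the HK into a single
#' Michaelis-Menten activity in the free regulator with
#' \deqn{k_{cat}^{app} = k_{ap} k_{cat}^t / (k_{ap} + k_{cat}^t), \qquad
#'       K_m^{app} = K_m^t (k_{ap} + k_{ad}) / (k_{ap} + k_{cat}^t).}
#' In the fast-autophosphorylation limit (`k_ap -> Inf`) both reduce to the
#' intrinsic values.  When `k_ap, k_ad << pt_cat` the regulatory factor
#' `(k_ap + k_ad)/(k_ap + pt_cat)` is small, so the intrinsic `Km_t` may be
#' comparable to or larger than `R_T` (non-saturated phosphotransfer) while
#' the apparent constant stays in the zero-order regime -- at the cost of a
#' transition point shifted to lower effector concentrations.
#'
#' @param params a [tcs_params()] object with `k_ap > 0`
#' @return an object of class `apparent_transfer_params`: list with
#'   `kcat_app` (1/min), `Km_app` (uM) and the dimensionless
#'   `regulatory_factor`
#' @export
apparent_transfer_params <- function(params) {
  stopifnot(inherits(params, "tcs_params"))
  if (params$k_ap <= 0)
    stop_validation("apparent transfer parameters require k_ap > 0")
  if (params$pt_cat <= 0)
    stop_validation("apparent transfer parameters require pt_cat > 0")
  factor <- (params$k_ap + params$k_ad) / (params$k_ap + params$pt_cat)
  structure(list(
    kcat_app = params$k_ap * params$pt_cat / (params$k_ap + params$pt_cat),
    Km_app = km_transfer(params) * factor,
    regulatory_factor = factor),
    class = "apparent_transfer_params")
}

#' Tight partition of enzyme states under a high-affinity effector
#'
#' When nearly all effector is enzyme-bound (`lambda` small, `L_T` below the
#' total enzyme), the enzyme splits into a phosphatase-active pool of size
#' `L_T` (effector-bound states) and a kinase-active pool `total - L_T`
#' (effector-free states); the pools sum to the total enzyme exactly.
#'
#' @param params a [cycle_params()] or [tcs_params()] object
#' @param L_T effector concentration (defaults to `params$L_T`); `L_T <`
#'   total enzyme required
#' @param threshold maximal `lambda` (default 0.01)
#' @param strict error (rather than warn) on regime violation
#' @return named vector `c(phosphatase_pool=, kinase_pool=)` (uM)
#' @export
enzyme_partition <- function(params, L_T = NULL, threshold = 0.01,
                             strict = FALSE) {
  tot <- total_enzyme(params)
  lt <- L_T %||% params$L_T
  check_regime(relative_affinity(params) <= threshold,
               sprintf("enzyme partition outside regime: lambda = %.3g > %g",
                       relative_affinity(params), threshold), strict)
  if (lt < 0 || lt >= tot)
    stop_validation("enzyme partition requires 0 <= L_T < total enzyme")
  c(phosphatase_pool = lt, kinase_pool = tot - lt)
}

#' High-affinity limit of the two-component system
#'
#' With a high-affinity effector the steady state is structurally the
#' Goldbeter-Koshland relation on the regulator pool: kinase side
#' `kcat_app * (H_T - L_T)` with Michaelis constant `Km_app` (see
#' [apparent_transfer_params()]), phosphatase side `ph_cat * L_T` with
#' `Km_p`.  Ultrasensitive in `L_T` when both apparent constants are small
#' relative to `R_T`; the on/off transition sits at [transition_point()].
#' As in [solve_cycle_high_affinity()], the enzyme pools carry the
#' lowest-order free-effector correction, solved to self-consistency.
#'
#' @param params a [tcs_params()] object with `k_auto = 0` (the reduction is
#'   derived without autodephosphorylation)
#' @param L_T optional effector concentration(s); must satisfy `L_T < H_T`
#' @param threshold maximal `lambda` (default 0.01)
#' @param strict error (rather than warn) on regime violation
#' @return phosphorylated regulator concentration(s), uM
#' @export
solve_tcs_high_affinity <- function(params, L_T = NULL, threshold = 0.01,
                                    strict = FALSE) {
  stopifnot(inherits(params, "tcs_params"))
  check_regime(relative_affinity(params) <= threshold,
               sprintf("high-affinity reduction outside regime: lambda = %.3g > %g",
                       relative_affinity(params), threshold), strict)
  if (params$k_auto != 0)
    stop_validation("high-affinity reduction requires k_auto = 0")
  lt <- if (is.null(L_T)) params$L_T else L_T
  if (any(lt < 0)) stop_validation("L_T must be non-negative")
  if (any(lt >= params$H_T))
    stop_validation("high-affinity reduction requires L_T < H_T")
  app <- apparent_transfer_params(params)
  kmp <- km_phosphatase(params)
  rt <- params$R_T
  k2 <- params$k_ad * km_transfer(params) / params$pt_cat
  # free effector pinned by the flux balance:
  # L = K_d k_ap Km_p R / (ph_cat Rp (R + K2))
  wl <- kd_effector(params) * params$k_ap * kmp / params$ph_cat
  rt * vapply(lt, function(l) {
    phi <- gk_fraction(app$kcat_app * (params$H_T - l), params$ph_cat * l,
                       app$Km_app / rt, kmp / rt)
    for (i in 1:50) {
      r_free <- rt * (1 - phi)
      lfree <- if (phi <= 0) 0.5 * l else
        min(wl * r_free / (rt * phi * (r_free + k2)), 0.5 * l)
      phi_new <- gk_fraction(app$kcat_app * (params$H_T - l + lfree),
                             params$ph_cat * (l - lfree),
                             app$Km_app / rt, kmp / rt)
      if (abs(phi_new - phi) < 1e-12) {
        phi <- phi_new
        break
      }
      phi <- 0.5 * (phi + phi_new)
    }
    phi
  }, numeric(1))
}

#' Effector concentration of the on/off transition
#'
#' The switch between the fully phosphorylated and unphosphorylated regulator
#' states occurs where the apparent maximal kinase and phosphatase rates
#' balance: `L* = total * kcat_kin / (kcat_kin + kcat_pho)` with
#' `kcat_kin = kin_cat` (cycle) or `kcat_app` (two-component system).  Always
#' below the total enzyme concentration, and decreasing in the phosphatase
#' catalytic strength.
#'
#' @param params a [cycle_params()] or [tcs_params()] object
#' @param threshold maximal `lambda` for the high-affinity regime
#' @param strict error (rather than warn) on regime violation
#' @return transition effector concentration `L*` (uM)
#' @export
transition_point <- function(params, threshold = 0.01, strict = FALSE) {
  check_regime(relative_affinity(params) <= threshold,
               sprintf("transition point defined in the high-affinity regime: lambda = %.3g > %g",
                       relative_affinity(params), threshold), strict)
  if (inherits(params, "cycle_params")) {
    kin <- params$kin_cat
    pho <- params$pho_cat
  } else {
    kin <- apparent_transfer_params(params)$kcat_app
    pho <- params$ph_cat
  }
  if (kin + pho == 0) stop_validation("transition point undefined: no catalytic activity")
  total_enzyme(params) * kin / (kin + pho)
}

#' Sharp-switch approximation of the ultrasensitive response
#'
#' Leading-order expansion of the Goldbeter-Koshland root in the zero-order
#' limit: on the 'on' branch (`L_T < L*`)
#' \eqn{Rp \approx R_T(1 - V_2 J/(V_1 - V_2))} and on the 'off' branch
#' \eqn{Rp \approx R_T V_1 K/((1+J)(V_2 - V_1/(1+J)))}, clipped to
#' `[0, R_T]`, where `V_1, V_2` are the apparent maximal rates and `J, K` the
#' normalized apparent Michaelis constants.  Valid when the ultrasensitivity
#' condition holds (both constants small), away from a window around `L*`.
#'
#' @param params a [tcs_params()] object in the high-affinity regime with
#'   small apparent Michaelis constants
#' @param L_T effector concentration(s)
#' @param saturation_max maximal `max(Km_app, Km_p)/R_T` for the
#'   ultrasensitivity condition (default 0.1)
#' @return approximate phosphorylated regulator concentration(s), uM
#' @export
approx_switch_solution <- function(params, L_T = NULL, saturation_max = 0.1) {
  stopifnot(inherits(params, "tcs_params"))
  app <- apparent_transfer_params(params)
  J <- app$Km_app / params$R_T
  K <- km_phosphatase(params) / params$R_T
  if (max(J, K) > saturation_max)
    stop_validation(sprintf(
      "ultrasensitivity condition violated: max(Km_app, Km_p)/R_T = %.3g > %g",
      max(J, K), saturation_max))
  lt <- if (is.null(L_T)) params$L_T else L_T
  if (any(lt < 0) || any(lt >= params$H_T))
    stop_validation("approx_switch_solution requires 0 <= L_T < H_T")
  v1 <- app$kcat_app * (params$H_T - lt)
  v2 <- params$ph_cat * lt
  phi <- ifelse(v1 > v2,
                1 - v2 * J / pmax(v1 - v2, .Machine$double.xmin),
                v1 * K / ((1 + J) * pmax(v2 - v1 / (1 + J), .Machine$double.xmin)))
  params$R_T * pmin(pmax(phi, 0), 1)
}

#' Classify the operating regime of a parameter set
#'
#' Labels the parameter set by the relative binding affinity
#' `lambda = K_d / total enzyme`: `low_affinity_graded` when
#' `lambda >= thresholds$low`, `high_affinity_ultrasensitive` when
#' `lambda <= thresholds$high`, `intermediate` otherwise.  The report carries
#' the saturation diagnostics: the normalized apparent Michaelis constants,
#' the saturation condition (both below `saturation_max`, required for
#' zero-order ultrasensitivity), the regulatory factor condition (factor
#' below `saturation_max`, under which the intrinsic transfer activity may be
#' non-saturated without losing ultrasensitivity), and the transition-point
#' estimate when the regime is high-affinity.
#'
#' @param params a [cycle_params()] or [tcs_params()] object
#' @param thresholds see [regime_thresholds()]
#' @param saturation_max threshold on the normalized Michaelis constants
#' @return an object of class `regime_report`
#' @export
classify_regime <- function(params, thresholds = regime_thresholds(),
                            saturation_max = 0.1) {
  lambda <- relative_affinity(params)
  label <- if (lambda >= thresholds$low) "low_affinity_graded"
  else if (lambda <= thresholds$high) "high_affinity_ultrasensitive"
  else "intermediate"
  if (inherits(params, "cycle_params")) {
    sat <- c(Km_kin = km_kinase(params) / params$S_T,
             Km_pho = km_phosphatase(params) / params$S_T)
    reg_factor <- NA_real_
  } else {
    app <- apparent_transfer_params(params)
    sat <- c(Km_app = app$Km_app / params$R_T,
             Km_p = km_phosphatase(params) / params$R_T)
    reg_factor <- app$regulatory_factor
  }
  high <- label == "high_affinity_ultrasensitive"
  structure(list(
    regime = label,
    lambda = lambda,
    stoich_binding = 1 / lambda,
    saturation = sat,
    saturated = all(sat < saturation_max),
    regulatory_factor = reg_factor,
    regulatory_factor_small = if (is.na(reg_factor)) NA else reg_factor < saturation_max,
    transition_point = if (high)
      transition_point(params, threshold = thresholds$high) else NA_real_),
    class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("Regime: %s (lambda = %.3g, stoichiometric binding = %.3g)\n",
              x$regime, x$lambda, x$stoich_binding))
  cat(sprintf("  saturation ratios: %s -> %s\n",
              paste(sprintf("%s = %.3g", names(x$saturation), x$saturation),
                    collapse = ", "),
              if (x$saturated) "saturated" else "not saturated"))
  if (!is.na(x$regulatory_factor))
    cat(sprintf("  regulatory factor (k_ap+k_ad)/(k_ap+pt_cat) = %.3g\n",
                x$regulatory_factor))
  if (!is.na(x$transition_point))
    cat(sprintf("  transition point L* = %.4g uM\n", x$transition_point))
  invisible(x)
}

regime_report_to_list <- function(x) {
  list(regime = x$regime, lambda = x$lambda,
       stoich_binding = x$stoich_binding,
       saturation = as.list(x$saturation), saturated = x$saturated,
       regulatory_factor = x$regulatory_factor,
       regulatory_factor_small = x$regulatory_factor_small,
       transition_point = x$transition_point)
}
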