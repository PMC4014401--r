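#' Lumped parameters of the Batchelor-Goulian steady-state equation
#'
#' In the limit of excess regulator (`H_T/R_T -> 0`) the steady-state
#' concentration of phosphorylated regulator in the bifunctional two-component
#' system is the physical root of the quadratic
#' \deqn{Rp^2 - Rp (R_T + K_1 + K_2) + K_1 R_T = 0,}
#' equivalently \eqn{Rp = K_1 (R_T - Rp) / (K_2 + R_T - Rp)}: a hyperbola in
#' the free regulator with plateau `K1` and half-saturation `K2`.
#' `K1 = k_ap * K_d * Km_p / (ph_cat * L)` lumps the phosphatase-side
#' constants (and carries the effector dependence, see [effective_k1()]);
#' `K2 = k_ad * Km_t / pt_cat` lumps the phosphotransfer side.
#'
#' @param K1 phosphatase-side lumped constant (uM), > 0 (may be `Inf` for a
#'   vanishing phosphatase path)
#' @param K2 phosphotransfer-side lumped constant (uM), >= 0
#' @param R_T total regulator concentration (uM)
#' @return an object of class `bg_params`
#' @export
bg_params <- function(K1, K2, R_T) {
  structure(list(
    K1 = check_scalar(K1, "K1", strict = TRUE, allow_inf = TRUE),
    K2 = check_scalar(K2, "K2"),
    R_T = check_scalar(R_T, "R_T")),
    class = "bg_params")
}

#' Solve the Batchelor-Goulian quadratic
#'
#' Returns the physical root (the one in `[0, min(R_T, K1)]`) computed with
#' the numerically stable quadratic formula.  Vectorized over `R_T` via the
#' `R_T` argument.  The root is the concentration of *free* phosphorylated
#' regulator; enzyme-bound regulator is neglected, consistently with the
#' `H_T/R_T -> 0` limit in which the quadratic is derived.
#'
#' @param p a [bg_params()] object
#' @param R_T optional vector of total regulator concentrations overriding
#'   `p$R_T`
#' @return steady-state phosphorylated regulator concentration(s), uM
#' @export
solve_bg_quadratic <- function(p, R_T = NULL) {
  stopifnot(inherits(p, "bg_params"))
  rt <- if (is.null(R_T)) p$R_T else R_T
  if (any(rt < 0)) stop_validation("R_T must be non-negative")
  if (!is.finite(p$K1)) return(rt)  # no phosphatase path: all regulator phosphorylated
  s <- rt + p$K1 + p$K2
  disc <- s * s - 4 * p$K1 * rt
  disc[disc < 0] <- 0  # round-off guard; true discriminant is positive
  rp <- 2 * p$K1 * rt / (s + sqrt(disc))
  bad <- rp < -1e-12 | rp > pmin(rt, p$K1) * (1 + 1e-9) + 1e-12
  if (any(bad))
    stop_validation("no physical root of the Batchelor-Goulian quadratic")
  pmin(pmax(rp, 0), rt)
}

#' Limiting-case approximations of the Batchelor-Goulian root
#'
#' Two closed-form limits of the quadratic: for `K1 >> K2` ("plateau" case)
#' the response rises approximately linearly with `R_T` and saturates at `K1`,
#' so `Rp ~ min(R_T, K1)` and `K1` sets both the robustness threshold and the
#' plateau; for `K1 << K2` ("hyperbolic" case) `Rp ~ K1 R_T / (K2 + R_T)`,
#' with a half-saturation threshold `K2` far above the asymptotic level `K1`.
#'
#' @param p a [bg_params()] object
#' @param case `"plateau"` (`K1 >= 10 K2` required) or `"hyperbolic"`
#'   (`K2 >= 10 K1` required)
#' @param R_T optional vector overriding `p$R_T`
#' @return approximate phosphorylated regulator concentration(s), uM
#' @export
approx_bg_limits <- function(p, case = c("plateau", "hyperbolic"), R_T = NULL) {
  stopifnot(inherits(p, "bg_params"))
  case <- match.arg(case)
  rt <- if (is.null(R_T)) p$R_T else R_T
  if (case == "plateau") {
    if (!(p$K1 >= 10 * p$K2))
      stop_validation("plateau case requires K1 >= 10 * K2")
    pmin(rt, p$K1)
  } else {
    if (!(p$K2 >= 10 * p$K1))
      stop_validation("hyperbolic case requires K2 >= 10 * K1")
    p$K1 * rt / (p$K2 + rt)
  }
}
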