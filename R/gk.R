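#' Parameters of the Goldbeter-Koshland steady-state relation
#'
#' Opposing zero-order-capable converter activities acting on a shared
#' substrate pool: a kinase-side activity with maximal rate `Vmax_kin` and
#' Michaelis constant `Km_kin` and a phosphatase-side activity with
#' `Vmax_pho`, `Km_pho`, acting on total substrate `S_T`.
#'
#' @param Vmax_kin,Vmax_pho apparent maximal rates (uM/min), >= 0 (not both 0)
#' @param Km_kin,Km_pho Michaelis constants (uM), > 0
#' @param S_T total substrate (uM), > 0
#' @return an object of class `gk_params`
#' @export
gk_params <- function(Vmax_kin, Vmax_pho, Km_kin, Km_pho, S_T) {
  p <- structure(list(
    Vmax_kin = check_scalar(Vmax_kin, "Vmax_kin"),
    Vmax_pho = check_scalar(Vmax_pho, "Vmax_pho"),
    Km_kin = check_scalar(Km_kin, "Km_kin", strict = TRUE),
    Km_pho = check_scalar(Km_pho, "Km_pho", strict = TRUE),
    S_T = check_scalar(S_T, "S_T", strict = TRUE)),
    class = "gk_params")
  if (p$Vmax_kin == 0 && p$Vmax_pho == 0)
    stop_validation("at least one maximal rate must be positive")
  p
}

# fraction phi solving a(1-phi)/(J+1-phi) = b*phi/(K+phi) on [0,1];
# a, b are the maximal rates, J, K the Michaelis constants normalized by S_T
gk_fraction <- function(a, b, J, K) {
  # (b - a) phi^2 + (a(1-K) - b(1+J)) phi + aK = 0
  A <- b - a
  B <- a * (1 - K) - b * (1 + J)
  C <- a * K
  if (abs(A) < 1e-14 * max(a, b)) {
    phi <- -C / B
  } else {
    phi <- physical_root(quadratic_roots(A, B, C), 0, 1,
                         "Goldbeter-Koshland relation")
  }
  min(max(phi, 0), 1)
}

#' Solve the Goldbeter-Koshland relation
#'
#' Returns the physically admissible root (modified fraction in `[0, 1]`) of
#' the steady-state balance between the two converter activities,
#' \eqn{V_{kin}(1-\phi)/(J + 1 - \phi) = V_{pho}\,\phi/(K + \phi)} with
#' `J = Km_kin/S_T`, `K = Km_pho/S_T`.  When both Michaelis constants are
#' small the response in `Vmax_kin/Vmax_pho` is the zero-order ultrasensitive
#' switch; when both are large it reduces to the first-order ratio
#' \eqn{(V_{kin}/K_{m,kin}) / (V_{kin}/K_{m,kin} + V_{pho}/K_{m,pho})}.
#'
#' @param p a [gk_params()] object
#' @return modified (phosphorylated) fraction of total substrate, in `[0, 1]`
#' @export
solve_gk <- function(p) {
  stopifnot(inherits(p, "gk_params"))
  gk_fraction(p$Vmax_kin, p$Vmax_pho, p$Km_kin / p$S_T, p$Km_pho / p$S_T)
}
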