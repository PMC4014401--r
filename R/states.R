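#' Species vectors of the model variants
#'
#' States are named numeric vectors of concentrations (uM).  Species orders:
#' \describe{
#'   \item{cycle}{`S, Sp, E, EL, ES, ELSp, L` -- unmodified/modified substrate,
#'     free enzyme, effector-bound enzyme, kinase and phosphatase complexes,
#'     free effector}
#'   \item{tcs}{`H, Hp, HL, HpR, HLRp, R, Rp, L` -- free and autophosphorylated
#'     HK, effector-bound HK, phosphotransfer and phosphatase complexes,
#'     free/phosphorylated regulator, free effector}
#'   \item{basal_tcs}{the tcs species plus `HpL` (phosphorylated,
#'     effector-bound HK), `HpLR` (basal transfer complex) and `HRp` (basal
#'     phosphatase complex)}
#' }
#'
#' @param S,Sp,E,EL,ES,ELSp,L,H,Hp,HL,HpR,HLRp,R,Rp,HpL,HpLR,HRp species
#'   concentrations (uM), all non-negative
#' @return a named numeric vector
#' @name model-states
NULL

#' @rdname model-states
#' @export
cycle_state <- function(S = 0, Sp = 0, E = 0, EL = 0, ES = 0, ELSp = 0, L = 0) {
  validate_state(c(S = S, Sp = Sp, E = E, EL = EL, ES = ES, ELSp = ELSp, L = L))
}

#' @rdname model-states
#' @export
tcs_state <- function(H = 0, Hp = 0, HL = 0, HpR = 0, HLRp = 0,
                      R = 0, Rp = 0, L = 0) {
  validate_state(c(H = H, Hp = Hp, HL = HL, HpR = HpR, HLRp = HLRp,
                   R = R, Rp = Rp, L = L))
}

#' @rdname model-states
#' @export
basal_tcs_state <- function(H = 0, Hp = 0, HL = 0, HpL = 0, HpR = 0,
                            HLRp = 0, HpLR = 0, HRp = 0,
                            R = 0, Rp = 0, L = 0) {
  validate_state(c(H = H, Hp = Hp, HL = HL, HpL = HpL, HpR = HpR,
                   HLRp = HLRp, HpLR = HpLR, HRp = HRp,
                   R = R, Rp = Rp, L = L))
}

species_names <- function(variant) {
  switch(variant,
    cycle = c("S", "Sp", "E", "EL", "ES", "ELSp", "L"),
    tcs = c("H", "Hp", "HL", "HpR", "HLRp", "R", "Rp", "L"),
    basal_tcs = c("H", "Hp", "HL", "HpL", "HpR", "HLRp", "HpLR", "HRp",
                  "R", "Rp", "L"),
    stop_validation(sprintf("unknown variant '%s'", variant)))
}

validate_state <- function(state, variant = NULL, negative_tol = 0) {
  if (!is.numeric(state) || is.null(names(state)))
    stop_validation("state must be a named numeric vector")
  if (!is.null(variant)) {
    nm <- species_names(variant)
    if (!identical(sort(names(state)), sort(nm)))
      stop_validation(sprintf("state does not match variant '%s'", variant))
    state <- state[nm]
  }
  if (any(!is.finite(state)))
    stop_validation("state contains non-finite concentrations")
  if (any(state < -negative_tol))
    stop_validation("state contains negative concentrations")
  state
}

variant_of <- function(params) model_tag(params)

#' Conservation totals of a state
#'
#' Sums the species groups that the mass-action dynamics conserve: total
#' substrate (or regulator), total enzyme (converter enzyme or HK) and total
#' effector, each including the complexes that carry the corresponding moiety.
#'
#' @param state a state vector (see [cycle_state()] and friends)
#' @param variant one of `"cycle"`, `"tcs"`, `"basal_tcs"`
#' @return named numeric vector `c(substrate=, enzyme=, effector=)`
#' @export
conservation_totals <- function(state, variant = c("cycle", "tcs", "basal_tcs")) {
  variant <- match.arg(variant)
  s <- validate_state(state, variant)
  with(as.list(s), switch(variant,
    cycle = c(substrate = S + Sp + ES + ELSp,
              enzyme = E + EL + ES + ELSp,
              effector = L + EL + ELSp),
    tcs = c(substrate = R + Rp + HpR + HLRp,
            enzyme = H + Hp + HL + HpR + HLRp,
            effector = L + HL + HLRp),
    basal_tcs = c(substrate = R + Rp + HpR + HLRp + HpLR + HRp,
                  enzyme = H + Hp + HL + HpL + HpR + HLRp + HpLR + HRp,
                  effector = L + HL + HpL + HLRp + HpLR)))
}

#' Default initial condition: all protein unmodified and free
#'
#' All substrate/regulator in the unmodified free pool, all enzyme free and
#' unphosphorylated, all effector free; complexes at zero.
#'
#' @param params a parameter object
#' @return a state vector consistent with the parameter totals
#' @export
default_initial_state <- function(params) {
  switch(variant_of(params),
    cycle = cycle_state(S = params$S_T, E = params$E_T, L = params$L_T),
    tcs = tcs_state(H = params$H_T, R = params$R_T, L = params$L_T),
    basal_tcs = basal_tcs_state(H = params$H_T, R = params$R_T, L = params$L_T))
}

#' Phosphorylated output of a steady state
#'
#' The experimentally measured response: total phosphorylated substrate
#' (`Sp + ELSp`) for the cycle, total phosphorylated regulator
#' (`Rp + HLRp`, plus `HRp` in the basal model) for the two-component system.
#'
#' @param state a state vector
#' @param variant model variant
#' @return concentration (uM)
#' @export
phosphorylated_output <- function(state, variant = c("cycle", "tcs", "basal_tcs")) {
  variant <- match.arg(variant)
  s <- validate_state(state, variant, negative_tol = Inf)
  switch(variant,
    cycle = unname(s["Sp"] + s["ELSp"]),
    tcs = unname(s["Rp"] + s["HLRp"]),
    basal_tcs = unname(s["Rp"] + s["HLRp"] + s["HRp"]))
}
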