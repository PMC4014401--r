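# Mass-action right-hand sides.  The exported functions validate their inputs;
# the .raw variants are the fast paths handed to the ODE integrator.

.cycle_rhs_raw <- function(y, p) {
  v_kb <- p$kin_on * y[["E"]] * y[["S"]] - p$kin_off * y[["ES"]]
  v_kc <- p$kin_cat * y[["ES"]]
  v_e  <- p$eff_on * y[["E"]] * y[["L"]] - p$eff_off * y[["EL"]]
  v_pb <- p$pho_on * y[["EL"]] * y[["Sp"]] - p$pho_off * y[["ELSp"]]
  v_pc <- p$pho_cat * y[["ELSp"]]
  c(S = -v_kb + v_pc,
    Sp = v_kc - v_pb,
    E = -v_kb + v_kc - v_e,
    EL = v_e - v_pb + v_pc,
    ES = v_kb - v_kc,
    ELSp = v_pb - v_pc,
    L = -v_e)
}

.tcs_rhs_raw <- function(y, p) {
  v_ap <- p$k_ap * y[["H"]] - p$k_ad * y[["Hp"]]
  v_tb <- p$pt_on * y[["Hp"]] * y[["R"]] - p$pt_off * y[["HpR"]]
  v_tc <- p$pt_cat * y[["HpR"]]
  v_e  <- p$eff_on * y[["H"]] * y[["L"]] - p$eff_off * y[["HL"]]
  v_pb <- p$ph_on * y[["HL"]] * y[["Rp"]] - p$ph_off * y[["HLRp"]]
  v_pc <- p$ph_cat * y[["HLRp"]]
  v_au <- p$k_auto * y[["Rp"]]
  c(H = -v_ap - v_e + v_tc,
    Hp = v_ap - v_tb,
    HL = v_e - v_pb + v_pc,
    HpR = v_tb - v_tc,
    HLRp = v_pb - v_pc,
    R = -v_tb + v_pc + v_au,
    Rp = v_tc - v_pb - v_au,
    L = -v_e)
}

.basal_tcs_rhs_raw <- function(y, p) {
  v_ap <- p$k_ap * y[["H"]] - p$k_ad * y[["Hp"]]
  v_tb <- p$pt_on * y[["Hp"]] * y[["R"]] - p$pt_off * y[["HpR"]]
  v_tc <- p$pt_cat * y[["HpR"]]
  v_e  <- p$eff_on * y[["H"]] * y[["L"]] - p$eff_off * y[["HL"]]
  v_pb <- p$ph_on * y[["HL"]] * y[["Rp"]] - p$ph_off * y[["HLRp"]]
  v_pc <- p$ph_cat * y[["HLRp"]]
  v_au <- p$k_auto * y[["Rp"]]
  # basal (dashed) reactions
  v_apb <- p$basal_autokinase * p$k_ap * y[["HL"]] -
    p$basal_autokinase_rev * p$k_ad * y[["HpL"]]
  v_ep <- p$bind_effector_phospho * p$eff_on * y[["Hp"]] * y[["L"]] -
    p$eff_off_phospho * y[["HpL"]]
  v_btb <- p$bind_transfer * p$pt_on * y[["HpL"]] * y[["R"]] -
    p$pt_off * y[["HpLR"]]
  v_btc <- p$basal_transfer * p$pt_cat * y[["HpLR"]]
  v_bpb <- p$bind_phosphatase * p$ph_on * y[["H"]] * y[["Rp"]] -
    p$ph_off * y[["HRp"]]
  v_bpc <- p$basal_phosphatase * p$ph_cat * y[["HRp"]]
  c(H = -v_ap - v_e + v_tc - v_bpb + v_bpc,
    Hp = v_ap - v_tb - v_ep,
    HL = v_e - v_pb + v_pc - v_apb + v_btc,
    HpL = v_apb + v_ep - v_btb,
    HpR = v_tb - v_tc,
    HLRp = v_pb - v_pc,
    HpLR = v_btb - v_btc,
    HRp = v_bpb - v_bpc,
    R = -v_tb + v_pc + v_au - v_btb + v_bpc,
    Rp = v_tc - v_pb - v_au + v_btc - v_bpb,
    L = -v_e - v_ep)
}

rhs_raw_fn <- function(variant) {
  switch(variant,
    cycle = .cycle_rhs_raw,
    tcs = .tcs_rhs_raw,
    basal_tcs = .basal_tcs_rhs_raw)
}

#' Mass-action derivatives of the model variants
#'
#' Time derivatives (uM/min) of every species under mass-action kinetics.
#' Within each conserved group (substrate/regulator, enzyme, effector) the
#' derivatives sum to zero up to round-off.
#'
#' `basal_tcs_rhs()` reduces exactly to `tcs_rhs()` on the shared species when
#' all basal factors are zero and the extended species are absent.
#'
#' @param state a state vector matching the variant (see [cycle_state()])
#' @param params the matching parameter object
#' @return named vector of derivatives (uM/min)
#' @name model-rhs
NULL

#' @rdname model-rhs
#' @export
cycle_rhs <- function(state, params) {
  if (!inherits(params, "cycle_params")) stop_validation("params must be cycle_params")
  .cycle_rhs_raw(validate_state(state, "cycle"), params)
}

#' @rdname model-rhs
#' @export
tcs_rhs <- function(state, params) {
  if (!inherits(params, "tcs_params") || inherits(params, "basal_tcs_params"))
    stop_validation("params must be tcs_params")
  .tcs_rhs_raw(validate_state(state, "tcs"), params)
}

#' @rdname model-rhs
#' @export
basal_tcs_rhs <- function(state, params) {
  if (!inherits(params, "basal_tcs_params"))
    stop_validation("params must be basal_tcs_params")
  .basal_tcs_rhs_raw(validate_state(state, "basal_tcs"), params)
}

#' Generic right-hand side dispatching on the parameter class
#' @inheritParams model-rhs
#' @export
model_rhs <- function(state, params) {
  switch(variant_of(params),
    cycle = cycle_rhs(state, params),
    tcs = tcs_rhs(state, params),
    basal_tcs = basal_tcs_rhs(state, params))
}
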