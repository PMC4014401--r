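# Independent right-hand-side oracle: per-reaction mass-action fluxes summed
# through an explicit stoichiometry matrix, built from the elementary reaction
# lists (one irreversible reaction per row).  Kept deliberately separate from
# the package's hand-written derivative expressions.

oracle_reactions <- function(variant, p) {
  r <- function(rate, ...) list(rate = rate, stoich = c(...))
  switch(variant,
    cycle = list(
      r(function(y) p$kin_on * y["E"] * y["S"], E = -1, S = -1, ES = 1),
      r(function(y) p$kin_off * y["ES"], ES = -1, E = 1, S = 1),
      r(function(y) p$kin_cat * y["ES"], ES = -1, E = 1, Sp = 1),
      r(function(y) p$eff_on * y["E"] * y["L"], E = -1, L = -1, EL = 1),
      r(function(y) p$eff_off * y["EL"], EL = -1, E = 1, L = 1),
      r(function(y) p$pho_on * y["EL"] * y["Sp"], EL = -1, Sp = -1, ELSp = 1),
      r(function(y) p$pho_off * y["ELSp"], ELSp = -1, EL = 1, Sp = 1),
      r(function(y) p$pho_cat * y["ELSp"], ELSp = -1, EL = 1, S = 1)),
    tcs = list(
      r(function(y) p$k_ap * y["H"], H = -1, Hp = 1),
      r(function(y) p$k_ad * y["Hp"], Hp = -1, H = 1),
      r(function(y) p$pt_on * y["Hp"] * y["R"], Hp = -1, R = -1, HpR = 1),
      r(function(y) p$pt_off * y["HpR"], HpR = -1, Hp = 1, R = 1),
      r(function(y) p$pt_cat * y["HpR"], HpR = -1, H = 1, Rp = 1),
      r(function(y) p$eff_on * y["H"] * y["L"], H = -1, L = -1, HL = 1),
      r(function(y) p$eff_off * y["HL"], HL = -1, H = 1, L = 1),
      r(function(y) p$ph_on * y["HL"] * y["Rp"], HL = -1, Rp = -1, HLRp = 1),
      r(function(y) p$ph_off * y["HLRp"], HLRp = -1, HL = 1, Rp = 1),
      r(function(y) p$ph_cat * y["HLRp"], HLRp = -1, HL = 1, R = 1),
      r(function(y) p$k_auto * y["Rp"], Rp = -1, R = 1)),
    basal_tcs = c(
      oracle_reactions("tcs", p),
      list(
        r(function(y) p$basal_autokinase * p$k_ap * y["HL"], HL = -1, HpL = 1),
        r(function(y) p$basal_autokinase_rev * p$k_ad * y["HpL"], HpL = -1, HL = 1),
        r(function(y) p$bind_effector_phospho * p$eff_on * y["Hp"] * y["L"],
          Hp = -1, L = -1, HpL = 1),
        r(function(y) p$eff_off_phospho * y["HpL"], HpL = -1, Hp = 1, L = 1),
        r(function(y) p$bind_transfer * p$pt_on * y["HpL"] * y["R"],
          HpL = -1, R = -1, HpLR = 1),
        r(function(y) p$pt_off * y["HpLR"], HpLR = -1, HpL = 1, R = 1),
        r(function(y) p$basal_transfer * p$pt_cat * y["HpLR"],
          HpLR = -1, HL = 1, Rp = 1),
        r(function(y) p$bind_phosphatase * p$ph_on * y["H"] * y["Rp"],
          H = -1, Rp = -1, HRp = 1),
        r(function(y) p$ph_off * y["HRp"], HRp = -1, H = 1, Rp = 1),
        r(function(y) p$basal_phosphatase * p$ph_cat * y["HRp"],
          HRp = -1, H = 1, R = 1))),
    stop("unknown variant"))
}

oracle_rhs <- function(state, params, variant) {
  reactions <- oracle_reactions(variant, params)
  species <- names(state)
  out <- stats::setNames(numeric(length(species)), species)
  for (rx in reactions) {
    v <- unname(rx$rate(state))
    out[names(rx$stoich)] <- out[names(rx$stoich)] + rx$stoich * v
  }
  out
}

oracle_random_state <- function(variant, scale = 1) {
  nm <- switch(variant,
    cycle = c("S", "Sp", "E", "EL", "ES", "ELSp", "L"),
    tcs = c("H", "Hp", "HL", "HpR", "HLRp", "R", "Rp", "L"),
    basal_tcs = c("H", "Hp", "HL", "HpL", "HpR", "HLRp", "HpLR", "HRp",
                  "R", "Rp", "L"))
  stats::setNames(scale * stats::runif(length(nm)), nm)
}

# ---- shared parameter fixtures ----------------------------------------------

test_cycle_params <- function(S_T = 100, E_T = 1, L_T = 0.5,
                              Km_K = 1, Km_P = 1, kin_cat = 10, pho_cat = 10,
                              kin_off = 10, pho_off = 10,
                              K_d = 1e-3, eff_off = 50) {
  cycle_params(kin_on = (kin_off + kin_cat) / Km_K, kin_off = kin_off,
               kin_cat = kin_cat,
               pho_on = (pho_off + pho_cat) / Km_P, pho_off = pho_off,
               pho_cat = pho_cat,
               eff_on = eff_off / K_d, eff_off = eff_off,
               S_T = S_T, E_T = E_T, L_T = L_T)
}

test_tcs_params <- function(R_T = 10, H_T = 0.1, L_T = 0.02,
                            Km_t = 0.1, Km_p = 0.1,
                            k_ap = 50, k_ad = 50, pt_cat = 50, ph_cat = 50,
                            pt_off = 50, ph_off = 50,
                            K_d = 1e-4, eff_off = 50, k_auto = 0) {
  tcs_params(k_ap = k_ap, k_ad = k_ad,
             pt_on = (pt_off + pt_cat) / Km_t, pt_off = pt_off,
             pt_cat = pt_cat,
             ph_on = (ph_off + ph_cat) / Km_p, ph_off = ph_off,
             ph_cat = ph_cat,
             eff_on = eff_off / K_d, eff_off = eff_off,
             k_auto = k_auto, R_T = R_T, H_T = H_T, L_T = L_T)
}

# two-component parameter set realizing given Batchelor-Goulian lumped
# constants in the low-affinity, regulator-excess regime
bg_regime_tcs_params <- function(K1, K2, R_T, L_T = NULL,
                                 hk_ratio = 1e-3, lambda = 1000) {
  H_T <- hk_ratio * R_T
  K_d <- lambda * H_T
  L_T <- L_T %||% K_d  # effective_k1 then equals Km_p
  Km_p <- K1 * L_T / K_d  # k_ap = ph_cat below
  tcs_params(k_ap = 10, k_ad = 10,
             pt_on = 20 / K2, pt_off = 10, pt_cat = 10,  # Km_t = K2
             ph_on = 20 / Km_p, ph_off = 10, ph_cat = 10,
             eff_on = 100 / K_d, eff_off = 100,
             R_T = R_T, H_T = H_T, L_T = L_T)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast ODE sweep of the phosphorylated output over one total
ode_curve <- function(params, variable, grid, control = ss_control()) {
  build_response_curve(params, variable, grid, solver = "ode",
                       control = control)
}
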