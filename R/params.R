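#' Parameters of the covalent modification cycle with a bifunctional enzyme
#'
#' A substrate S is reversibly phosphorylated by a bifunctional converter
#' enzyme E with a single catalytic site.  The free enzyme acts as a kinase
#' (E + S <-> ES -> E + Sp); binding of an allosteric effector L switches the
#' enzyme into its phosphatase form (EL + Sp <-> ELSp -> EL + S), so the
#' effector reciprocally inhibits the kinase and activates the phosphatase
#' activity.  Units are micromolar and minutes throughout.
#'
#' @param kin_on,kin_off,kin_cat kinase-form substrate binding
#'   (1/(uM min)), unbinding (1/min) and turnover (1/min)
#' @param pho_on,pho_off,pho_cat phosphatase-form binding/unbinding/turnover
#'   of the modified substrate
#' @param eff_on,eff_off effector association (1/(uM min)) and dissociation
#'   (1/min) for the free enzyme
#' @param S_T,E_T,L_T total substrate, enzyme and effector concentrations (uM)
#' @return an object of class `cycle_params`
#' @seealso [km_kinase()], [kd_effector()], [relative_affinity()]
#' @export
cycle_params <- function(kin_on, kin_off, kin_cat, pho_on, pho_off, pho_cat,
                         eff_on, eff_off, S_T, E_T, L_T) {
  p <- list(
    kin_on = check_scalar(kin_on, "kin_on", strict = TRUE),
    kin_off = check_scalar(kin_off, "kin_off"),
    kin_cat = check_scalar(kin_cat, "kin_cat"),
    pho_on = check_scalar(pho_on, "pho_on", strict = TRUE),
    pho_off = check_scalar(pho_off, "pho_off"),
    pho_cat = check_scalar(pho_cat, "pho_cat"),
    eff_on = check_scalar(eff_on, "eff_on", strict = TRUE),
    eff_off = check_scalar(eff_off, "eff_off"),
    S_T = check_scalar(S_T, "S_T"),
    E_T = check_scalar(E_T, "E_T"),
    L_T = check_scalar(L_T, "L_T"))
  class(p) <- "cycle_params"
  derived <- c(Km_K = km_kinase(p), Km_P = km_phosphatase(p), K_d = kd_effector(p))
  if (any(!is.finite(derived)) || any(derived <= 0))
    stop_validation("derived constants (Km_K, Km_P, K_d) must be finite and > 0")
  p
}

#' Parameters of the two-component system with reciprocal regulation
#'
#' Extension of the Batchelor-Goulian model of a bifunctional sensor histidine
#' kinase (HK) and its response regulator (RR).  The free HK autophosphorylates
#' (H <-> Hp, forward rate `k_ap`, reverse rate `k_ad`; ATP/ADP are lumped into
#' the rate constants) and transfers the phosphoryl group to the regulator
#' (Hp + R <-> HpR -> H + Rp).  Binding of an allosteric effector
#' (H + L <-> HL) blocks autophosphorylation and activates the HK's phosphatase
#' activity (HL + Rp <-> HLRp -> HL + R), implementing reciprocal regulation.
#' An optional first-order autodephosphorylation of the regulator
#' (Rp -> R, rate `k_auto`) models intrinsic RR phosphatase activity such as
#' that of NRI.
#'
#' @param k_ap autophosphorylation rate of free HK (1/min)
#' @param k_ad reverse autophosphorylation (dephosphorylation of Hp, 1/min);
#'   default 0
#' @param pt_on,pt_off,pt_cat phosphotransfer-complex association
#'   (1/(uM min)), dissociation and turnover (1/min)
#' @param ph_on,ph_off,ph_cat phosphatase-complex association, dissociation
#'   and turnover
#' @param eff_on,eff_off effector binding to the free HK
#' @param k_auto autodephosphorylation rate of the phosphorylated regulator
#'   (1/min); default 0
#' @param R_T,H_T,L_T total regulator, HK and effector concentrations (uM)
#' @return an object of class `tcs_params`
#' @export
tcs_params <- function(k_ap, pt_on, pt_off, pt_cat, ph_on, ph_off, ph_cat,
                       eff_on, eff_off, R_T, H_T, L_T,
                       k_ad = 0, k_auto = 0) {
  p <- list(
    k_ap = check_scalar(k_ap, "k_ap"),
    k_ad = check_scalar(k_ad, "k_ad"),
    pt_on = check_scalar(pt_on, "pt_on", strict = TRUE),
    pt_off = check_scalar(pt_off, "pt_off"),
    pt_cat = check_scalar(pt_cat, "pt_cat"),
    ph_on = check_scalar(ph_on, "ph_on", strict = TRUE),
    ph_off = check_scalar(ph_off, "ph_off"),
    ph_cat = check_scalar(ph_cat, "ph_cat"),
    eff_on = check_scalar(eff_on, "eff_on", strict = TRUE),
    eff_off = check_scalar(eff_off, "eff_off"),
    k_auto = check_scalar(k_auto, "k_auto"),
    R_T = check_scalar(R_T, "R_T"),
    H_T = check_scalar(H_T, "H_T"),
    L_T = check_scalar(L_T, "L_T"))
  class(p) <- "tcs_params"
  derived <- c(Km_t = km_transfer(p), Km_p = km_phosphatase(p), K_d = kd_effector(p))
  if (any(!is.finite(derived)) || any(derived <= 0))
    stop_validation("derived constants (Km_t, Km_p, K_d) must be finite and > 0")
  p
}

#' Two-component system parameters with basal sensor-kinase activities
#'
#' Generalizes [tcs_params()] to the case where the effector-bound HK retains
#' some autokinase/phosphotransfer activity and the free HK retains some
#' phosphatase activity (the "dashed" reactions of the extended scheme).
#' Catalytic scale factors are in \eqn{[0, 1]}; binding scale factors rescale
#' the corresponding association rate constants.
#'
#' The effector-binding/phosphorylation square H/Hp/HL/HpL supports a futile
#' cycle unless the rate products around the square balance.  When
#' `eff_off_phospho` is `NULL` it is derived from the other loop rates so the
#' net steady loop flux vanishes (see [balance_effector_loop()]); otherwise
#' [loop_flux_check()] is run and a warning is emitted when the loop is
#' inconsistent (suppress with `check_loop = FALSE`).
#'
#' @param base a `tcs_params` object with the full (regulated) activities
#' @param basal_autokinase scale on `k_ap` for the effector-bound HK (HL -> HpL)
#' @param basal_autokinase_rev scale on `k_ad` for HpL -> HL; defaults to
#'   `basal_autokinase`
#' @param basal_transfer scale on `pt_cat` for the basal transfer path
#'   (HpL + R <-> HpLR -> HL + Rp)
#' @param basal_phosphatase scale on `ph_cat` for the effector-free phosphatase
#'   path (H + Rp <-> HRp -> H + R)
#' @param bind_transfer,bind_phosphatase scales on the association rates of the
#'   basal transfer and basal phosphatase complexes (default 0: the basal
#'   complexes do not form unless explicitly enabled)
#' @param bind_effector_phospho scale on `eff_on` for effector binding to the
#'   phosphorylated HK (Hp + L -> HpL); reduced affinity corresponds to values
#'   below 1
#' @param eff_off_phospho dissociation rate of the HpL complex (1/min), or
#'   `NULL` to derive it from loop consistency
#' @param check_loop run the loop-consistency check (default `TRUE`)
#' @return an object of class `basal_tcs_params` (which inherits the fields of
#'   `tcs_params`)
#' @export
basal_tcs_params <- function(base,
                             basal_autokinase = 0,
                             basal_autokinase_rev = basal_autokinase,
                             basal_transfer = 0,
                             basal_phosphatase = 0,
                             bind_transfer = 0,
                             bind_phosphatase = 0,
                             bind_effector_phospho = 0,
                             eff_off_phospho = NULL,
                             check_loop = TRUE) {
  if (!inherits(base, "tcs_params"))
    stop_validation("'base' must be a tcs_params object")
  p <- unclass(base)
  p$basal_autokinase <- check_scalar(basal_autokinase, "basal_autokinase")
  p$basal_autokinase_rev <- check_scalar(basal_autokinase_rev, "basal_autokinase_rev")
  p$basal_transfer <- check_scalar(basal_transfer, "basal_transfer")
  p$basal_phosphatase <- check_scalar(basal_phosphatase, "basal_phosphatase")
  p$bind_transfer <- check_scalar(bind_transfer, "bind_transfer")
  p$bind_phosphatase <- check_scalar(bind_phosphatase, "bind_phosphatase")
  p$bind_effector_phospho <- check_scalar(bind_effector_phospho, "bind_effector_phospho")
  class(p) <- c("basal_tcs_params", "tcs_params")
  if (is.null(eff_off_phospho)) {
    p$eff_off_phospho <- balance_effector_loop(p)
  } else {
    p$eff_off_phospho <- check_scalar(eff_off_phospho, "eff_off_phospho")
    if (check_loop) loop_flux_check(p)
  }
  p
}

#' Derive the HpL dissociation rate that nulls the effector-binding loop
#'
#' Around the square H -> Hp -> HpL -> HL -> H (autophosphorylation and
#' effector binding in both phosphoforms) a nonzero difference between the
#' clockwise and counter-clockwise rate products drives a futile cycle at
#' steady state.  This helper returns the Hp-effector dissociation rate that
#' makes the two products equal, `eff_off_phospho =
#' bind_effector_phospho * (basal_autokinase_rev / basal_autokinase) * eff_off`.
#' When the square is broken (an edge rate is zero in both directions) any
#' non-negative value is admissible and 0 is returned for absent binding.
#'
#' @param p a `basal_tcs_params` object (or plain list with the same fields)
#' @return the balancing dissociation rate (1/min)
#' @export
balance_effector_loop <- function(p) {
  gamma <- p$bind_effector_phospho
  sa <- p$basal_autokinase
  sar <- p$basal_autokinase_rev
  if (gamma == 0) return(0)
  if (sa > 0 && p$k_ap > 0 && p$k_ad > 0)
    return(gamma * (sar / sa) * p$eff_off)
  if (sar * p$k_ad * p$k_ap == 0 || p$eff_off == 0) {
    # clockwise product already zero; any rate keeps the loop flux at zero
    return(gamma * p$eff_off)
  }
  stop_validation(paste(
    "effector-binding loop cannot be balanced:",
    "HL -> HpL is blocked while the reverse path is active"))
}

#' Check the effector-binding square for steady-state cycle fluxes
#'
#' Compares the products of rate constants around the H/Hp/HL/HpL square in
#' the two directions.  A relative imbalance above `tol` triggers a warning:
#' such parameter sets sustain a futile binding-phosphorylation cycle at
#' steady state.
#'
#' @param p a `basal_tcs_params` object
#' @param tol relative tolerance on the product imbalance
#' @return (invisibly) the relative imbalance, 0 when the square is inactive
#' @export
loop_flux_check <- function(p, tol = 1e-8) {
  fwd <- p$k_ap * (p$bind_effector_phospho * p$eff_on) *
    (p$basal_autokinase_rev * p$k_ad) * p$eff_off
  rev <- p$eff_on * (p$basal_autokinase * p$k_ap) *
    p$eff_off_phospho * p$k_ad
  if (fwd == 0 && rev == 0) return(invisible(0))
  imbalance <- abs(fwd - rev) / max(fwd, rev)
  if (imbalance > tol)
    warning(sprintf(
      "effector-binding loop is inconsistent (relative imbalance %.3g); expect a futile cycle flux at steady state",
      imbalance), call. = FALSE)
  invisible(imbalance)
}

# ---- derived constants ------------------------------------------------------

#' Derived kinetic constants
#'
#' Michaelis-Menten constants of the kinase/phosphotransfer and phosphatase
#' activities, the effector dissociation constant, the relative binding
#' affinity `lambda = K_d / total enzyme`, and the stoichiometric binding
#' parameter `total enzyme / K_d` (its reciprocal).  All concentrations in uM.
#'
#' @param p a `cycle_params` or `tcs_params` object
#' @return a numeric scalar
#' @name derived-constants
NULL

#' @rdname derived-constants
#' @export
km_kinase <- function(p) {
  stopifnot(inherits(p, "cycle_params"))
  (p$kin_off + p$kin_cat) / p$kin_on
}

#' @rdname derived-constants
#' @export
km_transfer <- function(p) {
  stopifnot(inherits(p, "tcs_params"))
  (p$pt_off + p$pt_cat) / p$pt_on
}

#' @rdname derived-constants
#' @export
km_phosphatase <- function(p) {
  if (inherits(p, "cycle_params")) (p$pho_off + p$pho_cat) / p$pho_on
  else if (inherits(p, "tcs_params")) (p$ph_off + p$ph_cat) / p$ph_on
  else stop_validation("unsupported parameter object")
}

#' @rdname derived-constants
#' @export
kd_effector <- function(p) p$eff_off / p$eff_on

#' @rdname derived-constants
#' @export
total_enzyme <- function(p) {
  if (inherits(p, "cycle_params")) p$E_T
  else if (inherits(p, "tcs_params")) p$H_T
  else stop_validation("unsupported parameter object")
}

#' @rdname derived-constants
#' @export
relative_affinity <- function(p) kd_effector(p) / total_enzyme(p)

#' @rdname derived-constants
#' @export
stoich_binding <- function(p) total_enzyme(p) / kd_effector(p)

# ---- printing ---------------------------------------------------------------

#' @export
print.cycle_params <- function(x, ...) {
  cat("Covalent modification cycle, bifunctional enzyme (uM, min)\n")
  cat(sprintf("  Km_K = %.4g  Km_P = %.4g  K_d = %.4g  lambda = %.4g\n",
              km_kinase(x), km_phosphatase(x), kd_effector(x), relative_affinity(x)))
  cat(sprintf("  totals: S_T = %.4g  E_T = %.4g  L_T = %.4g\n", x$S_T, x$E_T, x$L_T))
  invisible(x)
}

#' @export
print.tcs_params <- function(x, ...) {
  cat("Two-component system, reciprocal regulation (uM, min)\n")
  cat(sprintf("  k_ap = %.4g  k_ad = %.4g  k_auto = %.4g\n", x$k_ap, x$k_ad, x$k_auto))
  cat(sprintf("  Km_t = %.4g  Km_p = %.4g  K_d = %.4g  lambda = %.4g\n",
              km_transfer(x), km_phosphatase(x), kd_effector(x), relative_affinity(x)))
  cat(sprintf("  totals: R_T = %.4g  H_T = %.4g  L_T = %.4g\n", x$R_T, x$H_T, x$L_T))
  if (inherits(x, "basal_tcs_params"))
    cat(sprintf("  basal: autokinase %.3g/%.3g  transfer %.3g  phosphatase %.3g  binding %.3g/%.3g/%.3g\n",
                x$basal_autokinase, x$basal_autokinase_rev, x$basal_transfer,
                x$basal_phosphatase, x$bind_transfer, x$bind_phosphatase,
                x$bind_effector_phospho))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

param_units <- function(p) {
  second_order <- c("kin_on", "pho_on", "pt_on", "ph_on", "eff_on")
  totals <- c("S_T", "E_T", "R_T", "H_T", "L_T", "K1", "K2")
  scales <- c("basal_autokinase", "basal_autokinase_rev", "basal_transfer",
              "basal_phosphatase", "bind_transfer", "bind_phosphatase",
              "bind_effector_phospho")
  vapply(names(unclass(p)), function(nm) {
    if (nm %in% second_order) "1/(uM min)"
    else if (nm %in% totals) "uM"
    else if (nm %in% scales) "dimensionless"
    else "1/min"
  }, character(1))
}

model_tag <- function(p) {
  if (inherits(p, "basal_tcs_params")) "basal_tcs"
  else if (inherits(p, "tcs_params")) "tcs"
  else if (inherits(p, "cycle_params")) "cycle"
  else if (inherits(p, "bg_params")) "bg"
  else stop_validation("unsupported parameter object")
}

params_to_list <- function(p) {
  list(model = model_tag(p),
       parameters = lapply(unclass(p), unname),
       units = as.list(param_units(p)))
}

#' Read and write model parameter files
#'
#' Parameter sets are stored as JSON or YAML (chosen from the file extension)
#' with explicit unit strings.  `read_params()` validates the schema: the
#' `model` tag must be one of `cycle`, `tcs`, `basal_tcs`, all required rates
#' must be present, and unknown parameter names are rejected.
#'
#' @param p a parameter object
#' @param path file path ending in `.json`, `.yaml` or `.yml`
#' @return `read_params()` returns the reconstructed parameter object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  obj <- params_to_list(p)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("parameter file '%s' does not exist", path))
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(obj$model) || is.null(obj$parameters))
    stop_validation("parameter file must contain 'model' and 'parameters'")
  pars <- lapply(obj$parameters, as.numeric)
  build <- switch(obj$model,
    cycle = cycle_params,
    tcs = tcs_params,
    bg = bg_params,
    basal_tcs = NULL,
    stop_validation(sprintf("unknown model tag '%s'", obj$model)))
  if (obj$model == "basal_tcs") {
    base_names <- names(formals(tcs_params))
    basal_names <- setdiff(names(formals(basal_tcs_params)),
                           c("base", "check_loop"))
    basal_names <- c(basal_names, "eff_off_phospho")
    unknown <- setdiff(names(pars), c(base_names, basal_names))
    if (length(unknown))
      stop_validation(sprintf("unknown parameters: %s", paste(unknown, collapse = ", ")))
    base <- do.call(tcs_params, pars[intersect(names(pars), base_names)])
    do.call(basal_tcs_params,
            c(list(base = base), pars[intersect(names(pars), setdiff(basal_names, "base"))]))
  } else {
    known <- names(formals(build))
    unknown <- setdiff(names(pars), known)
    if (length(unknown))
      stop_validation(sprintf("unknown parameters: %s", paste(unknown, collapse = ", ")))
    do.call(build, pars)
  }
}
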