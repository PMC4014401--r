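#' Compartment context for transmembrane signaling
#'
#' For a transmembrane sensor kinase the catalytic reactions take place in the
#' cytosol while effector binding occurs in the periplasm or the extracellular
#' space.  Because effector binding involves no mass transfer, the
#' two-compartment mass balances have the same structure as the
#' single-compartment model; only the effector-binding second-order rate
#' constant picks up the volume ratio `alpha = V_cyt / V_ext` when everything
#' is expressed in cytosolic concentration units.
#'
#' @param volume_ratio `alpha = V_cyt / V_ext` (> 0); `alpha > 1` for a
#'   periplasmic effector, `alpha < 1` typically for an extracellular one
#' @param basis `"concentration"` (uM, default) or `"amount"` (pmol with
#'   second-order rates in 1/(pmol min)); the tag records how rescaled
#'   quantities are to be read
#' @return an object of class `compartment_context`
#' @export
compartment_context <- function(volume_ratio,
                                basis = c("concentration", "amount")) {
  structure(list(
    volume_ratio = check_scalar(volume_ratio, "volume_ratio", strict = TRUE),
    basis = match.arg(basis)),
    class = "compartment_context")
}

#' Rescale two-component parameters between compartment bases
#'
#' Maps a parameter set whose effector quantities refer to the external
#' (periplasmic/extracellular) compartment onto the equivalent
#' single-compartment parameter set expressed on the requested basis.  Only
#' the effector association rate changes: `eff_on` is multiplied by the
#' volume ratio, so the effective dissociation constant becomes
#' `K_d / alpha`.  First-order rates and the cytosolic second-order rates are
#' untouched.  Applying the inverse ratio recovers the original set, and
#' `alpha = 1` is the identity.
#'
#' A periplasmic effector (`alpha > 1`) therefore tightens the effective
#' affinity and favors the ultrasensitive operating regime, while a dilute
#' extracellular effector (`alpha < 1`) suppresses it.
#'
#' @param params a `tcs_params` object with `eff_on`/`eff_off` referring to
#'   the external compartment
#' @param ctx a [compartment_context()]
#' @return a `tcs_params` object on the requested basis
#' @export
two_compartment_rescale <- function(params, ctx) {
  if (!inherits(params, "tcs_params"))
    stop_validation("params must be a tcs_params object")
  if (!inherits(ctx, "compartment_context"))
    stop_validation("ctx must be a compartment_context")
  out <- unclass(params)
  out$eff_on <- out$eff_on * ctx$volume_ratio
  class(out) <- class(params)
  out
}

#' Cytosol-to-periplasm volume ratio from the periplasmic volume fraction
#'
#' For a cell whose periplasm occupies a fraction `f` of the total cell
#' volume, the cytosol-to-periplasm volume ratio is `(1 - f) / f`; periplasmic
#' fractions of 40% and 20% give ratios of 1.5 and 4.
#'
#' @param periplasmic_fraction fraction of total cell volume in (0, 1)
#' @return the volume ratio `alpha`
#' @export
volume_ratio_from_periplasmic_fraction <- function(periplasmic_fraction) {
  f <- periplasmic_fraction
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop_validation("periplasmic_fraction must lie in (0, 1)")
  (1 - f) / f
}
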