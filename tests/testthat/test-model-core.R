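test_that("hand-written derivatives match the stoichiometry-flux oracle", {
  set.seed(42)
  params <- list(
    cycle = test_cycle_params(K_d = 0.5, L_T = 2),
    tcs = test_tcs_params(K_d = 0.05, k_auto = 0.3),
    basal_tcs = basal_tcs_params(test_tcs_params(K_d = 0.05, k_auto = 0.1),
                                 basal_autokinase = 0.4, basal_transfer = 0.6,
                                 basal_phosphatase = 0.2, bind_transfer = 0.8,
                                 bind_phosphatase = 1.5,
                                 bind_effector_phospho = 0.5))
  rhs_fn <- list(cycle = cycle_rhs, tcs = tcs_rhs, basal_tcs = basal_tcs_rhs)
  for (variant in names(params)) {
    p <- params[[variant]]
    worst <- 0
    for (i in 1:1000) {
      y <- oracle_random_state(variant, scale = 10)
      got <- rhs_fn[[variant]](y, p)
      want <- oracle_rhs(y, p, variant)
      worst <- max(worst, max(abs(got - want[names(got)])) /
                     max(1, max(abs(want))))
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("conserved-group derivative sums vanish on random states", {
  set.seed(7)
  groups <- list(
    cycle = list(substrate = c("S", "Sp", "ES", "ELSp"),
                 enzyme = c("E", "EL", "ES", "ELSp"),
                 effector = c("L", "EL", "ELSp")),
    tcs = list(substrate = c("R", "Rp", "HpR", "HLRp"),
               enzyme = c("H", "Hp", "HL", "HpR", "HLRp"),
               effector = c("L", "HL", "HLRp")),
    basal_tcs = list(
      substrate = c("R", "Rp", "HpR", "HLRp", "HpLR", "HRp"),
      enzyme = c("H", "Hp", "HL", "HpL", "HpR", "HLRp", "HpLR", "HRp"),
      effector = c("L", "HL", "HpL", "HLRp", "HpLR")))
  params <- list(
    cycle = test_cycle_params(),
    tcs = test_tcs_params(k_auto = 0.2),
    basal_tcs = basal_tcs_params(test_tcs_params(k_auto = 0.2),
                                 basal_autokinase = 1, basal_transfer = 1,
                                 basal_phosphatase = 1,
                                 bind_effector_phospho = 1))
  rhs_fn <- list(cycle = cycle_rhs, tcs = tcs_rhs, basal_tcs = basal_tcs_rhs)
  for (variant in names(groups)) {
    p <- params[[variant]]
    worst <- 0
    for (i in 1:1000) {
      y <- oracle_random_state(variant, scale = 5)
      d <- rhs_fn[[variant]](y, p)
      scale <- max(1, max(abs(d)))
      for (g in groups[[variant]])
        worst <- max(worst, abs(sum(d[g])) / scale)
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("degenerate states give zero or sign-constrained derivatives", {
  pc <- test_cycle_params(L_T = 0)
  expect_true(all(cycle_rhs(cycle_state(), pc) == 0))
  # absent effector pathway stays absent
  y <- cycle_state(S = 50, Sp = 10, E = 0.5, ES = 0.3, L = 0)
  d <- cycle_rhs(y, pc)
  expect_identical(unname(d[c("EL", "ELSp", "L")]), c(0, 0, 0))

  pt <- test_tcs_params(L_T = 0, k_auto = 0)
  expect_true(all(tcs_rhs(tcs_state(), pt) == 0))
  # with no dephosphorylation path, Rp can only grow while transfer runs
  y <- tcs_state(H = 0.02, Hp = 0.03, HpR = 0.05, R = 5, Rp = 1, L = 0)
  expect_gte(tcs_rhs(y, pt)[["Rp"]], 0)
})

test_that("basal model reduces exactly to the core model at zero factors", {
  base <- test_tcs_params(k_auto = 0.05)
  pb <- basal_tcs_params(base)
  set.seed(11)
  for (i in 1:50) {
    y_tcs <- oracle_random_state("tcs", scale = 3)
    y_basal <- basal_tcs_state(H = y_tcs[["H"]], Hp = y_tcs[["Hp"]],
                               HL = y_tcs[["HL"]], HpR = y_tcs[["HpR"]],
                               HLRp = y_tcs[["HLRp"]], R = y_tcs[["R"]],
                               Rp = y_tcs[["Rp"]], L = y_tcs[["L"]])
    d_basal <- basal_tcs_rhs(y_basal, pb)
    d_tcs <- tcs_rhs(y_tcs, base)
    expect_identical(d_basal[names(d_tcs)], d_tcs)
    expect_identical(unname(d_basal[c("HpL", "HpLR", "HRp")]), c(0, 0, 0))
  }
})

test_that("conservation totals count complexes in every relevant group", {
  p <- test_cycle_params(S_T = 10, E_T = 1, L_T = 3)
  s0 <- default_initial_state(p)
  expect_equal(conservation_totals(s0, "cycle"),
               c(substrate = 10, enzyme = 1, effector = 3))
  # one phosphatase complex carries substrate, enzyme and effector moieties
  s1 <- cycle_state(S = 9, Sp = 0.6, E = 0.4, EL = 0.2, ELSp = 0.4,
                    L = 2.4)
  expect_equal(conservation_totals(s1, "cycle"),
               c(substrate = 10, enzyme = 1, effector = 3))
  s2 <- tcs_state(H = 1, Hp = 0.5, HLRp = 0.5, R = 8, Rp = 1.5, L = 2)
  expect_equal(conservation_totals(s2, "tcs"),
               c(substrate = 10, enzyme = 2, effector = 2.5))
})

test_that("invalid states and parameters are rejected", {
  p <- test_cycle_params()
  bad <- cycle_state(S = 1)
  bad[["S"]] <- -1
  expect_error(cycle_rhs(bad, p), "negative")
  expect_error(cycle_params(kin_on = 0, kin_off = 1, kin_cat = 1,
                            pho_on = 1, pho_off = 1, pho_cat = 1,
                            eff_on = 1, eff_off = 1, S_T = 1, E_T = 1,
                            L_T = 1), "kin_on")
  expect_error(tcs_params(k_ap = 1, pt_on = 1, pt_off = 1, pt_cat = 1,
                          ph_on = 1, ph_off = 1, ph_cat = 1,
                          eff_on = 1, eff_off = 0, R_T = 1, H_T = 1,
                          L_T = 1), "derived")
  expect_error(cycle_rhs(tcs_state(), p), "variant")
})

test_that("two-compartment rescaling is an involution that moves the regime", {
  p <- test_tcs_params(K_d = 0.0025)  # lambda = 0.025 at H_T = 0.1
  expect_equal(two_compartment_rescale(p, compartment_context(1)), p)
  back <- two_compartment_rescale(
    two_compartment_rescale(p, compartment_context(2)),
    compartment_context(1 / 2))
  expect_equal(back$eff_on, p$eff_on, tolerance = 1e-12)
  # periplasmic effector (alpha = 4) reaches the high-affinity condition,
  # dilute extracellular effector (alpha = 0.1) does not
  hi <- two_compartment_rescale(p, compartment_context(4))
  lo <- two_compartment_rescale(p, compartment_context(0.1))
  expect_identical(classify_regime(hi)$regime, "high_affinity_ultrasensitive")
  expect_lt(relative_affinity(hi), 0.01)
  expect_gt(relative_affinity(lo), 0.01)
  expect_error(compartment_context(0), "volume_ratio")
})

test_that("periplasmic volume fractions map to the stated volume ratios", {
  expect_equal(volume_ratio_from_periplasmic_fraction(0.4), 1.5)
  expect_equal(volume_ratio_from_periplasmic_fraction(0.2), 4)
  expect_error(volume_ratio_from_periplasmic_fraction(1.2))
})

test_that("effector-binding loop consistency is enforced or warned about", {
  base <- test_tcs_params()
  # derived dissociation rate nulls the loop
  p <- basal_tcs_params(base, basal_autokinase = 0.5,
                        basal_autokinase_rev = 1,
                        bind_effector_phospho = 0.25)
  expect_equal(p$eff_off_phospho, 0.25 * (1 / 0.5) * base$eff_off)
  expect_silent(loop_flux_check(p))
  # K_d of the phosphorylated form is then larger: reduced affinity
  expect_gt(p$eff_off_phospho / (p$bind_effector_phospho * p$eff_on),
            kd_effector(base))
  expect_warning(
    basal_tcs_params(base, basal_autokinase = 0.5, basal_autokinase_rev = 1,
                     bind_effector_phospho = 0.25,
                     eff_off_phospho = base$eff_off),
    "loop")
  # broken square: no warning, any rate admissible
  expect_silent(p0 <- basal_tcs_params(base, basal_phosphatase = 0.3))
  expect_identical(p0$eff_off_phospho, 0)
})
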