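test_that("apparent transfer parameters interpolate between their limits", {
  # fast autophosphorylation: apparent values reduce to the intrinsic ones
  p_fast <- test_tcs_params(k_ap = 1e7, k_ad = 50, pt_cat = 50, Km_t = 0.1)
  app <- apparent_transfer_params(p_fast)
  expect_equal(app$kcat_app, p_fast$pt_cat, tolerance = 1e-4)
  expect_equal(app$Km_app, km_transfer(p_fast), tolerance = 1e-4)
  # slow autophosphorylation relative to transfer deflates the apparent Km:
  # the intrinsic transfer step may be non-saturated without losing the switch
  p_slow <- test_tcs_params(k_ap = 5, k_ad = 5, pt_cat = 500, Km_t = 20)
  app <- apparent_transfer_params(p_slow)
  expect_equal(app$regulatory_factor, 10 / 505)
  expect_lt(app$Km_app, km_transfer(p_slow) / 10)
  expect_equal(app$kcat_app, 5 * 500 / 505)
  expect_error(apparent_transfer_params(test_tcs_params(k_ap = 0)), "k_ap")
})

test_that("effective K1 follows the inverse-effector law", {
  p <- get_preset("graded_low_affinity")$params
  l <- lseq(0.01, 100, 20)
  k1 <- effective_k1(l, p)
  expect_true(all(diff(k1) < 0))                      # strictly decreasing
  expect_equal(effective_k1(2 * 50, p), effective_k1(50, p) / 2)  # exact 1/L
  expect_identical(effective_k1(0, p), Inf)
  expect_error(effective_k1(-1, p), "non-negative")
  # analytic value: k_ap * K_d * Km_p / (ph_cat * L)
  expect_equal(effective_k1(1, p),
               p$k_ap * kd_effector(p) * km_phosphatase(p) / p$ph_cat)
})

test_that("enzyme partition matches grouped steady-state pools", {
  p <- test_tcs_params(L_T = 0.1 / 3)   # lambda = 1e-3, L_T = H_T/3
  pools <- enzyme_partition(p)
  expect_equal(unname(sum(pools)), p$H_T)
  expect_equal(unname(pools["phosphatase_pool"]), p$L_T)
  st <- integrate_to_steady_state(p)$state
  expect_equal(unname(st[["HL"]] + st[["HLRp"]]),
               unname(pools[["phosphatase_pool"]]), tolerance = 0.05)
  expect_equal(unname(st[["H"]] + st[["Hp"]] + st[["HpR"]]),
               unname(pools[["kinase_pool"]]), tolerance = 0.05)
  expect_equal(unname(enzyme_partition(test_tcs_params(L_T = 0))),
               c(0, 0.1))
  expect_error(enzyme_partition(test_tcs_params(L_T = 0.2)), "L_T")
})

test_that("transition point sits at the apparent rate balance", {
  # symmetric catalytic rates: half the enzyme pool
  pc <- test_cycle_params(kin_cat = 10, pho_cat = 10)
  expect_equal(transition_point(pc), pc$E_T / 2)
  # stronger phosphatase moves the transition down, bounded by the total
  pc10 <- test_cycle_params(kin_cat = 10, pho_cat = 100)
  expect_lt(transition_point(pc10), transition_point(pc))
  expect_lt(transition_point(pc10), pc10$E_T)
  pt <- test_tcs_params()
  app <- apparent_transfer_params(pt)
  expect_equal(transition_point(pt),
               pt$H_T * app$kcat_app / (app$kcat_app + pt$ph_cat))
  # numeric half-max of the full model agrees within 5%
  lstar <- transition_point(pt)
  curve <- ode_curve(pt, "L_T", lseq(lstar / 4, min(2.5 * lstar, 0.09), 21))
  expect_equal(half_max_point(curve), lstar, tolerance = 0.05)
})

test_that("Batchelor-Goulian limiting cases approximate the exact root", {
  p_plat <- bg_params(K1 = 1, K2 = 0.02, R_T = 1)
  expect_identical(approx_bg_limits(p_plat, "plateau", R_T = 0), 0)
  # far above threshold the plateau approximation matches quadratic and K1
  rt <- 10 * p_plat$K1
  expect_equal(approx_bg_limits(p_plat, "plateau", R_T = rt),
               solve_bg_quadratic(p_plat, R_T = rt), tolerance = 0.05)
  expect_equal(approx_bg_limits(p_plat, "plateau", R_T = rt), p_plat$K1,
               tolerance = 0.05)
  # hyperbolic case: half the asymptote at R_T = K2, matching the exact root
  p_hyp <- bg_params(K1 = 0.1, K2 = 10, R_T = 10)
  expect_identical(approx_bg_limits(p_hyp, "hyperbolic", R_T = 0), 0)
  expect_equal(approx_bg_limits(p_hyp, "hyperbolic"), p_hyp$K1 / 2,
               tolerance = 1e-9)
  expect_equal(approx_bg_limits(p_hyp, "hyperbolic"),
               solve_bg_quadratic(p_hyp), tolerance = 0.05)
  expect_error(approx_bg_limits(p_hyp, "plateau"), "K1")
  expect_error(approx_bg_limits(p_plat, "hyperbolic"), "K2")
})

test_that("cycle low-affinity reduction is exactly hyperbolic", {
  p <- test_cycle_params(K_d = 1000, L_T = 0, Km_K = 2, Km_P = 5,
                         kin_cat = 8, pho_cat = 12)
  expect_equal(solve_cycle_low_affinity(p, L_T = 0), 1)
  l <- lseq(1, 1e5, 25)
  frac <- solve_cycle_low_affinity(p, L_T = l)
  curve <- response_curve("L_T", l, frac * p$S_T, p, "low_affinity")
  est <- hill_coefficient(curve)
  expect_equal(est$n_H, 1, tolerance = 0.05)
  expect_identical(est$direction, "decreasing")
  # against the ODE oracle inside the regime
  l_small <- lseq(100, 1e4, 6)
  ode <- ode_curve(p, "L_T", l_small)$values / p$S_T
  expect_equal(solve_cycle_low_affinity(p, L_T = l_small), ode,
               tolerance = 0.02)
  expect_warning(solve_cycle_low_affinity(test_cycle_params(K_d = 1)),
                 "regime")
})

test_that("cycle high-affinity reduction matches the oracle and its limits", {
  p <- test_cycle_params(K_d = 1e-3, Km_K = 1, Km_P = 1)  # Km = 0.01 S_T
  expect_equal(solve_cycle_high_affinity(p, L_T = 0), 1, tolerance = 1e-6)
  l <- seq(0.05, 0.95, length.out = 10) * p$E_T
  frac <- solve_cycle_high_affinity(p, L_T = l)
  ode <- ode_curve(p, "L_T", l)$values / p$S_T
  expect_lt(max(abs(frac - ode)), 0.03)
  # symmetric catalytic rates: half-max at E_T/2 within 5%
  curve <- ode_curve(p, "L_T", seq(0.3, 0.7, length.out = 9) * p$E_T)
  expect_equal(half_max_point(curve), p$E_T / 2, tolerance = 0.05)
  expect_error(solve_cycle_high_affinity(p, L_T = p$E_T), "L_T")
})

test_that("tcs low-affinity reduction equals the effective-K1 quadratic", {
  p <- get_preset("graded_low_affinity")$params
  # large effector: response decays toward zero as 1/L
  rp <- solve_tcs_low_affinity(p, L_T = c(10, 100, 1000))
  expect_true(all(diff(rp) < 0))
  expect_lt(rp[3], 0.02 * p$R_T)
  # grid over (L_T, R_T) against the ODE oracle
  worst <- 0
  for (l in c(0.3, 3, 30)) {
    for (rt in c(3, 10, 30)) {
      p_i <- p; p_i$L_T <- l; p_i$R_T <- rt
      ode <- integrate_to_steady_state(p_i)$state[["Rp"]]
      alg <- solve_tcs_low_affinity(p_i)
      worst <- max(worst, abs(alg - ode) / ode)
    }
  }
  expect_lt(worst, 0.02)
  # graded: effective Hill coefficient stays at or below 1.2 in the regime
  curve <- build_response_curve(p, "L_T", lseq(1e-3, 1e3, 33),
                                solver = "low_affinity")
  expect_lte(hill_coefficient(curve)$n_H, 1.2)
})

test_that("tcs high-affinity reduction matches the oracle in regime", {
  p <- test_tcs_params()        # saturated, lambda = 1e-3
  expect_equal(solve_tcs_high_affinity(p, L_T = 0), p$R_T, tolerance = 1e-4)
  l <- seq(0.05, 0.9, length.out = 10) * p$H_T
  alg <- solve_tcs_high_affinity(p, L_T = l)
  ode <- ode_curve(p, "L_T", l)$values
  expect_lt(max(abs(alg - ode)) / p$R_T, 0.03)
  expect_error(solve_tcs_high_affinity(test_tcs_params(k_auto = 0.1)),
               "k_auto")
  expect_error(solve_tcs_high_affinity(p, L_T = p$H_T), "L_T")
  expect_warning(solve_tcs_high_affinity(test_tcs_params(K_d = 0.05)),
                 "regime")
})

test_that("switch approximation brackets the transition", {
  p <- test_tcs_params()
  lstar <- transition_point(p)
  expect_gt(approx_switch_solution(p, L_T = lstar / 10) / p$R_T, 0.95)
  expect_lt(approx_switch_solution(p, L_T = 2 * lstar) / p$R_T, 0.05)
  l <- lseq(lstar / 10, min(2.5 * lstar, 0.95 * p$H_T), 41)
  rp <- approx_switch_solution(p, L_T = l)
  expect_true(all(diff(rp) <= 1e-12))   # monotone nonincreasing
  # within 5% of the exact reduction outside a +/-10% window of L*
  outside <- abs(l - lstar) > 0.1 * lstar
  exact <- solve_tcs_high_affinity(p, L_T = l)
  expect_lt(max(abs(rp - exact)[outside]) / p$R_T, 0.05)
  p_wide <- test_tcs_params(Km_p = 5)   # Km_p/R_T = 0.5: condition violated
  expect_error(approx_switch_solution(p_wide, L_T = lstar), "condition")
})

test_that("regime classification labels and diagnostics are consistent", {
  r_low <- classify_regime(get_preset("graded_low_affinity")$params)
  expect_identical(r_low$regime, "low_affinity_graded")
  expect_true(is.na(r_low$transition_point))
  r_high <- classify_regime(test_tcs_params())
  expect_identical(r_high$regime, "high_affinity_ultrasensitive")
  expect_true(r_high$saturated)
  expect_equal(r_high$transition_point, transition_point(test_tcs_params()))
  r_mid <- classify_regime(test_tcs_params(K_d = 0.1))  # lambda = 1
  expect_identical(r_mid$regime, "intermediate")
  r_cycle <- classify_regime(test_cycle_params(K_d = 1e-3))
  expect_identical(r_cycle$regime, "high_affinity_ultrasensitive")
  expect_true(is.na(r_cycle$regulatory_factor))
})
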