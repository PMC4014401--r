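hill_curve <- function(n, K = 1, x = lseq(K * 1e-6, K * 1e6, 400),
                       decreasing = FALSE) {
  y <- x^n / (K^n + x^n)
  if (decreasing) y <- 1 - y
  response_curve("L_T", x, y, solver = "analytic")
}

test_that("Hill estimator recovers exact Hill exponents within 2%", {
  for (n in c(0.5, 1, 2, 4, 8)) {
    est <- hill_coefficient(hill_curve(n))
    expect_equal(est$n_H, n, tolerance = 0.02)
    expect_identical(est$direction, "increasing")
    est_dec <- hill_coefficient(hill_curve(n, decreasing = TRUE))
    expect_equal(est_dec$n_H, n, tolerance = 0.02)
    expect_identical(est_dec$direction, "decreasing")
  }
  # x10/x90 of the unit hyperbola sit at K/9 and 9K
  est <- hill_coefficient(hill_curve(1))
  expect_equal(est$x10, 1 / 9, tolerance = 0.02)
  expect_equal(est$x90, 9, tolerance = 0.02)
})

test_that("Hill estimator rejects unusable curves", {
  x <- lseq(0.01, 100, 50)
  bump <- response_curve("L_T", x, dnorm(log(x)), solver = "analytic")
  expect_error(hill_coefficient(bump), "monotone")
  flat <- response_curve("L_T", x, rep(1, 50), solver = "analytic")
  expect_error(hill_coefficient(flat), "dynamic range")
  short <- response_curve("L_T", 1:5, 1:5, solver = "analytic")
  expect_error(hill_coefficient(short), "8 grid points")
})

test_that("response curves are built point-wise from the chosen solver", {
  p <- test_tcs_params()
  one <- build_response_curve(p, "L_T", 0.02, solver = "ode")
  expect_equal(one$values, steady_state_output(p))
  # saturated high-affinity effector sweep: monotone nonincreasing
  sweep <- build_response_curve(p, "L_T",
                                seq(0.1, 0.9, length.out = 9) * p$H_T,
                                solver = "high_affinity")
  expect_true(all(diff(sweep$values) <= 0))
  # total-regulator sweep at fixed effector: nondecreasing with a plateau
  pg <- get_preset("graded_low_affinity")$params
  pg$L_T <- 1
  rcurve <- build_response_curve(as_bg_params(pg), "R_T", lseq(0.1, 300, 12))
  expect_true(all(diff(rcurve$values) >= 0))
  expect_error(response_curve("L_T", c(1, 1, 2), c(1, 2, 3)), "increasing")
})

test_that("robustness report finds plateau, threshold and flat tail", {
  x <- lseq(0.01, 30, 60)
  const <- response_curve("R_T", x, rep(2.5, 60), solver = "analytic")
  rep0 <- robustness_report(const)
  expect_equal(rep0$plateau, 2.5)
  expect_equal(rep0$max_loglog_slope, 0)
  expect_lte(rep0$threshold, min(x))
  # plateau-regime curve: threshold and plateau coincide (within 20%)
  plat <- build_response_curve(get_preset("plateau_robust")$params, "R_T",
                               lseq(0.01, 31.6, 60))
  r1 <- robustness_report(plat)
  expect_equal(r1$threshold / r1$plateau, 1, tolerance = 0.2)
  # hyperbolic-regime curve: threshold far above the plateau
  hyp <- build_response_curve(get_preset("hyperbolic_robust")$params, "R_T",
                              lseq(0.05, 1000, 60))
  r2 <- robustness_report(hyp)
  expect_gt(r2$threshold / r2$plateau, 50)
  # a curve that keeps rising has no plateau
  rising <- response_curve("R_T", x, x, solver = "analytic")
  expect_error(robustness_report(rising), "no plateau")
})

test_that("stimulus-dependent robustness distinguishes the two regimes", {
  # plateau regime (K1 >> K2 at the probed stimuli): threshold tracks plateau
  p <- get_preset("graded_low_affinity")$params   # K1(L) = 1000/L, K2 = 1000
  p_plat <- p
  p_plat$pt_on <- 1000      # Km_t = 0.1 -> K2 = 0.1: deep plateau regime
  grid <- lseq(0.01, 1e4, 50)
  plat <- stimulus_dependent_robustness(p_plat, L_T_set = c(10, 50), grid)
  expect_lt(plat$plateau[2], plat$plateau[1])
  expect_lt(plat$threshold[2], plat$threshold[1])
  expect_equal(plat$threshold / plat$plateau, c(1, 1), tolerance = 0.25)
  # hyperbolic regime (K2 >> K1): plateau rescales, threshold pinned at K2
  hyp <- stimulus_dependent_robustness(p, L_T_set = c(20, 100),
                                       lseq(1, 4e5, 60))
  expect_lt(hyp$plateau[2], hyp$plateau[1])
  expect_equal(hyp$threshold[2] / hyp$threshold[1], 1, tolerance = 0.1)
  # inverse law: 5x the stimulus cuts the plateau about 5-fold
  expect_equal(hyp$plateau[1] / hyp$plateau[2], 5, tolerance = 0.05)
})

test_that("curves round-trip through CSV with their parameter sidecar", {
  p <- test_tcs_params()
  curve <- build_response_curve(p, "L_T",
                                seq(0.1, 0.9, length.out = 9) * p$H_T,
                                solver = "high_affinity")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_response_curve(curve, path)
  back <- read_response_curve(path)
  expect_equal(back$grid, curve$grid)
  expect_equal(back$values, curve$values)
  expect_identical(back$variable, "L_T")
  expect_equal(back$params$eff_on, p$eff_on)
})
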