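#' Titration dataset
#'
#' A measured titration: strictly increasing independent variable (total
#' regulator or effector), non-negative responses, optional standard
#' deviations.
#'
#' @param x independent variable (uM or pmol), strictly increasing
#' @param y measured phosphorylated-regulator levels, `length(y) == length(x)`
#' @param sd optional measurement standard deviations (> 0)
#' @param x_meaning `"total_regulator"` or `"effector"`
#' @param units unit tag (default `"uM"`)
#' @return an object of class `titration_dataset`
#' @export
titration_dataset <- function(x, y, sd = NULL,
                              x_meaning = c("total_regulator", "effector"),
                              units = "uM") {
  x_meaning <- match.arg(x_meaning)
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) >= 2L && any(diff(x) <= 0))
    stop_validation("x must be strictly increasing")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(y < 0))
    stop_validation("y must be finite and non-negative")
  if (!is.null(sd)) {
    if (length(sd) != length(x) || any(!is.finite(sd)) || any(sd <= 0))
      stop_validation("sd must be positive and match x in length")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 sd = if (!is.null(sd)) as.numeric(sd),
                 x_meaning = x_meaning, units = units),
            class = "titration_dataset")
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat(sprintf("Titration dataset: %d points, x = %s (%s), y in [%.4g, %.4g]\n",
              length(x$x), x$x_meaning, x$units, min(x$y), max(x$y)))
  invisible(x)
}

#' Read and write titration datasets (CSV plus JSON sidecar)
#'
#' The CSV holds `x`, `y` and optionally `sd`; the sidecar `<path>.json`
#' stores the x meaning, units and -- for synthetic data -- the ground-truth
#' parameters and generator seed.
#'
#' @param dataset a [titration_dataset()]
#' @param path CSV file path
#' @return `read_titration()` returns a [titration_dataset()];
#'   `write_titration()` returns `path` invisibly.
#' @export
write_titration <- function(dataset, path) {
  d <- data.frame(x = dataset$x, y = dataset$y)
  if (!is.null(dataset$sd)) d$sd <- dataset$sd
  utils::write.csv(d, path, row.names = FALSE)
  gt <- attr(dataset, "ground_truth")
  meta <- list(x_meaning = dataset$x_meaning, units = dataset$units,
               seed = attr(dataset, "seed"),
               ground_truth = if (!is.null(gt)) params_to_list(gt))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  d <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(x_meaning = "total_regulator", units = "uM")
  ds <- titration_dataset(d$x, d$y, sd = d$sd,
                          x_meaning = meta$x_meaning %||% "total_regulator",
                          units = meta$units %||% "uM")
  if (!is.null(meta$ground_truth)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(meta$ground_truth, tmp, auto_unbox = TRUE, digits = NA)
    attr(ds, "ground_truth") <- read_params(tmp)
    attr(ds, "seed") <- meta$seed
  }
  ds
}

fit_result <- function(estimates, fixed, rss, converged, rel_se, trace, model) {
  structure(list(estimates = estimates, fixed = fixed, rss = rss,
                 converged = converged, rel_se = rel_se, trace = trace,
                 model = model),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s): RSS = %.6g, %s\n", x$model, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  est <- data.frame(estimate = signif(x$estimates, 6),
                    rel_se = signif(x$rel_se, 3))
  print(est)
  flat <- names(x$rel_se)[is.finite(x$rel_se) & x$rel_se > 1]
  if (length(flat))
    cat("  note: near-flat directions (relative SE > 100%):",
        paste(flat, collapse = ", "), "\n")
  invisible(x)
}

# multi-start log-space least squares; returns best optim fit plus the log of
# accepted (improving) objective values
logspace_least_squares <- function(objective, init_log, n_starts, seed,
                                   lower = log(1e-10), upper = log(1e10),
                                   method = "L-BFGS-B", maxit = 500) {
  trace <- numeric(0)
  best_seen <- Inf
  wrapped <- function(lp) {
    val <- objective(lp)
    if (!is.finite(val)) val <- 1e300
    if (val < best_seen) {
      best_seen <<- val
      trace <<- c(trace, val)
    }
    val
  }
  starts <- list(init_log)
  if (n_starts > 1L) {
    jitters <- with_seed(seed, lapply(seq_len(n_starts - 1L), function(i)
      stats::rnorm(length(init_log), sd = log(3))))
    starts <- c(starts, lapply(jitters, function(j) init_log + j))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, wrapped, method = method, lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_validation("all optimizer starts failed")
  best$trace <- trace
  best
}

rel_se_from_hessian <- function(objective, par_log, rss, n_obs) {
  p <- length(par_log)
  sigma2 <- rss / max(n_obs - p, 1)
  H <- tryCatch(stats::optimHess(par_log, function(lp) {
    v <- objective(lp)
    if (!is.finite(v)) 1e300 else v
  }), error = function(e) NULL)
  if (is.null(H)) return(rep(NA_real_, p))
  cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(cov)) return(rep(Inf, p))
  se <- suppressWarnings(sqrt(diag(cov)))
  ifelse(is.finite(se), se, Inf)  # SE of log-parameter ~ relative SE
}

#' Fit the Batchelor-Goulian quadratic to a total-regulator titration
#'
#' Least-squares estimation of the lumped constants `(K1, K2)` from a
#' phosphorylated-regulator vs total-regulator titration, with the quadratic
#' root as the prediction.  Optimization runs in log-parameter space with
#' positivity bounds and multi-start (deterministic given `seed`); residuals
#' are inverse-variance weighted when the dataset carries standard
#' deviations.
#'
#' @param dataset a [titration_dataset()] with `x_meaning = "total_regulator"`
#' @param init optional named vector `c(K1=, K2=)` of starting values
#' @param n_starts number of optimizer starts (default 5)
#' @param seed seed for the start jitter
#' @return a `fit_result` with estimates, residual sum of squares, relative
#'   standard errors (from the local quadratic approximation in log space) and
#'   the log of accepted objective values
#' @export
fit_bg <- function(dataset, init = NULL, n_starts = 5, seed = 1) {
  stopifnot(inherits(dataset, "titration_dataset"))
  if (dataset$x_meaning != "total_regulator")
    stop_validation("fit_bg expects a total-regulator titration")
  x <- dataset$x
  y <- dataset$y
  w <- if (!is.null(dataset$sd)) 1 / dataset$sd^2 else rep(1, length(y))
  if (is.null(init)) {
    init <- c(K1 = 1.05 * max(y), K2 = stats::median(x))
  }
  objective <- function(lp) {
    pred <- tryCatch(
      solve_bg_quadratic(bg_params(exp(lp[1L]), exp(lp[2L]), 1), R_T = x),
      error = function(e) NULL)
    if (is.null(pred)) return(1e300)
    sum(w * (pred - y)^2)
  }
  best <- logspace_least_squares(objective, log(unname(init)), n_starts, seed)
  est <- exp(best$par)
  names(est) <- c("K1", "K2")
  rel_se <- rel_se_from_hessian(objective, best$par, best$value, length(y))
  names(rel_se) <- names(est)
  fit_result(est, fixed = numeric(0), rss = best$value,
             converged = best$convergence == 0, rel_se = rel_se,
             trace = best$trace, model = "bg")
}

# set a two-component parameter, mapping Michaelis/dissociation constants onto
# the corresponding association rate (off-rates held fixed)
set_tcs_param <- function(params, name, value) {
  if (name %in% names(unclass(params))) {
    params[[name]] <- value
  } else if (name == "Km_t") {
    params$pt_on <- (params$pt_off + params$pt_cat) / value
  } else if (name == "Km_p") {
    params$ph_on <- (params$ph_off + params$ph_cat) / value
  } else if (name == "K_d") {
    params$eff_on <- params$eff_off / value
  } else {
    stop_validation(sprintf("unknown parameter '%s'", name))
  }
  params
}

get_tcs_param <- function(params, name) {
  if (name %in% names(unclass(params))) params[[name]]
  else switch(name,
              Km_t = km_transfer(params),
              Km_p = km_phosphatase(params),
              K_d = kd_effector(params),
              stop_validation(sprintf("unknown parameter '%s'", name)))
}

#' Fit the full two-component model (with autodephosphorylation) to an
#' effector titration
#'
#' Reproduces the workflow used for the NRII/NRI data: the steady-state
#' response over the effector grid is computed by stiff integration of the
#' full model (including the `Rp -> R` autodephosphorylation term), a chosen
#' subset of parameters is free (typically the Michaelis constants and the
#' catalytic rates of (de-)phosphorylation) and the rest stay fixed at their
#' given values.  Optimization runs in log space with positivity bounds and
#' multi-start.  Near-flat directions are reported through relative standard
#' errors above 100%, not suppressed.
#'
#' @param dataset a [titration_dataset()] with `x_meaning = "effector"`
#' @param params a [tcs_params()] object providing the fixed values and the
#'   starting point for the free ones
#' @param free names of free parameters; any of the `tcs_params` fields or
#'   the derived `Km_t`, `Km_p`, `K_d` (default
#'   `c("Km_t", "Km_p", "pt_cat", "ph_cat")`)
#' @param n_starts number of optimizer starts (default 5)
#' @param seed seed for the start jitter
#' @param control [ss_control()] for the steady-state predictions; the default
#'   trades a little residual tolerance for speed
#' @param maxit optimizer iteration cap per start
#' @return a `fit_result`; `fixed` carries the non-free parameter values
#' @export
fit_tcs_autodephos <- function(dataset, params,
                               free = c("Km_t", "Km_p", "pt_cat", "ph_cat"),
                               n_starts = 5, seed = 1,
                               control = ss_control(rtol = 1e-8, atol = 1e-10,
                                                    rhs_tol = 1e-8,
                                                    change_tol = 1e-7),
                               maxit = 200) {
  stopifnot(inherits(dataset, "titration_dataset"))
  if (dataset$x_meaning != "effector")
    stop_validation("fit_tcs_autodephos expects an effector titration")
  if (length(free) == 0L) stop_validation("at least one free parameter required")
  x <- dataset$x
  y <- dataset$y
  w <- if (!is.null(dataset$sd)) 1 / dataset$sd^2 else rep(1, length(y))
  predict_fn <- function(p) {
    vapply(x, function(l) {
      p$L_T <- l
      steady_state_output(p, control = control)
    }, numeric(1))
  }
  # apply direct rate constants first so that derived constants (Km_t, Km_p,
  # K_d) are realized against the updated rates they are defined through
  apply_order <- order(free %in% c("Km_t", "Km_p", "K_d"))
  objective <- function(lp) {
    p <- params
    for (i in apply_order) p <- set_tcs_param(p, free[i], exp(lp[i]))
    pred <- tryCatch(predict_fn(p), error = function(e) NULL)
    if (is.null(pred)) return(1e300)
    sum(w * (pred - y)^2)
  }
  init_log <- log(vapply(free, get_tcs_param, numeric(1), params = params))
  best <- logspace_least_squares(objective, init_log, n_starts, seed,
                                 method = "Nelder-Mead", lower = -Inf,
                                 upper = Inf, maxit = maxit)
  est <- exp(best$par)
  names(est) <- free
  rel_se <- rel_se_from_hessian(objective, best$par, best$value, length(y))
  names(rel_se) <- free
  all_names <- c(names(unclass(params)))
  fixed <- unlist(unclass(params))[setdiff(all_names, free)]
  fit_result(est, fixed = fixed, rss = best$value,
             converged = best$convergence == 0, rel_se = rel_se,
             trace = best$trace, model = "tcs_autodephos")
}

#' Monte-Carlo parameter-recovery study for the Batchelor-Goulian fit
#'
#' Generates `n_replicates` synthetic total-regulator titrations from a
#' preset (or `bg_params`), fits each with [fit_bg()], and summarizes the
#' per-parameter recovery: bias, relative RMSE and the median absolute
#' relative error.  Deterministic given `seed`; fit failures are counted and
#' reported, not fatal.
#'
#' @param x a `regime_preset` with `bg_params` (e.g.
#'   `get_preset("hyperbolic_robust")`) or a `bg_params` object
#' @param n_replicates number of synthetic datasets (default 20)
#' @param cv noise coefficient of variation (default 0.05)
#' @param n_points design points per dataset (default 12)
#' @param seed base seed; replicate `i` uses `seed * 1000 + i`
#' @param n_starts optimizer starts per fit
#' @return an object of class `recovery_study`: list with `summary` (data
#'   frame), `replicates` (per-replicate relative errors) and `n_failed`
#' @export
parameter_recovery_study <- function(x, n_replicates = 20, cv = 0.05,
                                     n_points = 12, seed = 1, n_starts = 3) {
  if (inherits(x, "regime_preset")) {
    params <- x$params
    grid_full <- x$sweep$grid
  } else {
    params <- x
    grid_full <- lseq(max(params$K2, params$K1) / 50,
                      max(params$K2, params$K1) * 50, 40)
  }
  stopifnot(inherits(params, "bg_params"))
  if (seed >= 2e5) stop_validation("seed must be below 2e5")
  grid <- lseq(min(grid_full), max(grid_full), n_points)
  truth <- c(K1 = params$K1, K2 = params$K2)
  sweep <- list(variable = "R_T", grid = grid)
  reps <- vector("list", n_replicates)
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    nm <- noise_model(cv = cv, seed = as.integer(seed * 1000 + i))
    ds <- generate_titration(params, noise = nm, sweep = sweep, solver = "bg")
    fit <- tryCatch(fit_bg(ds, n_starts = n_starts, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[i]] <- (fit$estimates - truth) / truth
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) == 0L) stop_validation("all replicates failed to fit")
  err <- do.call(rbind, reps)
  summary <- data.frame(
    parameter = colnames(err),
    truth = unname(truth[colnames(err)]),
    bias = colMeans(err),
    median_abs_rel_error = apply(abs(err), 2, stats::median),
    rel_rmse = sqrt(colMeans(err^2)),
    row.names = NULL)
  structure(list(summary = summary, replicates = err, n_failed = n_failed,
                 cv = cv, n_points = n_points, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d replicates (%d failed), cv = %g, n = %d\n",
              nrow(x$replicates) + x$n_failed, x$n_failed, x$cv, x$n_points))
  print(transform(x$summary,
                  bias = signif(bias, 3),
                  median_abs_rel_error = signif(median_abs_rel_error, 3),
                  rel_rmse = signif(rel_rmse, 3)))
  invisible(x)
}
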