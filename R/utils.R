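# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = 0, strict = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation(sprintf("'%s' must be a numeric scalar", name))
  if (!allow_inf && !is.finite(x))
    stop_validation(sprintf("'%s' must be finite", name))
  if (strict && x <= lower)
    stop_validation(sprintf("'%s' must be > %g", name, lower))
  if (!strict && x < lower)
    stop_validation(sprintf("'%s' must be >= %g", name, lower))
  as.numeric(x)
}

#' Log-spaced sequence
#'
#' @param from,to positive endpoints
#' @param length.out number of points
#' @return numeric vector, strictly increasing when `from < to`
#' @export
lseq <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0, length.out >= 1)
  exp(seq(log(from), log(to), length.out = length.out))
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# roots of a*x^2 + b*x + c = 0, computed with the cancellation-free formula
quadratic_roots <- function(a, b, c) {
  if (a == 0) {
    if (b == 0) return(numeric(0))
    return(-c / b)
  }
  disc <- b * b - 4 * a * c
  scale <- max(b * b, abs(4 * a * c), .Machine$double.xmin)
  if (disc < 0) {
    if (disc > -1e-10 * scale) disc <- 0 else return(numeric(0))
  }
  s <- if (b >= 0) 1 else -1
  q <- -0.5 * (b + s * sqrt(disc))
  if (q == 0) return(c(0, -b / a))
  c(q / a, c / q)
}

# pick the unique root inside [lo, hi] (with slack for round-off)
physical_root <- function(roots, lo, hi, context, tol = 1e-9) {
  slack <- tol * max(1, abs(hi))
  inside <- roots[roots >= lo - slack & roots <= hi + slack]
  inside <- unique(pmin(pmax(inside, lo), hi))
  if (length(inside) == 0L)
    stop_validation(sprintf("no admissible root in [%g, %g] for %s", lo, hi, context))
  if (length(inside) > 1L && diff(range(inside)) > 1e-7 * max(1, abs(hi)))
    stop_validation(sprintf("multiple admissible roots for %s", context))
  inside[1L]
}
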