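## Population parameters from a life schedule.
##
## With discrete pivotal ages x and schedules lx, mx:
##   net reproductive rate   R0     = sum(lx * mx)
##   intrinsic rate          r      solves sum(exp(-r x) lx mx) = 1
##   finite rate             lambda = exp(r)
##   mean generation time    T      = ln(R0) / r
## The Euler-Lotka left side is strictly decreasing in r whenever any
## reproduction occurs at a positive age, so the root is unique; it is
## bracketed, solved with Brent's method, and polished with Newton steps
## to drive the residual below 1e-10.

#' Net reproductive rate
#'
#' @param schedule A [life_schedule()].
#' @return `R0 = sum(lx * mx)`, female offspring per female per
#'   generation.
#' @export
net_reproductive_rate <- function(schedule) {
  stopifnot(inherits(schedule, "life_schedule"))
  sum(schedule$lx * schedule$mx)
}

euler_lotka <- function(r, x, lxmx) sum(exp(-r * x) * lxmx) - 1

#' Intrinsic rate of increase (Euler-Lotka root)
#'
#' Solves `sum(exp(-r x) lx mx) = 1` for the per-day exponential growth
#' rate `r`. The bracket starts at `[-1, 2]` per day (generous for any
#' arthropod schedule in daily units) and is expanded geometrically if
#' the root lies outside.
#'
#' @param schedule A [life_schedule()].
#' @param bracket Initial search interval for `r` (per day).
#' @param tol Residual tolerance (default 1e-12; must be below 1e-10).
#' @param diagnostics Return a list with solver diagnostics instead of a
#'   bare number.
#' @return The root `r`, or (with `diagnostics = TRUE`) a list with
#'   `r`, `residual`, `iterations`, `bracket`.
#' @export
intrinsic_rate <- function(schedule, bracket = c(-1, 2), tol = 1e-12,
                           diagnostics = FALSE) {
  stopifnot(inherits(schedule, "life_schedule"))
  x <- schedule$x
  lxmx <- schedule$lx * schedule$mx
  R0 <- sum(lxmx)
  if (!isTRUE(R0 > 0)) {
    condition_stop("R0 = 0: the Euler-Lotka equation has no solution",
                   "lifetab_solver_error")
  }
  if (all(x[lxmx > 0] <= 0)) {
    condition_stop("all reproduction at age <= 0: r is not identified",
                   "lifetab_solver_error")
  }
  lo <- min(bracket); hi <- max(bracket)
  expansions <- 0L
  while (euler_lotka(lo, x, lxmx) <= 0) {   # f decreasing: need f(lo) > 0
    hi <- lo
    lo <- lo - 2^expansions
    expansions <- expansions + 1L
    if (expansions > 60L) {
      condition_stop("bracket expansion failed (lower end)",
                     "lifetab_solver_error")
    }
  }
  expansions <- 0L
  while (euler_lotka(hi, x, lxmx) >= 0) {
    hi <- hi + 2^expansions
    expansions <- expansions + 1L
    if (expansions > 60L) {
      condition_stop("bracket expansion failed (upper end)",
                     "lifetab_solver_error")
    }
  }
  sol <- uniroot(euler_lotka, c(lo, hi), x = x, lxmx = lxmx,
                 tol = .Machine$double.eps^0.75)
  r <- sol$root
  iter <- sol$iter
  # Newton polish: f'(r) = -sum(x exp(-r x) lx mx)
  for (k in 1:10) {
    f <- euler_lotka(r, x, lxmx)
    if (abs(f) < tol) break
    fp <- -sum(x * exp(-r * x) * lxmx)
    r <- r - f / fp
    iter <- iter + 1L
  }
  resid <- euler_lotka(r, x, lxmx)
  if (abs(resid) > 1e-10) {
    condition_stop(sprintf("solver residual %.3g exceeds 1e-10", resid),
                   "lifetab_solver_error")
  }
  if (diagnostics) {
    list(r = r, residual = resid, iterations = iter, bracket = c(lo, hi))
  } else {
    r
  }
}

#' Finite rate of increase
#'
#' @param r Intrinsic rate of increase (per day).
#' @return `lambda = exp(r)`, the per-day multiplication factor.
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time
#'
#' `T = ln(R0) / r` days. At `r = 0` this is a 0/0 limit; the cohort
#' generation time `sum(x lx mx) / R0` is returned instead (requires the
#' schedule) and carries attribute `limit = TRUE`.
#'
#' @param R0 Net reproductive rate.
#' @param r Intrinsic rate of increase.
#' @param schedule Optional [life_schedule()], needed only when `r = 0`.
#' @return Generation time in days.
#' @export
generation_time <- function(R0, r, schedule = NULL) {
  if (!isTRUE(R0 > 0)) {
    condition_stop("generation time requires R0 > 0", "lifetab_solver_error")
  }
  if (abs(r) < 1e-12) {
    if (is.null(schedule)) {
      condition_stop("r = 0: supply the schedule for the limit T = sum(x lx mx)/R0",
                     "lifetab_solver_error")
    }
    Tc <- sum(schedule$x * schedule$lx * schedule$mx) / R0
    return(structure(Tc, limit = TRUE))
  }
  log(R0) / r
}

#' All four demographic parameters of a schedule
#'
#' @param schedule A [life_schedule()].
#' @return An object of class `demographic_params`: list with `r`,
#'   `lambda`, `R0`, `T`, and solver diagnostics (`residual`,
#'   `iterations`, `bracket`).
#' @export
demographic_params <- function(schedule) {
  R0 <- net_reproductive_rate(schedule)
  sol <- intrinsic_rate(schedule, diagnostics = TRUE)
  structure(
    list(r = sol$r, lambda = finite_rate(sol$r), R0 = R0,
         T = generation_time(R0, sol$r, schedule),
         residual = sol$residual, iterations = sol$iterations,
         bracket = sol$bracket,
         group = schedule$meta$group),
    class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, digits = 4, ...) {
  cat("<demographic_params>")
  if (!is.null(x$group)) cat(" ", format(x$group))
  cat("\n")
  cat(sprintf("  r = %.*f /d   lambda = %.*f /d   R0 = %.*f   T = %.*f d\n",
              digits, x$r, digits, x$lambda, digits, x$R0, digits, x$T))
  cat(sprintf("  residual %.2e in %d iterations\n", x$residual, x$iterations))
  invisible(x)
}
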