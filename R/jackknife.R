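## Leave-one-female-out jackknife for life-table parameters.
##
## The resampling unit is one single-pair family: a female together with
## her offspring tally. For each deletion the pooled immature survival,
## sex ratio, adult survival, and per-capita fecundity are recomputed and
## the Euler-Lotka system re-solved. Pseudo-values
##   v_i = n * theta_hat - (n - 1) * theta_hat_(-i)
## give the jackknife mean and its standard error sd(v)/sqrt(n).

new_jackknife_estimate <- function(parameter, theta_all, theta_loo, n,
                                   flagged = rep(FALSE, length(theta_loo))) {
  valid <- !flagged & !is.na(theta_loo)
  pseudo <- n * theta_all - (n - 1) * theta_loo
  nv <- sum(valid)
  if (nv < 3L) {
    condition_stop(
      sprintf("parameter %s: fewer than 3 valid jackknife deletions", parameter),
      "lifetab_analysis_error")
  }
  structure(
    list(parameter = parameter, theta_all = theta_all, theta_loo = theta_loo,
         pseudo = pseudo, jk_mean = mean(pseudo[valid]),
         jk_se = sd(pseudo[valid]) / sqrt(nv), n = n, n_valid = nv,
         flagged = flagged),
    class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<jackknife_estimate> %s: %.*f (all-data %.*f) +/- %.*f SE, n = %d (%d valid)\n",
              x$parameter, digits, x$jk_mean, digits, x$theta_all,
              digits, x$jk_se, x$n, x$n_valid))
  invisible(x)
}

#' Jackknife a statistic of per-unit values
#'
#' Generic delete-one jackknife for a statistic of a numeric vector
#' (e.g. a mean, a ratio of sums). For statistics linear in the
#' per-unit contributions the jackknife SE equals the classic
#' `sd(x)/sqrt(n)` exactly.
#'
#' @param x Numeric vector, one entry per resampling unit.
#' @param statistic Function of a numeric vector returning one number.
#' @param parameter Label for the estimate.
#' @return A `jackknife_estimate`.
#' @export
jackknife_stat <- function(x, statistic = mean, parameter = "statistic") {
  n <- length(x)
  if (n < 3L) {
    condition_stop("jackknife needs at least 3 units", "lifetab_analysis_error")
  }
  theta_all <- statistic(x)
  theta_loo <- vapply(seq_len(n), function(i) statistic(x[-i]), 0)
  new_jackknife_estimate(parameter, theta_all, theta_loo, n)
}

#' Jackknife the four life-table parameters of a treatment cell
#'
#' Deletes one family at a time (the female and her offspring tally),
#' rebuilds the schedule, and re-solves for `r`, `lambda`, `R0`, `T`.
#' `lambda` and `T` are jackknifed directly on the transformed scale (not
#' derived from `r`'s pseudo-values). The development offset is held
#' fixed across deletions because the development subsample is not linked
#' to individual mothers; set `resample_dev = TRUE` to bootstrap it per
#' deletion instead (uses the current RNG stream).
#'
#' @inheritParams build_life_schedule
#' @param resample_dev Bootstrap the development offset per deletion.
#' @return An object of class `jackknife_lifetable`: named list of
#'   `jackknife_estimate`s for `r`, `lambda`, `R0`, `T`, plus the
#'   all-data `demographic_params`.
#' @export
jackknife_lifetable <- function(data, group, step = 1,
                                age_convention = c("spread", "midpoint"),
                                negg_convention = c("initial_females",
                                                    "living_females"),
                                dev_offset = NULL,
                                dev_sex = c("combined", "female", "male"),
                                resample_dev = FALSE) {
  age_convention <- match.arg(age_convention)
  negg_convention <- match.arg(negg_convention)
  dev_sex <- match.arg(dev_sex)
  cell <- cohort_subset(data, group)
  fem <- cell$females
  n <- nrow(fem)
  if (n < 3L) {
    condition_stop(sprintf("cell %s: jackknife needs >= 3 females", format(group)),
                   "lifetab_analysis_error")
  }

  dev_emerged <- cell$dev$dev_days[cell$dev$outcome == "emerged"]
  if (dev_sex != "combined") {
    dev_emerged <- cell$dev$dev_days[cell$dev$outcome == "emerged" &
                                       cell$dev$sex == dev_sex]
  }
  if (is.null(dev_offset)) {
    if (!length(dev_emerged)) {
      condition_stop(
        sprintf("cell %s has no emerged development records; supply dev_offset",
                format(group)),
        "lifetab_analysis_error")
    }
    dev_offset <- mean(dev_emerged)
  }

  # per-female tally contributions aligned to the female table
  m <- match(fem$female_id, cell$offspring$female_id)
  eggs_i <- ifelse(is.na(m), 0, cell$offspring$n_eggs[m])
  adults_i <- ifelse(is.na(m), 0, cell$offspring$n_adults[m])
  fem_ad_i <- ifelse(is.na(m), 0, cell$offspring$n_female_adults[m])
  E <- sum(eggs_i); A <- sum(adults_i); FA <- sum(fem_ad_i)
  if (!isTRUE(E > 0) || !isTRUE(A > 0)) {
    condition_stop(sprintf("cell %s has no emerged offspring", format(group)),
                   "lifetab_analysis_error")
  }

  comp <- schedule_components(fem, step, age_convention)
  all_sched <- assemble_schedule(comp, seq_len(n), SURV = A / E, SR = FA / A,
                                 dev_offset = dev_offset, group = group,
                                 negg_convention = negg_convention)
  all_par <- demographic_params(all_sched)

  loo <- matrix(NA_real_, n, 4,
                dimnames = list(fem$female_id, c("r", "lambda", "R0", "T")))
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    Ei <- E - eggs_i[i]; Ai <- A - adults_i[i]; FAi <- FA - fem_ad_i[i]
    if (Ei <= 0 || Ai <= 0) {
      flagged[i] <- TRUE
      next
    }
    off_d <- if (resample_dev) {
      mean(sample(dev_emerged, length(dev_emerged), replace = TRUE))
    } else {
      dev_offset
    }
    sched <- assemble_schedule(comp, setdiff(seq_len(n), i),
                               SURV = Ai / Ei, SR = FAi / Ai,
                               dev_offset = off_d, group = group,
                               negg_convention = negg_convention)
    R0i <- net_reproductive_rate(sched)
    loo[i, "R0"] <- R0i
    if (R0i <= 0) {
      flagged[i] <- TRUE
      next
    }
    ri <- intrinsic_rate(sched)
    loo[i, "r"] <- ri
    loo[i, "lambda"] <- finite_rate(ri)
    loo[i, "T"] <- generation_time(R0i, ri, sched)
  }

  theta_all <- c(r = all_par$r, lambda = all_par$lambda, R0 = all_par$R0,
                 T = all_par$T)
  est <- lapply(colnames(loo), function(p) {
    fl <- flagged | is.na(loo[, p])
    new_jackknife_estimate(p, theta_all[[p]], loo[, p], n, fl)
  })
  names(est) <- colnames(loo)
  structure(c(est, list(all_data = all_par, group = group)),
            class = "jackknife_lifetable")
}

#' @export
print.jackknife_lifetable <- function(x, digits = 4, ...) {
  cat("<jackknife_lifetable>", format(x$group), "\n")
  for (p in c("r", "lambda", "R0", "T")) {
    cat(sprintf("  %-6s %.*f +/- %.*f\n", p, digits, x[[p]]$jk_mean,
                digits, x[[p]]$jk_se))
  }
  invisible(x)
}

#' Tukey studentized-range comparison of jackknife estimates
#'
#' One-way comparison of one parameter across treatment cells, run on the
#' jackknife pseudo-values with pooled within-cell variance; unequal cell
#' sizes use the Tukey-Kramer adjustment. Cells sharing a letter are not
#' significantly different at `alpha`; letters are assigned by descending
#' mean.
#'
#' @param estimates Named list, one element per cell: either a
#'   `jackknife_estimate` or a `jackknife_lifetable` (then `parameter`
#'   selects the component).
#' @param parameter One of `"r"`, `"lambda"`, `"R0"`, `"T"` when
#'   `estimates` holds `jackknife_lifetable`s.
#' @param alpha Familywise significance level (default 0.05).
#' @return A data.frame (cell, n, mean, se, letters) ordered by
#'   descending mean, with the pairwise comparison table in attribute
#'   `"pairs"`.
#' @export
compare_groups <- function(estimates, parameter = NULL, alpha = 0.05) {
  if (length(estimates) < 2L) {
    condition_stop("compare_groups needs >= 2 cells", "lifetab_analysis_error")
  }
  if (is.null(names(estimates)) || any(!nzchar(names(estimates)))) {
    condition_stop("estimates must be a named list", "lifetab_analysis_error")
  }
  pseudo <- lapply(estimates, function(e) {
    if (inherits(e, "jackknife_lifetable")) {
      if (is.null(parameter)) {
        condition_stop("supply parameter when passing jackknife_lifetable objects",
                       "lifetab_analysis_error")
      }
      e <- e[[parameter]]
    }
    stopifnot(inherits(e, "jackknife_estimate"))
    e$pseudo[!e$flagged & !is.na(e$pseudo)]
  })
  res <- tukey_hsd(pseudo, alpha = alpha)
  out <- res$groups
  names(out)[names(out) == "group"] <- "cell"
  attr(out, "pairs") <- res$pairs
  attr(out, "alpha") <- alpha
  out
}
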