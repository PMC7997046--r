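## Age-indexed survival (lx) and fecundity (mx) schedules at pivotal ages.
##
## The pivotal age x of an adult age step is the egg-to-adult development
## offset plus the adult age plus 0.5 (mid-step). Immature survival SURV is
## a single egg-to-adult fraction applied to the whole adult span:
##   lx = SURV * NSF_x / NF          mx = NEGG_x * SR
## where NSF_x counts females surviving past age x, NF is the initial
## number of females, NEGG_x the per-capita eggs laid at the step, and SR
## the pooled female fraction among emerged offspring.

#' Construct an age-specific survival/fecundity schedule
#'
#' @param x Strictly increasing pivotal ages (days from egg).
#' @param lx Survival probabilities in `[0, 1]`, non-increasing.
#' @param mx Female eggs per female per age step, non-negative.
#' @param step_days Spacing of `x`.
#' @param meta Optional list of provenance fields (group, `NF`, `SURV`,
#'   `SR`, `dev_offset_days`, conventions).
#' @return An object of class `life_schedule`.
#' @export
life_schedule <- function(x, lx, mx, step_days = NULL, meta = list()) {
  x <- as.numeric(x); lx <- as.numeric(lx); mx <- as.numeric(mx)
  if (length(x) != length(lx) || length(x) != length(mx)) {
    condition_stop("x, lx, mx must have equal length", "lifetab_validation_error")
  }
  if (length(x) == 0L) {
    condition_stop("empty schedule", "lifetab_validation_error")
  }
  if (any(diff(x) <= 0)) {
    condition_stop("pivotal ages must be strictly increasing",
                   "lifetab_validation_error")
  }
  if (any(lx < -1e-12) || any(lx > 1 + 1e-12) || any(diff(lx) > 1e-12)) {
    condition_stop("lx must be non-increasing probabilities",
                   "lifetab_validation_error")
  }
  if (any(mx < 0)) {
    condition_stop("mx must be non-negative", "lifetab_validation_error")
  }
  if (is.null(step_days)) {
    step_days <- if (length(x) > 1L) x[2] - x[1] else NA_real_
  }
  structure(list(x = x, lx = pmin(pmax(lx, 0), 1), mx = mx,
                 step_days = step_days, meta = meta),
            class = "life_schedule")
}

#' @export
print.life_schedule <- function(x, ...) {
  cat(sprintf("<life_schedule> %d pivotal ages, x in [%.2f, %.2f] d, step %.3g d\n",
              length(x$x), x$x[1], x$x[length(x$x)], x$step_days))
  if (!is.null(x$meta$group)) cat("  group:", format(x$meta$group), "\n")
  if (!is.null(x$meta$SURV)) {
    cat(sprintf("  NF = %d, SURV = %.4f, SR = %.4f, dev offset = %.2f d\n",
                x$meta$NF, x$meta$SURV, x$meta$SR, x$meta$dev_offset_days))
  }
  invisible(x)
}

#' @export
as.data.frame.life_schedule <- function(x, ...) {
  data.frame(x = x$x, lx = x$lx, mx = x$mx)
}

## ---- component operations -------------------------------------------------

#' Adult survival fractions NSF_x / NF per age step
#'
#' The fraction of the cell's initial females (`NF`) alive past each age
#' step: step `a` (0-based, width `step`) counts females with longevity
#' strictly greater than `a * step` days.
#'
#' @param data A `cohort_dataset`.
#' @param group A `group_key`.
#' @param step Step width in days (default 1).
#' @return Numeric vector starting at 1, non-increasing, one entry per
#'   step up to the longest-lived female.
#' @export
adult_survival <- function(data, group, step = 1) {
  fem <- cohort_subset(data, group)$females
  n_steps <- ceiling(max(fem$longevity_days) / step)
  ages <- (seq_len(n_steps) - 1L) * step
  vapply(ages, function(a) sum(fem$longevity_days > a), 0) / nrow(fem)
}

#' Pooled immature (egg-to-adult) survival SURV
#'
#' @param data A `cohort_dataset`.
#' @param group A `group_key`.
#' @return Total emerged adults over total eggs across the cell's broods.
#' @export
immature_survival <- function(data, group) {
  off <- cohort_subset(data, group)$offspring
  eggs <- sum(off$n_eggs)
  if (!isTRUE(eggs > 0)) {
    condition_stop(sprintf("cell %s has no offspring eggs", format(group)),
                   "lifetab_analysis_error")
  }
  sum(off$n_adults) / eggs
}

#' Pooled offspring sex ratio SR (female fraction among emerged adults)
#'
#' @param data A `cohort_dataset`.
#' @param group A `group_key`.
#' @return Total female adults over total emerged adults.
#' @export
offspring_sex_ratio <- function(data, group) {
  off <- cohort_subset(data, group)$offspring
  adults <- sum(off$n_adults)
  if (!isTRUE(adults > 0)) {
    condition_stop(sprintf("cell %s has no emerged offspring", format(group)),
                   "lifetab_analysis_error")
  }
  sum(off$n_female_adults) / adults
}

## Allocate each female's census egg counts to age steps.
## age_convention "spread": daily steps; an interval's count is divided
##   evenly over its days, the final interval truncated at the death day so
##   no eggs are assigned past death. "midpoint": steps at the census
##   interval resolution (requires a common interval across females).
## Returns list(egg_mat [n x S], longevity, step, n_steps).
schedule_components <- function(fem, step = 1,
                                age_convention = c("spread", "midpoint")) {
  age_convention <- match.arg(age_convention)
  n <- nrow(fem)
  if (age_convention == "midpoint") {
    ci <- unique(fem$census_interval_days)
    if (length(ci) != 1L) {
      condition_stop("midpoint convention needs a common census interval",
                     "lifetab_analysis_error")
    }
    S <- max(vapply(fem$census_eggs, length, 0L))
    egg_mat <- matrix(0, n, S)
    for (i in seq_len(n)) {
      e <- fem$census_eggs[[i]]
      egg_mat[i, seq_along(e)] <- e
    }
    return(list(egg_mat = egg_mat, longevity = fem$longevity_days,
                step = ci, n_steps = S, age_convention = age_convention))
  }
  if (!isTRUE(all.equal(step, 1))) {
    condition_stop("the spread convention uses daily steps (step = 1)",
                   "lifetab_analysis_error")
  }
  last_day <- ceiling(fem$longevity_days)
  S <- max(last_day)
  egg_mat <- matrix(0, n, S)
  for (i in seq_len(n)) {
    e <- fem$census_eggs[[i]]
    ci <- fem$census_interval_days[i]
    for (k in seq_along(e)) {
      if (e[k] == 0) next
      d0 <- floor((k - 1) * ci) + 1L
      d1 <- min(ceiling(k * ci), last_day[i])
      days <- if (d0 > d1) last_day[i] else d0:d1
      egg_mat[i, days] <- egg_mat[i, days] + e[k] / length(days)
    }
  }
  list(egg_mat = egg_mat, longevity = fem$longevity_days, step = 1,
       n_steps = S, age_convention = age_convention)
}

## Assemble lx/mx from precomputed components for a subset of females.
## Used by build_life_schedule (all females) and by the jackknife (leave-
## one-out subsets) so the two paths share one definition.
assemble_schedule <- function(comp, idx, SURV, SR, dev_offset, group = NULL,
                              negg_convention = "initial_females") {
  longevity <- comp$longevity[idx]
  NF <- length(idx)
  step <- comp$step
  S <- ceiling(max(longevity) / step)
  eggs_step <- colSums(comp$egg_mat[idx, seq_len(S), drop = FALSE])
  ages <- (seq_len(S) - 1L) * step
  alive <- vapply(ages, function(a) sum(longevity > a), 0)
  if (negg_convention == "initial_females") {
    negg <- eggs_step / NF
  } else {
    if (any(alive == 0 & eggs_step > 0)) {
      condition_stop("eggs recorded at a step with no surviving female",
                     "lifetab_analysis_error")
    }
    negg <- ifelse(alive > 0, eggs_step / alive, 0)
  }
  # pivotal rule: adult age + 0.5; midpoint schedules sit half a census
  # interval further into each step
  half <- if (comp$age_convention == "midpoint") 0.5 + step / 2 else 0.5
  x <- dev_offset + ages + half
  life_schedule(
    x = x, lx = SURV * alive / NF, mx = negg * SR, step_days = step,
    meta = list(group = group, NF = NF, SURV = SURV, SR = SR,
                dev_offset_days = dev_offset,
                age_convention = comp$age_convention,
                negg_convention = negg_convention))
}

#' Per-capita eggs laid per age step (NEGG_x)
#'
#' @param data A `cohort_dataset`.
#' @param group A `group_key`.
#' @param convention `"initial_females"` divides each step's egg total by
#'   the cell's initial female count `NF` (default; keeps `lx` and `mx`
#'   independent); `"living_females"` divides by the females alive at the
#'   step.
#' @param step,age_convention Passed to the schedule grid; see
#'   [build_life_schedule()].
#' @return Numeric vector of eggs per female per step.
#' @export
per_capita_fecundity <- function(data, group,
                                 convention = c("initial_females",
                                                "living_females"),
                                 step = 1,
                                 age_convention = c("spread", "midpoint")) {
  convention <- match.arg(convention)
  fem <- cohort_subset(data, group)$females
  comp <- schedule_components(fem, step, match.arg(age_convention))
  sched <- assemble_schedule(comp, seq_len(nrow(fem)), SURV = 1, SR = 1,
                             dev_offset = 0, group = group,
                             negg_convention = convention)
  sched$mx
}

#' Build the full life schedule of a treatment cell
#'
#' Combines adult survival, pooled immature survival, pooled offspring
#' sex ratio, and per-capita fecundity into the `(x, lx, mx)` schedule at
#' pivotal ages `x = dev_offset + adult age + 0.5` (plus half a census
#' interval under the midpoint convention). The development offset is the
#' mean egg-to-adult period of the cell's emerged subsample individuals
#' (sexes combined by default).
#'
#' @inheritParams per_capita_fecundity
#' @param negg_convention See [per_capita_fecundity()].
#' @param dev_offset Override the development offset in days (e.g. for
#'   sensitivity analysis, or when the cell has no development records).
#' @param dev_sex `"combined"` (default), `"female"`, or `"male"`:
#'   which emerged individuals set the offset.
#' @return A [life_schedule()] with provenance metadata.
#' @export
build_life_schedule <- function(data, group, step = 1,
                                age_convention = c("spread", "midpoint"),
                                negg_convention = c("initial_females",
                                                    "living_females"),
                                dev_offset = NULL,
                                dev_sex = c("combined", "female", "male")) {
  age_convention <- match.arg(age_convention)
  negg_convention <- match.arg(negg_convention)
  dev_sex <- match.arg(dev_sex)
  cell <- cohort_subset(data, group)
  if (is.null(dev_offset)) {
    dev <- cell$dev[cell$dev$outcome == "emerged", , drop = FALSE]
    if (dev_sex != "combined") dev <- dev[dev$sex == dev_sex, , drop = FALSE]
    if (nrow(dev) == 0L) {
      condition_stop(
        sprintf("cell %s has no emerged development records; supply dev_offset",
                format(group)),
        "lifetab_analysis_error")
    }
    dev_offset <- mean(dev$dev_days)
  }
  comp <- schedule_components(cell$females, step, age_convention)
  assemble_schedule(comp, seq_len(nrow(cell$females)),
                    SURV = immature_survival(data, group),
                    SR = offspring_sex_ratio(data, group),
                    dev_offset = dev_offset, group = group,
                    negg_convention = negg_convention)
}
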