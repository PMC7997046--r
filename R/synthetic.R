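## Stochastic single-pair cohort generator.
##
## Emulates the rearing design the analysis expects: n single-pair
## families per treatment cell, egg censuses every census_interval_days,
## per-family offspring tallies, and an independent egg-to-adult
## development subsample. Distribution families are modelling choices
## (not claims about the organism): gamma for longevity, fecundity and
## development (integerized to whole observation days), binomial for
## offspring survival and sex, and a front-loaded exponential-decay
## kernel for the within-life placement of eggs. A single master seed
## drives deterministic per-family substreams, so datasets are
## reproducible and insertion-order invariant.

#' Generator parameters for one treatment cell
#'
#' @param group A [group_key()].
#' @param n_females Number of single-pair families.
#' @param longevity_mean,longevity_sd Adult female longevity (days;
#'   gamma, recorded to whole days, minimum 1).
#' @param oviposition_fraction Fraction of each female's longevity spent
#'   ovipositing (the egg-laying window).
#' @param fecundity_mean,fecundity_sd Lifetime eggs per female (gamma,
#'   rounded to an integer).
#' @param fecundity_decay Exponential decay rate (per day) of the
#'   egg-deposition kernel across the oviposition window; 0 = flat.
#' @param offspring_survival_p Egg-to-adult survival probability.
#' @param female_fraction_p Probability an emerged adult is female.
#' @param dev_female_mean,dev_female_sd,dev_male_mean,dev_male_sd
#'   Egg-to-adult development period by sex (days; gamma, recorded to
#'   whole days).
#' @param census_interval_days Census spacing (default 2).
#' @param dev_subsample_n Eggs in the development subsample (default 60).
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(group, n_females = 30,
                       longevity_mean, longevity_sd,
                       oviposition_fraction,
                       fecundity_mean, fecundity_sd,
                       fecundity_decay = 0,
                       offspring_survival_p, female_fraction_p,
                       dev_female_mean, dev_female_sd,
                       dev_male_mean, dev_male_sd,
                       census_interval_days = 2,
                       dev_subsample_n = 60) {
  stopifnot(inherits(group, "group_key"))
  p <- structure(
    list(group = group, n_females = as.integer(n_females),
         longevity_mean = longevity_mean, longevity_sd = longevity_sd,
         oviposition_fraction = oviposition_fraction,
         fecundity_mean = fecundity_mean, fecundity_sd = fecundity_sd,
         fecundity_decay = fecundity_decay,
         offspring_survival_p = offspring_survival_p,
         female_fraction_p = female_fraction_p,
         dev_female_mean = dev_female_mean, dev_female_sd = dev_female_sd,
         dev_male_mean = dev_male_mean, dev_male_sd = dev_male_sd,
         census_interval_days = census_interval_days,
         dev_subsample_n = as.integer(dev_subsample_n)),
    class = "gen_params")
  probs <- c(p$offspring_survival_p, p$female_fraction_p)
  if (any(probs < 0) || any(probs > 1) ||
      p$oviposition_fraction <= 0 || p$oviposition_fraction > 1) {
    condition_stop("probabilities/fractions must lie in [0, 1]",
                   "lifetab_validation_error")
  }
  if (p$n_females < 1L || p$longevity_mean <= 0 || p$fecundity_mean <= 0 ||
      p$dev_female_mean <= 0 || p$dev_male_mean <= 0 ||
      p$census_interval_days <= 0) {
    condition_stop("means, counts and intervals must be positive",
                   "lifetab_validation_error")
  }
  if (min(p$longevity_sd, p$fecundity_sd, p$dev_female_sd, p$dev_male_sd) < 0 ||
      p$fecundity_decay < 0) {
    condition_stop("sds and the kernel decay must be non-negative",
                   "lifetab_validation_error")
  }
  p
}

#' @export
print.gen_params <- function(x, ...) {
  cat(sprintf("<gen_params> %s: %d females, longevity %.1f +/- %.1f d, fecundity %.1f +/- %.1f\n",
              format(x$group), x$n_females, x$longevity_mean, x$longevity_sd,
              x$fecundity_mean, x$fecundity_sd))
  cat(sprintf("  ovip fraction %.3f, kernel decay %.4f /d, surv %.4f, female %.4f\n",
              x$oviposition_fraction, x$fecundity_decay,
              x$offspring_survival_p, x$female_fraction_p))
  invisible(x)
}

## Exact distribution of max(min_value, round(X)), X ~ gamma(mean, sd).
## sd = 0 degenerates to a point mass. Tail truncated at 1e-12 total mass.
discretize_gamma <- function(mean, sd, min_value = 1) {
  if (sd <= 0) {
    return(list(values = max(min_value, round(mean)), prob = 1))
  }
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  top <- ceiling(qgamma(1 - 1e-12, shape, rate)) + 1
  values <- min_value:top
  upper <- pgamma(values + 0.5, shape, rate)
  lower <- pgamma(values - 0.5, shape, rate)
  prob <- upper - lower
  prob[1] <- upper[1]            # all mass below min_value + 0.5 clamps up
  keep <- prob > 0
  list(values = values[keep], prob = prob[keep] / sum(prob[keep]))
}

draw_int_gamma <- function(n, mean, sd, min_value = 1) {
  if (sd <= 0) return(rep(max(min_value, round(mean)), n))
  shape <- (mean / sd)^2
  pmax(min_value, round(rgamma(n, shape, mean / sd^2)))
}

## Daily egg-placement weights over the oviposition window of a female
## with integer longevity L: J = max(1, round(frac * L)) laying days,
## weight exp(-decay * (d - 1)) on day d, normalized.
kernel_weights <- function(L, frac, decay) {
  J <- max(1, round(frac * L))
  w <- exp(-decay * (0:(J - 1)))
  w / sum(w)
}

## Aggregate a daily weight vector into censuses of width ci (the last
## census truncated at the death day L) and respread each census total
## evenly over its days -- exactly the information loss the 2-day census
## and the daily-spread schedule convention impose on real data.
census_blur <- function(w, L, ci) {
  out <- numeric(L)
  out[seq_along(w)] <- w
  K <- ceiling(L / ci)
  for (k in seq_len(K)) {
    d0 <- floor((k - 1) * ci) + 1
    d1 <- min(ceiling(k * ci), L)
    days <- d0:d1
    out[days] <- sum(out[days]) / length(days)
  }
  out
}

## Deterministic substream seed below 2^31, Lehmer-style mix of the
## master seed and an entity index.
substream_seed <- function(master, idx) {
  as.integer((as.double(master %% 2147483647L) * 48271 + idx * 16807 + 1) %%
               2147483647)
}

#' Generate a synthetic cohort dataset for one treatment cell
#'
#' Draws `n_females` single-pair families under `params` (see
#' [gen_params()]): integer-day longevity, lifetime fecundity placed
#' across the oviposition window by a multinomial draw over the decay
#' kernel, egg counts recorded per census interval, binomial offspring
#' survival and sex tallies, and an independent development subsample.
#' The same `(params, seed)` pair always yields an identical dataset.
#'
#' @param params A `gen_params`.
#' @param seed Master seed (integer). `NULL` draws one from the current
#'   RNG stream.
#' @return A validated [cohort_dataset()] for the single cell.
#' @export
generate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "gen_params"))
  p <- params
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  ci <- p$census_interval_days
  n <- p$n_females
  ids <- sprintf("%s_%s_F%03d", p$group$treatment, p$group$host, seq_len(n))

  females <- vector("list", n)
  offspring <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    L <- as.integer(draw_int_gamma(1, p$longevity_mean, p$longevity_sd))
    Fi <- as.integer(draw_int_gamma(1, p$fecundity_mean, p$fecundity_sd,
                                    min_value = 0))
    w <- kernel_weights(L, p$oviposition_fraction, p$fecundity_decay)
    daily <- numeric(L)
    if (Fi > 0) {
      daily[seq_along(w)] <- rmultinom(1, Fi, w)[, 1]
    }
    K <- ceiling(L / ci)
    census <- integer(K)
    for (k in seq_len(K)) {
      d0 <- floor((k - 1) * ci) + 1
      d1 <- min(ceiling(k * ci), L)
      census[k] <- as.integer(sum(daily[d0:d1]))
    }
    ovip <- if (any(daily > 0)) max(which(daily > 0)) else 0L
    n_ad <- rbinom(1, Fi, p$offspring_survival_p)
    n_fa <- rbinom(1, n_ad, p$female_fraction_p)
    females[[i]] <- data.frame(
      female_id = ids[i], treatment = p$group$treatment, host = p$group$host,
      census_interval_days = ci, longevity_days = L,
      oviposition_days = ovip, post_oviposition_days = L - ovip,
      stringsAsFactors = FALSE)
    females[[i]]$census_eggs <- list(census)
    offspring[[i]] <- data.frame(
      female_id = ids[i], n_eggs = Fi, n_adults = n_ad,
      n_female_adults = n_fa, stringsAsFactors = FALSE)
  }
  fem <- do.call(rbind, females)
  off <- do.call(rbind, offspring)

  set.seed(substream_seed(seed, 1000003L))
  nd <- p$dev_subsample_n
  emerged <- rbinom(nd, 1, p$offspring_survival_p) == 1
  sex <- ifelse(emerged,
                ifelse(rbinom(nd, 1, p$female_fraction_p) == 1,
                       "female", "male"),
                NA_character_)
  dev_days <- rep(NA_real_, nd)
  is_f <- emerged & sex == "female"
  is_m <- emerged & sex == "male"
  dev_days[which(is_f)] <- draw_int_gamma(sum(is_f), p$dev_female_mean,
                                          p$dev_female_sd)
  dev_days[which(is_m)] <- draw_int_gamma(sum(is_m), p$dev_male_mean,
                                          p$dev_male_sd)
  dev <- data.frame(
    treatment = p$group$treatment, host = p$group$host, sex = sex,
    outcome = ifelse(emerged, "emerged", "died"), dev_days = dev_days,
    stringsAsFactors = FALSE)

  cohort_dataset(fem, off, dev)
}

#' Generate a full factorial synthetic study
#'
#' One cohort per requested cell (default: all eight published cells),
#' each from its calibrated preset, with per-cell seeds derived from one
#' master seed.
#'
#' @param seed Master seed.
#' @param cells Optional data.frame with columns `treatment`, `host`
#'   (default [reference_table()]'s eight cells).
#' @param n_females Families per cell.
#' @return A combined, validated [cohort_dataset()].
#' @export
generate_study <- function(seed, cells = NULL, n_females = 30) {
  if (is.null(cells)) cells <- reference_table()[, c("treatment", "host")]
  parts <- lapply(seq_len(nrow(cells)), function(j) {
    g <- group_key(cells$treatment[j], cells$host[j])
    params <- preset_params(g, n_females = n_females)
    generate_cohort(params, seed = substream_seed(seed, 7000000L + j))
  })
  cohort_dataset(
    do.call(rbind, lapply(parts, `[[`, "females")),
    do.call(rbind, lapply(parts, `[[`, "offspring")),
    do.call(rbind, lapply(parts, `[[`, "dev")))
}
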