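# Fixtures are built in code: tiny hand-specified cohorts for exact
# checks, and generator-driven cohorts for property-style tests.

female_row <- function(id, eggs, longevity = NULL, ci = 2,
                       treatment = "C1", host = "cucumber",
                       ovip = NULL, post = NULL) {
  if (is.null(longevity)) longevity <- length(eggs) * ci
  if (is.null(ovip)) ovip <- if (any(eggs > 0)) max(which(eggs > 0)) * ci else 0
  ovip <- min(ovip, longevity)
  if (is.null(post)) post <- longevity - ovip
  df <- data.frame(female_id = id, treatment = treatment, host = host,
                   census_interval_days = ci, longevity_days = longevity,
                   oviposition_days = ovip, post_oviposition_days = post,
                   stringsAsFactors = FALSE)
  df$census_eggs <- list(as.integer(eggs))
  df
}

tally_row <- function(id, eggs, adults, females) {
  data.frame(female_id = id, n_eggs = eggs, n_adults = adults,
             n_female_adults = females, stringsAsFactors = FALSE)
}

dev_rows <- function(days, sex = "female", treatment = "C1",
                     host = "cucumber") {
  data.frame(treatment = treatment, host = host,
             sex = rep_len(sex, length(days)), outcome = "emerged",
             dev_days = days, stringsAsFactors = FALSE)
}

# two-female toy cell used across modules
toy_cohort <- function() {
  cohort_dataset(
    rbind(female_row("f1", c(6, 4), longevity = 4),
          female_row("f2", c(10, 0), longevity = 3)),
    rbind(tally_row("f1", 10, 8, 5), tally_row("f2", 10, 6, 3)),
    dev_rows(c(15, 16, 14)))
}

# unconstrained random schedule for solver property tests
random_schedule <- function(n_ages = sample(5:40, 1)) {
  x0 <- runif(1, 5, 25)
  x <- x0 + seq_len(n_ages) - 1
  lx <- cumprod(runif(n_ages, 0.7, 1)) * runif(1, 0.5, 1)
  mx <- rgamma(n_ages, shape = 1.2, rate = 0.4) *
    exp(-0.1 * seq_len(n_ages)) * sample(c(0.3, 1, 3), 1)
  life_schedule(x, lx, mx)
}

# independent Euler-Lotka oracle: staged grid sign-scan down to 1e-6
grid_scan_r <- function(schedule, lo = -1, hi = 2) {
  x <- schedule$x
  lxmx <- schedule$lx * schedule$mx
  f <- function(r) colSums(exp(-outer(x, r)) * lxmx) - 1
  for (step in c(1e-2, 1e-4, 1e-6)) {
    grid <- seq(lo, hi, by = step)
    v <- f(grid)
    i <- which(v[-length(v)] > 0 & v[-1] <= 0)
    if (!length(i)) stop("oracle: no sign change in bracket")
    i <- i[1]
    lo <- grid[i]; hi <- grid[i + 1]
  }
  (lo + hi) / 2
}

# small generator-driven cohort for integration-style tests
sim_cohort <- function(seed, n = 12, treatment = "C2", host = "cucumber") {
  g <- group_key(treatment, host)
  generate_cohort(preset_params(g, n_females = n), seed = seed)
}
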