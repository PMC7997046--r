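test_that("adult survival counts females alive past each step", {
  d <- cohort_dataset(
    rbind(female_row("f1", c(2), longevity = 1, ci = 2),
          female_row("f2", c(2), longevity = 2, ci = 2),
          female_row("f3", c(2, 2), longevity = 3, ci = 2)),
    rbind(tally_row("f1", 2, 1, 1), tally_row("f2", 2, 1, 1),
          tally_row("f3", 4, 2, 1)),
    dev_rows(15))
  g <- group_key("C1", "cucumber")
  expect_equal(adult_survival(d, g, step = 1), c(1, 2 / 3, 1 / 3))

  # all females share a longevity: survival is flat 1 over the lifespan
  shared <- cohort_dataset(
    rbind(female_row("a", c(3, 3), longevity = 4),
          female_row("b", c(1, 1), longevity = 4)),
    rbind(tally_row("a", 6, 3, 2), tally_row("b", 2, 2, 1)),
    dev_rows(15))
  expect_equal(adult_survival(shared, g, step = 1), rep(1, 4))

  # brute-force recount over a generated cohort
  d2 <- sim_cohort(seed = 3, n = 20)
  g2 <- group_key("C2", "cucumber")
  frac <- adult_survival(d2, g2, step = 1)
  lon <- d2$females$longevity_days
  oracle <- sapply(seq_along(frac) - 1, function(a) mean(lon > a))
  expect_equal(frac, oracle)
})

test_that("pooled immature survival and sex ratio are count ratios", {
  g <- group_key("C1", "cucumber")
  make <- function(tallies) {
    fem <- do.call(rbind, lapply(tallies$female_id, function(id) {
      female_row(id, c(1, 1))
    }))
    cohort_dataset(fem, tallies, dev_rows(15))
  }
  # brood tallies summing to published pooled counts give exact ratios
  d <- make(rbind(tally_row("f1", 5000, 4031, 1543),
                  tally_row("f2", 32, 32, 32)))
  expect_equal(immature_survival(d, g), 4063 / 5032)
  expect_equal(offspring_sex_ratio(d, g), 1575 / 4063)

  zero <- make(rbind(tally_row("f1", 10, 0, 0), tally_row("f2", 5, 0, 0)))
  expect_equal(immature_survival(zero, g), 0)
  expect_error(offspring_sex_ratio(zero, g), class = "lifetab_analysis_error")
  none <- make(rbind(tally_row("f1", 0, 0, 0), tally_row("f2", 0, 0, 0)))
  expect_error(immature_survival(none, g), class = "lifetab_analysis_error")
})

test_that("per-capita fecundity spreads census counts and conserves eggs", {
  g <- group_key("C1", "cucumber")
  d <- cohort_dataset(
    rbind(female_row("f1", c(4), longevity = 2),
          female_row("f2", c(4), longevity = 2)),
    rbind(tally_row("f1", 4, 2, 1), tally_row("f2", 4, 2, 1)),
    dev_rows(15))
  # 4 eggs per female in one 2-day interval -> 2/d per female on 2 daily steps
  expect_equal(per_capita_fecundity(d, g), c(2, 2))
  # at interval resolution the whole count sits on one step
  expect_equal(per_capita_fecundity(d, g, age_convention = "midpoint"), 4)

  zero <- cohort_dataset(
    female_row("f1", c(0, 0)), tally_row("f1", 0, 0, 0), dev_rows(15))
  expect_equal(per_capita_fecundity(zero, g), c(0, 0, 0, 0))

  # conservation: sum(NEGG) * NF = total eggs (initial-females convention)
  d2 <- sim_cohort(seed = 5, n = 25)
  g2 <- group_key("C2", "cucumber")
  negg <- per_capita_fecundity(d2, g2)
  expect_equal(sum(negg) * nrow(d2$females),
               sum(unlist(d2$females$census_eggs)))
})

test_that("build_life_schedule composes components and sets pivotal ages", {
  g <- group_key("C1", "cucumber")
  # NF=2, daily censuses; day-1 total 8 eggs, day-2 total 8 eggs;
  # one female dies after day 1 -> adult survival [1, 0.5];
  # SURV = 8/16 = 0.5, SR = 4/8 = 0.5
  d <- cohort_dataset(
    rbind(female_row("f1", c(8), longevity = 1, ci = 1),
          female_row("f2", c(0, 8), longevity = 2, ci = 1)),
    rbind(tally_row("f1", 8, 4, 2), tally_row("f2", 8, 4, 2)),
    dev_rows(c(15, 15)))
  s <- build_life_schedule(d, g)
  expect_equal(s$lx, c(0.5, 0.25))
  expect_equal(s$mx, c(2, 2))
  expect_equal(s$x, c(15.5, 16.5))
  expect_equal(s$meta$SURV, 0.5)
  expect_equal(net_reproductive_rate(s), sum(s$lx * s$mx))

  # mean development period of emerged offspring sets the offset (+0.5)
  dev <- dev_rows(c(15, 15.3, 15.0))   # mean 15.1
  d2 <- cohort_dataset(d$females, d$offspring, dev)
  s2 <- build_life_schedule(d2, g)
  expect_equal(s2$x[1], 15.1 + 0.5)
  # explicit override wins
  s3 <- build_life_schedule(d2, g, dev_offset = 20)
  expect_equal(s3$x[1], 20.5)

  # midpoint convention: x starts at dev + 0.5 + half the census interval
  d3 <- toy_cohort()
  s4 <- build_life_schedule(d3, g, age_convention = "midpoint")
  expect_equal(s4$x[1], mean(c(15, 16, 14)) + 0.5 + 1)
  expect_equal(s4$step_days, 2)
})

test_that("schedules obey invariants and ignore record order", {
  g <- group_key("C2", "cucumber")
  d <- sim_cohort(seed = 8, n = 18)
  s <- build_life_schedule(d, g)
  expect_true(all(diff(s$lx) <= 1e-12))
  expect_equal(s$lx[1], s$meta$SURV)   # everyone alive at first adult step
  expect_true(all(diff(s$x) > 0))
  # integer egg conservation through lx/mx assembly
  expect_equal(sum(s$mx) * s$meta$NF / s$meta$SR,
               sum(unlist(d$females$census_eggs)))

  perm <- sample(nrow(d$females))
  d2 <- cohort_dataset(d$females[perm, ], d$offspring, d$dev)
  s2 <- build_life_schedule(d2, g)
  expect_equal(s2$x, s$x)
  expect_equal(s2$lx, s$lx)
  expect_equal(s2$mx, s$mx)

  # living-females convention: conservation against direct per-step sums
  s5 <- build_life_schedule(d, g, negg_convention = "living_females")
  expect_equal(length(s5$mx), length(s$mx))
  expect_true(all(s5$mx >= s$mx - 1e-12))  # divisor never exceeds NF
})
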