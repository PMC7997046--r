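test_that("CSV round trip is lossless and grouped access works", {
  dir <- withr::local_tempdir()
  orig <- toy_cohort()
  write_cohort(orig, dir)
  back <- read_cohort(dir)
  expect_identical(back$females$female_id, orig$females$female_id)
  expect_identical(back$females$census_eggs, orig$females$census_eggs)
  for (col in c("longevity_days", "oviposition_days",
                "post_oviposition_days", "census_interval_days")) {
    expect_equal(back$females[[col]], orig$females[[col]])
  }
  expect_equal(back$offspring, orig$offspring)
  expect_equal(back$dev, orig$dev)

  cell <- cohort_subset(back, group_key("C1", "cucumber"))
  expect_equal(nrow(cell$females), 2L)
  expect_error(cohort_subset(back, group_key("C2", "tobacco")),
               class = "lifetab_analysis_error")
})

test_that("schema and invariant violations raise named classed errors", {
  dir <- withr::local_tempdir()
  write_cohort(toy_cohort(), dir)

  # missing column -> schema error naming the column
  fem <- read.csv(file.path(dir, "females.csv"))
  fem$longevity_days <- NULL
  write.csv(fem, file.path(dir, "females.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "longevity_days",
               class = "lifetab_schema_error")

  # n_adults > n_eggs -> validation error citing the ordering rule
  expect_error(
    cohort_dataset(female_row("f1", c(5, 5)),
                   tally_row("f1", eggs = 4, adults = 9, females = 1),
                   dev_rows(15)),
    "n_female_adults <= n_adults <= n_eggs",
    class = "lifetab_validation_error")

  # unresolved offspring reference
  expect_error(
    cohort_dataset(female_row("f1", c(5, 5)),
                   tally_row("ghost", 4, 3, 1), dev_rows(15)),
    "ghost", class = "lifetab_validation_error")

  # periods exceeding longevity + census slack
  expect_error(
    cohort_dataset(female_row("f1", c(5, 5), longevity = 4,
                              ovip = 4, post = 3),
                   tally_row("f1", 10, 8, 4), dev_rows(15)),
    class = "lifetab_validation_error")

  # census series too short for the lifespan
  expect_error(
    cohort_dataset(female_row("f1", c(5), longevity = 9, ci = 2),
                   tally_row("f1", 5, 4, 2), dev_rows(15)),
    class = "lifetab_validation_error")

  # dev_days on a dead individual
  bad_dev <- data.frame(treatment = "C1", host = "cucumber", sex = "female",
                        outcome = "died", dev_days = 12)
  expect_error(
    cohort_dataset(female_row("f1", c(5, 5)), tally_row("f1", 10, 8, 4),
                   bad_dev),
    class = "lifetab_validation_error")
})

test_that("summarize_biology computes per-female means, SEs and both ratio scales", {
  # single female: total 10 eggs over 5 d -> daily 2.0
  one <- cohort_dataset(female_row("f1", c(6, 4), longevity = 5),
                        tally_row("f1", 10, 8, 4), dev_rows(15))
  s1 <- summarize_biology(one, group_key("C1", "cucumber"))
  expect_equal(s1$total_fecundity[["mean"]], 10)
  expect_equal(s1$daily_fecundity[["mean"]], 2)

  s <- summarize_biology(toy_cohort(), group_key("C1", "cucumber"))
  expect_equal(s$total_fecundity[["mean"]], 10)
  expect_equal(s$total_fecundity[["se"]], sd(c(10, 10)) / sqrt(2))
  expect_equal(s$longevity[["mean"]], 3.5)
  # per-female mean of ratios vs pooled counts: equal egg counts -> equal
  expect_equal(s$survival[["mean"]], mean(c(8 / 10, 6 / 10)))
  expect_equal(s$survival_pooled, 14 / 20)
  expect_equal(s$survival[["mean"]], s$survival_pooled)
  # unequal broods: the two scales genuinely differ
  uneq <- cohort_dataset(
    rbind(female_row("f1", c(20, 0)), female_row("f2", c(2, 2))),
    rbind(tally_row("f1", 20, 10, 5), tally_row("f2", 4, 4, 2)),
    dev_rows(15))
  su <- summarize_biology(uneq, group_key("C1", "cucumber"))
  expect_equal(su$survival[["mean"]], mean(c(0.5, 1)))
  expect_equal(su$survival_pooled, 14 / 24)
  expect_false(isTRUE(all.equal(su$survival[["mean"]], su$survival_pooled)))
  expect_equal(su$dev_all[["n"]], 1)
})

test_that("fecundity totals conserve census counts on generated cohorts", {
  d <- sim_cohort(seed = 11, n = 15)
  s <- summarize_biology(d, group_key("C2", "cucumber"))
  manual <- vapply(d$females$census_eggs, sum, 0)
  expect_equal(s$total_fecundity[["mean"]] * s$n_females, sum(manual))
})
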