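test_that("jackknife of a linear statistic reproduces the closed-form SE", {
  set.seed(123)
  for (k in 1:10) {
    x <- rgamma(sample(5:40, 1), shape = 2, rate = 0.1)
    jk <- jackknife_stat(x, mean)
    expect_equal(jk$jk_mean, mean(x), tolerance = 1e-12)
    expect_equal(jk$jk_se, sd(x) / sqrt(length(x)), tolerance = 1e-12)
  }
})

test_that("identical families give zero jackknife spread", {
  fem <- do.call(rbind, lapply(1:5, function(i) {
    female_row(paste0("f", i), c(30, 20, 10), longevity = 6)
  }))
  off <- do.call(rbind, lapply(1:5, function(i) {
    tally_row(paste0("f", i), 60, 48, 24)
  }))
  d <- cohort_dataset(fem, off, dev_rows(c(15, 16)))
  jk <- jackknife_lifetable(d, group_key("C1", "cucumber"))
  for (p in c("r", "lambda", "R0", "T")) {
    expect_equal(jk[[p]]$jk_se, 0, tolerance = 1e-10)
    expect_equal(jk[[p]]$jk_mean, jk[[p]]$theta_all, tolerance = 1e-8)
  }
})

test_that("pseudo-values match a from-scratch leave-one-out recomputation", {
  g <- group_key("C2", "cucumber")
  d <- sim_cohort(seed = 21, n = 8)
  dev_off <- mean(d$dev$dev_days[d$dev$outcome == "emerged"])
  jk <- jackknife_lifetable(d, g)
  n <- nrow(d$females)
  theta_all <- demographic_params(build_life_schedule(d, g))

  for (i in seq_len(n)) {
    keep <- d$females$female_id[-i]
    sub <- cohort_dataset(
      d$females[d$females$female_id %in% keep, ],
      d$offspring[d$offspring$female_id %in% keep, ],
      d$dev)
    p_i <- demographic_params(build_life_schedule(sub, g, dev_offset = dev_off))
    for (p in c("r", "lambda", "R0", "T")) {
      expect_equal(jk[[p]]$pseudo[i],
                   n * theta_all[[p]] - (n - 1) * p_i[[p]],
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
  # pseudo-value mean/SE invariants
  expect_equal(jk$r$jk_mean, mean(jk$r$pseudo))
  expect_equal(jk$r$jk_se, sd(jk$r$pseudo) / sqrt(n))
})

test_that("compare_groups separates cells consistently with pairwise tests", {
  set.seed(5)
  fake_est <- function(pseudo, name = "r") {
    structure(list(parameter = name, pseudo = pseudo,
                   flagged = rep(FALSE, length(pseudo)),
                   jk_mean = mean(pseudo),
                   jk_se = sd(pseudo) / sqrt(length(pseudo)),
                   n = length(pseudo)),
              class = "jackknife_estimate")
  }
  # identical pseudo-value sets share a letter
  p0 <- rnorm(20, 0.2, 0.01)
  cld <- compare_groups(list(a = fake_est(p0), b = fake_est(p0)))
  expect_equal(cld$letters[1], cld$letters[2])

  # separation far beyond within-cell spread -> distinct letters in mean order
  cld2 <- compare_groups(list(hi = fake_est(rnorm(20, 0.9, 0.005)),
                              lo = fake_est(rnorm(20, 0.1, 0.005))))
  expect_equal(cld2$cell, c("hi", "lo"))
  expect_equal(cld2$letters, c("a", "b"))

  # 4 cells with known ordering: letters agree with brute-force all-pairs
  # studentized-range decisions (unequal n exercises Tukey-Kramer)
  for (trial in 1:20) {
    mu <- c(0.10, 0.14, 0.141, 0.25)
    ns <- c(25, 30, 28, 30)
    cells <- Map(function(m, n) fake_est(rnorm(n, m, 0.02)), mu, ns)
    names(cells) <- paste0("g", 1:4)
    cld <- compare_groups(cells)

    pseudo <- lapply(cells, `[[`, "pseudo")
    means <- vapply(pseudo, mean, 0)
    nn <- lengths(pseudo)
    dfe <- sum(nn - 1)
    mse <- sum((nn - 1) * vapply(pseudo, var, 0)) / dfe
    share <- function(i, j) {
      li <- strsplit(cld$letters[cld$cell == names(cells)[i]], "")[[1]]
      lj <- strsplit(cld$letters[cld$cell == names(cells)[j]], "")[[1]]
      length(intersect(li, lj)) > 0
    }
    for (i in 1:3) for (j in (i + 1):4) {
      q <- abs(means[i] - means[j]) /
        sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
      sig <- unname(ptukey(q, 4, dfe, lower.tail = FALSE) < 0.05)
      expect_equal(share(i, j), !sig)
    }
  }
})

test_that("deletions that erase all reproduction are flagged, not fatal", {
  # one dominant family holds nearly all reproduction; removing others is fine
  fem <- rbind(female_row("big", c(50, 50), longevity = 4),
               female_row("s1", c(0, 0), longevity = 4),
               female_row("s2", c(0, 0), longevity = 4),
               female_row("s3", c(0, 0), longevity = 4))
  off <- rbind(tally_row("big", 100, 80, 40), tally_row("s1", 0, 0, 0),
               tally_row("s2", 0, 0, 0), tally_row("s3", 0, 0, 0))
  d <- cohort_dataset(fem, off, dev_rows(c(15, 16)))
  jk <- jackknife_lifetable(d, group_key("C1", "cucumber"))
  expect_true(jk$r$flagged[1])          # deleting "big" kills reproduction
  expect_equal(jk$r$n_valid, 3L)
  expect_error(
    jackknife_lifetable(cohort_dataset(fem[1:3, ], off[1:3, ],
                                       dev_rows(c(15, 16))),
                        group_key("C1", "cucumber")),
    class = "lifetab_analysis_error")
})
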