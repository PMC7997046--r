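test_that("arcsine square-root transform hits endpoints and is monotone", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.5), pi / 4)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_sqrt(p)) > 0))
  expect_error(arcsine_sqrt(1.2), class = "lifetab_validation_error")
  expect_error(arcsine_sqrt(-0.1), class = "lifetab_validation_error")
})

test_that("balanced additive two-way data have zero interaction SS", {
  A <- rep(c("c1", "c2"), each = 6)
  B <- rep(rep(c("h1", "h2"), each = 3), 2)
  y <- 10 + 2 * (A == "c2") + 5 * (B == "h2")   # purely additive, no noise
  tab <- two_way_anova(y, A, B)
  expect_equal(tab["A:B", "ss"], 0, tolerance = 1e-20)
  expect_equal(sum(tab$df), length(y) - 1)
  # balanced: Type III equals sequential Type I
  set.seed(1)
  y2 <- y + rnorm(12)
  t3 <- two_way_anova(y2, A, B)
  t1 <- two_way_anova(y2, A, B, ss_type = "I")
  expect_equal(t3$ss, t1$ss, tolerance = 1e-10)
  # permutation of factor-level labels leaves SS unchanged
  t3b <- two_way_anova(y2, ifelse(A == "c1", "z9", "a0"), B)
  expect_equal(t3b$ss, t3$ss, tolerance = 1e-10)
})

test_that("constant responses yield zero SS and flagged F", {
  tab <- two_way_anova(rep(3, 12), rep(c("a", "b"), 6),
                       rep(c("x", "y"), each = 6))
  expect_equal(tab$ss, rep(0, 4), tolerance = 1e-20)
  expect_true(all(!is.finite(tab$F[1:3])))
})

test_that("unbalanced Type-III SS match a from-scratch normal-equations oracle", {
  set.seed(31)
  for (trial in 1:5) {
    nA <- sample(3:8, 4, replace = TRUE)  # unequal cell sizes
    A <- rep(rep(c("c1", "c2"), each = 2), times = nA)
    B <- rep(c("h1", "h2", "h1", "h2"), times = nA)
    y <- 5 + 1.5 * (A == "c2") - 2 * (B == "h2") +
      0.8 * (A == "c2") * (B == "h2") + rnorm(length(A))
    tab <- two_way_anova(y, A, B)

    # oracle: explicit sum-contrast dummies + normal equations via solve()
    a <- ifelse(A == "c1", 1, -1)
    b <- ifelse(B == "h1", 1, -1)
    X <- cbind(1, a, b, a * b)
    rss <- function(Xm) {
      beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
      sum((y - Xm %*% beta)^2)
    }
    full <- rss(X)
    ss_or <- c(rss(X[, -2]) - full, rss(X[, -3]) - full, rss(X[, -4]) - full)
    dfe <- length(y) - 4
    f_or <- ss_or / (full / dfe)
    expect_equal(tab$ss[1:3], ss_or, tolerance = 1e-9)
    expect_equal(tab$F[1:3], f_or, tolerance = 1e-9)
    expect_equal(tab["Residuals", "ss"], full, tolerance = 1e-9)
    expect_equal(sum(tab$df), length(y) - 1)
  }
  expect_error(two_way_anova(1:5, c("a", "a", "a", "b", "b"),
                             c("x", "x", "x", "x", "y")),
               "empty cell", class = "lifetab_analysis_error")
})

test_that("tukey_hsd separates means and matches the two-sample t-test", {
  # identical groups share one letter
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- tukey_hsd(g0)
  expect_equal(unique(r0$groups$letters), "a")

  # huge separation -> all distinct letters, descending means
  r1 <- tukey_hsd(list(lo = rnorm(10, 0, 0.1), hi = rnorm(10, 50, 0.1),
                       mid = rnorm(10, 25, 0.1)))
  expect_equal(r1$groups$group, c("hi", "mid", "lo"))
  expect_equal(r1$groups$letters, c("a", "b", "c"))

  # k = 2: studentized-range decision == pooled-variance t-test decision
  set.seed(17)
  for (trial in 1:20) {
    x <- rnorm(8, 0, 1); y <- rnorm(12, 0.8, 1)
    r <- tukey_hsd(list(x = x, y = y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$pairs$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("letter display equals brute-force graph partition on many groups", {
  set.seed(71)
  for (trial in 1:10) {
    k <- 8
    mu <- sample(c(0, 0.5, 0.6, 2, 2.05, 4, 6, 6.1))
    gr <- setNames(lapply(mu, function(m) rnorm(12, m, 0.5)),
                   paste0("g", 1:k))
    res <- tukey_hsd(gr)
    sig <- res$pairs
    share <- function(i, j) {
      li <- strsplit(res$groups$letters[res$groups$group == i], "")[[1]]
      lj <- strsplit(res$groups$letters[res$groups$group == j], "")[[1]]
      length(intersect(li, lj)) > 0
    }
    for (row in seq_len(nrow(sig))) {
      expect_equal(share(sig$group1[row], sig$group2[row]),
                   !sig$significant[row])
    }
  }
})
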