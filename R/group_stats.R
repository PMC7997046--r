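## Trait-level statistics across treatment cells: two-way ANOVA with a
## cluster x host interaction (Type-III-style sums of squares for
## unbalanced designs), the arcsine square-root transform for
## proportions, and Tukey studentized-range mean separation with a
## compact letter display.

#' Arcsine square-root transform for proportions
#'
#' @param p Proportions in `[0, 1]`.
#' @return `asin(sqrt(p))`, in radians; monotone on `[0, 1]` mapping 0 to
#'   0 and 1 to `pi/2`. Variance-stabilizing for binomial fractions.
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    condition_stop("proportions must lie in [0, 1]", "lifetab_validation_error")
  }
  asin(sqrt(p))
}

#' Two-way factorial analysis of variance
#'
#' Fits the full `A + B + A:B` model by least squares. With balanced
#' data the sums of squares are the classical orthogonal decomposition;
#' with unbalanced data the default is Type-III-style model-comparison
#' sums of squares under sum-to-zero contrasts (each term's SS is the
#' increase in residual SS when its columns are dropped from the full
#' model), mirroring the default of the usual GLM procedures. Type-I
#' (sequential) SS are available for comparison.
#'
#' @param values Numeric response vector.
#' @param factorA,factorB Factors (or coercible) of the same length.
#' @param ss_type `"III"` (default) or `"I"`.
#' @param term_names Labels for the two factors in the output.
#' @return An object of class `anova_table`: data.frame with rows for
#'   each factor, the interaction, and residuals; columns `df`, `ss`,
#'   `ms`, `F`, `p`.
#' @export
two_way_anova <- function(values, factorA, factorB, ss_type = c("III", "I"),
                          term_names = c("A", "B")) {
  ss_type <- match.arg(ss_type)
  fA <- factor(factorA); fB <- factor(factorB)
  stopifnot(length(values) == length(fA), length(fA) == length(fB))
  if (nlevels(fA) < 2L || nlevels(fB) < 2L) {
    condition_stop("each factor needs >= 2 levels", "lifetab_analysis_error")
  }
  tab <- table(fA, fB)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    condition_stop(
      sprintf("empty cell %s:%s", levels(fA)[empty[1]], levels(fB)[empty[2]]),
      "lifetab_analysis_error")
  }
  df <- data.frame(y = values, fA = fA, fB = fB)
  contr <- list(fA = "contr.sum", fB = "contr.sum")
  X <- stats::model.matrix(~ fA * fB, df, contrasts.arg = contr)
  assign <- attr(X, "assign")     # 0 intercept, 1 A, 2 B, 3 A:B
  rss <- function(Xm) {
    fit <- stats::lm.fit(Xm, values)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X)
  n <- length(values)
  df_res <- n - ncol(X)
  ms_res <- rss_full / df_res

  terms <- c(1, 2, 3)
  labels <- c(term_names[1], term_names[2],
              paste(term_names, collapse = ":"))
  if (ss_type == "III") {
    ss <- vapply(terms, function(t) rss(X[, assign != t, drop = FALSE]) - rss_full, 0)
    dfs <- vapply(terms, function(t) sum(assign == t), 0L)
  } else {
    ss <- numeric(3); dfs <- integer(3)
    prev <- rss(X[, assign == 0, drop = FALSE])
    for (k in seq_along(terms)) {
      cur <- rss(X[, assign <= terms[k], drop = FALSE])
      ss[k] <- prev - cur
      dfs[k] <- sum(assign == terms[k])
      prev <- cur
    }
  }
  ss <- pmax(ss, 0)
  # degenerate response (no variation at all): SS are pure roundoff and
  # the F ratios are 0/0 -- flag rather than report noise
  if (sum((values - mean(values))^2) <= 0) {
    ss[] <- 0
    rss_full <- 0
    ms_res <- NaN
  }
  out <- data.frame(
    df = c(dfs, df_res),
    ss = c(ss, rss_full),
    ms = c(ss / dfs, ms_res),
    F = c((ss / dfs) / ms_res, NA),
    p = c(pf((ss / dfs) / ms_res, dfs, df_res, lower.tail = FALSE), NA),
    row.names = c(labels, "Residuals"))
  structure(out, class = c("anova_table", "data.frame"), ss_type = ss_type)
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type %s sums of squares)\n", attr(x, "ss_type")))
  print.data.frame(format(as.data.frame(x), digits = 4))
  invisible(x)
}

## Compact letter display by insert-and-absorb: start from one class
## containing every group; each significantly different pair splits the
## classes containing both; classes that become subsets of another are
## absorbed. Groups are ordered by descending mean (ties broken by label)
## and letters assigned in that order, so output is deterministic.
letter_display <- function(means, sig) {
  labs <- names(means)
  ord <- labs[order(-unname(means), labs)]
  classes <- list(ord)
  key <- function(cl) paste(sort(cl), collapse = "\r")
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      a <- ord[i]; b <- ord[j]
      if (!isTRUE(sig[a, b])) next
      nxt <- list()
      for (cl in classes) {
        if (a %in% cl && b %in% cl) {
          nxt <- c(nxt, list(setdiff(cl, a)), list(setdiff(cl, b)))
        } else {
          nxt <- c(nxt, list(cl))
        }
      }
      nxt <- nxt[lengths(nxt) > 0]
      keys <- vapply(nxt, key, "")
      nxt <- nxt[!duplicated(keys)]
      keep <- rep(TRUE, length(nxt))
      for (p in seq_along(nxt)) {
        for (q in seq_along(nxt)) {
          if (p != q && keep[p] && keep[q] &&
              length(nxt[[p]]) < length(nxt[[q]]) &&
              all(nxt[[p]] %in% nxt[[q]])) {
            keep[p] <- FALSE
          }
        }
      }
      classes <- nxt[keep]
    }
  }
  # order classes by the first (highest-mean) group they contain
  first_pos <- vapply(classes, function(cl) min(match(cl, ord)), 0)
  classes <- classes[order(first_pos)]
  letters_out <- setNames(rep("", length(labs)), labs)
  for (k in seq_along(classes)) {
    for (g in classes[[k]]) {
      letters_out[g] <- paste0(letters_out[g], letters[k])
    }
  }
  letters_out
}

#' Tukey studentized-range test with compact letter display
#'
#' All-pairs comparison of group means using the studentized-range
#' distribution with the pooled within-group variance; unequal group
#' sizes use the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))`. Groups sharing a letter do not
#' differ significantly at `alpha`.
#'
#' @param groups Named list of numeric vectors (one per group, each of
#'   length >= 2).
#' @param alpha Familywise significance level.
#' @return List with `groups` (data.frame: group, n, mean, se, letters,
#'   ordered by descending mean), `pairs` (data.frame of pairwise
#'   differences, q statistics, p-values), `mse`, `df`. Degenerate
#'   (zero) pooled variance is flagged via attribute `degenerate`;
#'   groups with exactly equal means then share a letter.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    condition_stop("tukey_hsd needs a named list of >= 2 groups",
                   "lifetab_analysis_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    condition_stop("groups must be named", "lifetab_analysis_error")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    condition_stop("each group needs n >= 2", "lifetab_analysis_error")
  }
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, var, 0)
  dfe <- sum(ns - 1L)
  mse <- sum((ns - 1L) * vars) / dfe
  degenerate <- !isTRUE(mse > 0)

  labs <- names(groups)
  pairs <- t(combn(k, 2))
  pair_df <- data.frame(
    group1 = labs[pairs[, 1]], group2 = labs[pairs[, 2]],
    diff = means[pairs[, 1]] - means[pairs[, 2]])
  se_pair <- sqrt(mse / 2 * (1 / ns[pairs[, 1]] + 1 / ns[pairs[, 2]]))
  if (degenerate) {
    pair_df$q <- ifelse(abs(pair_df$diff) > 0, Inf, 0)
  } else {
    pair_df$q <- abs(pair_df$diff) / se_pair
  }
  pair_df$p <- ptukey(pair_df$q, k, dfe, lower.tail = FALSE)
  pair_df$significant <- pair_df$p < alpha
  rownames(pair_df) <- NULL

  sig <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  sig[cbind(pair_df$group1, pair_df$group2)] <- pair_df$significant
  sig[cbind(pair_df$group2, pair_df$group1)] <- pair_df$significant
  letters_out <- letter_display(means, sig)

  ord <- order(-means, labs)
  groups_df <- data.frame(
    group = labs[ord], n = as.integer(ns[ord]), mean = means[ord],
    se = sqrt(vars[ord] / ns[ord]), letters = letters_out[labs[ord]],
    row.names = NULL)
  structure(list(groups = groups_df, pairs = pair_df, mse = mse, df = dfe),
            degenerate = degenerate)
}
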