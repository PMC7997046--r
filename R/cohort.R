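## Individual-level cohort records: types, validation, delimited-text I/O.
##
## A cohort dataset couples three tables keyed by single-pair family:
##   females   - one row per adult female: interval egg censuses (stored as a
##               list column of integer counts), longevity, oviposition and
##               post-oviposition periods, treatment cell.
##   offspring - per-female progeny tallies: eggs laid, survivors to adult,
##               females among the adults.
##   dev       - an egg-to-adult development subsample (not linked to
##               mothers): sex, outcome, development days.

condition_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lifetab_error")))
}

#' Construct a treatment-cell key
#'
#' A group key identifies one treatment cell of the factorial design:
#' a mating treatment (single or reciprocal-cross cluster pairing) on a
#' host plant. Default vocabularies follow the four mating groups
#' (`C1`, `C2`, `C1fC2m`, `C2fC1m`) and two hosts (`cucumber`,
#' `tobacco`); both can be extended for other designs.
#'
#' @param treatment Mating-treatment label.
#' @param host Host-plant label.
#' @param treatments,hosts Allowed vocabularies.
#' @return An object of class `group_key` with elements `treatment` and
#'   `host`.
#' @export
#' @examples
#' group_key("C2", "cucumber")
group_key <- function(treatment, host,
                      treatments = .lifetab_treatments,
                      hosts = .lifetab_hosts) {
  treatment <- as.character(treatment)
  host <- as.character(host)
  if (length(treatment) != 1L || !treatment %in% treatments) {
    condition_stop(
      sprintf("unknown treatment '%s' (known: %s)", treatment,
              paste(treatments, collapse = ", ")),
      "lifetab_validation_error")
  }
  if (length(host) != 1L || !host %in% hosts) {
    condition_stop(
      sprintf("unknown host '%s' (known: %s)", host,
              paste(hosts, collapse = ", ")),
      "lifetab_validation_error")
  }
  structure(list(treatment = treatment, host = host), class = "group_key")
}

#' @export
format.group_key <- function(x, ...) paste0(x$treatment, "/", x$host)

#' @export
print.group_key <- function(x, ...) {
  cat("<group_key>", format(x), "\n")
  invisible(x)
}

#' All treatment cells present in a dataset
#'
#' @param data A `cohort_dataset`.
#' @return A data.frame with columns `treatment` and `host`, one row per
#'   non-empty cell, in first-appearance order.
#' @export
cohort_groups <- function(data) {
  stopifnot(inherits(data, "cohort_dataset"))
  unique(data$females[, c("treatment", "host")])
}

#' Assemble and validate a cohort dataset
#'
#' @param females data.frame with columns `female_id`, `treatment`, `host`,
#'   `census_interval_days`, `longevity_days`, `oviposition_days`,
#'   `post_oviposition_days` and a list column `census_eggs` of
#'   non-negative integer vectors (one count per census interval).
#' @param offspring data.frame with columns `female_id`, `n_eggs`,
#'   `n_adults`, `n_female_adults`.
#' @param dev data.frame with columns `treatment`, `host`, `sex`
#'   (`female`/`male`, `NA` allowed when the individual died before
#'   emergence), `outcome` (`emerged`/`died`), `dev_days` (`NA` unless
#'   emerged).
#' @param treatments,hosts Allowed label vocabularies.
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(females, offspring, dev,
                           treatments = .lifetab_treatments,
                           hosts = .lifetab_hosts,
                           validate = TRUE) {
  females <- as.data.frame(females, stringsAsFactors = FALSE)
  offspring <- as.data.frame(offspring, stringsAsFactors = FALSE)
  dev <- as.data.frame(dev, stringsAsFactors = FALSE)
  obj <- structure(
    list(females = females, offspring = offspring, dev = dev,
         treatments = treatments, hosts = hosts),
    class = "cohort_dataset")
  if (validate) validate_cohort(obj)
  obj
}

.required_cols <- list(
  females = c("female_id", "treatment", "host", "census_interval_days",
              "longevity_days", "oviposition_days", "post_oviposition_days",
              "census_eggs"),
  offspring = c("female_id", "n_eggs", "n_adults", "n_female_adults"),
  dev = c("treatment", "host", "sex", "outcome", "dev_days"))

check_schema <- function(df, what) {
  missing <- setdiff(.required_cols[[what]], names(df))
  if (length(missing)) {
    condition_stop(
      sprintf("%s table: missing column(s) %s", what,
              paste(sQuote(missing), collapse = ", ")),
      "lifetab_schema_error")
  }
}

#' Validate a cohort dataset against all record invariants
#'
#' Checks schemas, label vocabularies, and per-record rules: census egg
#' counts are non-negative integers; oviposition plus post-oviposition
#' periods cannot exceed longevity by more than one census interval (the
#' census-granularity slack); the census series must span the lifetime;
#' offspring tallies obey `n_female_adults <= n_adults <= n_eggs` and
#' resolve to a known female; development days are recorded exactly for
#' emerged individuals.
#'
#' @param data A `cohort_dataset`.
#' @return `data`, invisibly, if valid; otherwise a classed error
#'   (`lifetab_schema_error` / `lifetab_validation_error`) naming the
#'   offending record and rule.
#' @export
validate_cohort <- function(data) {
  stopifnot(inherits(data, "cohort_dataset"))
  fem <- data$females; off <- data$offspring; dev <- data$dev
  check_schema(fem, "females")
  check_schema(off, "offspring")
  check_schema(dev, "dev")

  if (anyDuplicated(fem$female_id)) {
    condition_stop("females: duplicated female_id", "lifetab_validation_error")
  }
  bad <- !fem$treatment %in% data$treatments | !fem$host %in% data$hosts
  if (any(bad)) {
    condition_stop(
      sprintf("females %s: treatment/host outside declared vocabulary",
              paste(fem$female_id[bad], collapse = ", ")),
      "lifetab_validation_error")
  }
  for (i in seq_len(nrow(fem))) {
    id <- fem$female_id[i]
    eggs <- fem$census_eggs[[i]]
    ci <- fem$census_interval_days[i]
    lon <- fem$longevity_days[i]
    ovi <- fem$oviposition_days[i]
    post <- fem$post_oviposition_days[i]
    if (!is.numeric(eggs) || length(eggs) < 1L ||
        any(eggs < 0) || any(eggs != round(eggs))) {
      condition_stop(
        sprintf("female %s: census_eggs must be non-negative integers", id),
        "lifetab_validation_error")
    }
    if (!isTRUE(ci > 0) || !isTRUE(lon > 0) || !isTRUE(ovi >= 0) ||
        !isTRUE(post >= 0)) {
      condition_stop(
        sprintf("female %s: periods must be positive (longevity, interval) or non-negative", id),
        "lifetab_validation_error")
    }
    if (ovi + post > lon + ci + 1e-9) {
      condition_stop(
        sprintf("female %s: oviposition + post-oviposition (%.3g) exceeds longevity + census interval (%.3g)",
                id, ovi + post, lon + ci),
        "lifetab_validation_error")
    }
    if (length(eggs) * ci < lon - ci - 1e-9) {
      condition_stop(
        sprintf("female %s: %d census entries x %.3g d do not span longevity %.3g d",
                id, length(eggs), ci, lon),
        "lifetab_validation_error")
    }
  }

  unresolved <- setdiff(off$female_id, fem$female_id)
  if (length(unresolved)) {
    condition_stop(
      sprintf("offspring: female_id(s) %s do not resolve to a female record",
              paste(unresolved, collapse = ", ")),
      "lifetab_validation_error")
  }
  counts_ok <- off$n_eggs >= 0 & off$n_adults >= 0 & off$n_female_adults >= 0 &
    off$n_adults <= off$n_eggs & off$n_female_adults <= off$n_adults
  if (any(!counts_ok)) {
    condition_stop(
      sprintf("offspring for female %s: require n_female_adults <= n_adults <= n_eggs, all non-negative",
              paste(off$female_id[!counts_ok], collapse = ", ")),
      "lifetab_validation_error")
  }

  if (nrow(dev)) {
    if (any(!dev$outcome %in% c("emerged", "died"))) {
      condition_stop("dev: outcome must be 'emerged' or 'died'",
                     "lifetab_validation_error")
    }
    emerged <- dev$outcome == "emerged"
    if (any(emerged & (is.na(dev$dev_days) | dev$dev_days <= 0))) {
      condition_stop("dev: emerged individuals need positive dev_days",
                     "lifetab_validation_error")
    }
    if (any(!emerged & !is.na(dev$dev_days))) {
      condition_stop("dev: dev_days must be absent unless outcome = emerged",
                     "lifetab_validation_error")
    }
    if (any(emerged & !dev$sex %in% c("female", "male"))) {
      condition_stop("dev: emerged individuals need sex 'female' or 'male'",
                     "lifetab_validation_error")
    }
  }
  invisible(data)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cells <- cohort_groups(x)
  cat(sprintf("<cohort_dataset> %d females, %d offspring tallies, %d dev records, %d cell(s)\n",
              nrow(x$females), nrow(x$offspring), nrow(x$dev), nrow(cells)))
  invisible(x)
}

## ---- subsetting -----------------------------------------------------------

#' Restrict a cohort dataset to one treatment cell
#'
#' @param data A `cohort_dataset`.
#' @param group A `group_key`.
#' @param require_nonempty Error if the cell holds no females.
#' @return A `cohort_dataset` containing only records of that cell (the
#'   dev table is filtered by treatment and host).
#' @export
cohort_subset <- function(data, group, require_nonempty = TRUE) {
  stopifnot(inherits(data, "cohort_dataset"), inherits(group, "group_key"))
  keep <- data$females$treatment == group$treatment &
    data$females$host == group$host
  fem <- data$females[keep, , drop = FALSE]
  if (require_nonempty && nrow(fem) == 0L) {
    condition_stop(sprintf("no females in cell %s", format(group)),
                   "lifetab_analysis_error")
  }
  off <- data$offspring[data$offspring$female_id %in% fem$female_id, ,
                        drop = FALSE]
  dev <- data$dev[data$dev$treatment == group$treatment &
                    data$dev$host == group$host, , drop = FALSE]
  cohort_dataset(fem, off, dev, data$treatments, data$hosts, validate = FALSE)
}

## ---- I/O ------------------------------------------------------------------

#' Read a cohort dataset from its three CSV files
#'
#' Column dictionary (UTF-8, comma-delimited, header row required):
#' \describe{
#'   \item{females.csv}{`female_id`, `treatment`, `host`,
#'     `census_interval_days`, `longevity_days`, `oviposition_days`,
#'     `post_oviposition_days`, `census_eggs` (integer counts joined by
#'     `";"`, one per census interval).}
#'   \item{offspring.csv}{`female_id`, `n_eggs`, `n_adults`,
#'     `n_female_adults`.}
#'   \item{dev.csv}{`treatment`, `host`, `sex`, `outcome`, `dev_days`
#'     (empty unless `outcome = emerged`).}
#' }
#'
#' @param females_path,offspring_path,dev_path File paths, or a single
#'   directory in `females_path` holding `females.csv`, `offspring.csv`,
#'   `dev.csv`.
#' @param treatments,hosts Allowed label vocabularies.
#' @return A validated `cohort_dataset`.
#' @seealso [write_cohort()] for the inverse; the round trip is lossless.
#' @export
read_cohort <- function(females_path, offspring_path = NULL, dev_path = NULL,
                        treatments = .lifetab_treatments,
                        hosts = .lifetab_hosts) {
  if (is.null(offspring_path) && dir.exists(females_path)) {
    dir <- females_path
    females_path <- file.path(dir, "females.csv")
    offspring_path <- file.path(dir, "offspring.csv")
    dev_path <- file.path(dir, "dev.csv")
  }
  for (p in c(females_path, offspring_path, dev_path)) {
    if (!file.exists(p)) {
      condition_stop(sprintf("file not found: %s", p), "lifetab_schema_error")
    }
  }
  fem <- read.csv(females_path, stringsAsFactors = FALSE,
                  colClasses = c(female_id = "character"))
  check_schema(fem, "females")
  fem$census_eggs <- lapply(strsplit(as.character(fem$census_eggs), ";",
                                     fixed = TRUE),
                            function(s) as.integer(s))
  off <- read.csv(offspring_path, stringsAsFactors = FALSE,
                  colClasses = c(female_id = "character"))
  dev <- read.csv(dev_path, stringsAsFactors = FALSE)
  check_schema(off, "offspring")
  check_schema(dev, "dev")
  if (nrow(dev)) {
    dev$dev_days <- as.numeric(dev$dev_days)
    dev$sex <- as.character(dev$sex)
  }
  cohort_dataset(fem, off, dev, treatments, hosts)
}

#' Write a cohort dataset to three CSV files
#'
#' @param data A `cohort_dataset`.
#' @param dir Output directory (created if needed); writes `females.csv`,
#'   `offspring.csv`, `dev.csv` in the [read_cohort()] column dictionary.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(data, dir) {
  stopifnot(inherits(data, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fem <- data$females
  fem$census_eggs <- vapply(fem$census_eggs, paste, "", collapse = ";")
  write.csv(fem, file.path(dir, "females.csv"), row.names = FALSE)
  write.csv(data$offspring, file.path(dir, "offspring.csv"), row.names = FALSE)
  write.csv(data$dev, file.path(dir, "dev.csv"), row.names = FALSE)
  invisible(dir)
}

## ---- biological summary ---------------------------------------------------

mean_se <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  c(mean = mean(x), se = if (n > 1) sd(x) / sqrt(n) else NA_real_, n = n)
}

#' Summarize the biological traits of one treatment cell
#'
#' Per-female means with standard errors (SE = sample SD / sqrt(n)) for
#' total fecundity, daily fecundity (each female's total fecundity over
#' her longevity), longevity, oviposition and post-oviposition periods.
#' Offspring survival (egg to adult) and sex ratio (females among adults)
#' are reported two ways: as the mean of per-female ratios (the scale on
#' which trait comparisons are run) and as the pooled count ratio (the
#' scale on which life-table schedules are built); the two differ unless
#' all broods are equal. Development periods are summarized by sex and
#' combined over emerged individuals of the cell's subsample.
#'
#' @param data A `cohort_dataset`.
#' @param group A `group_key`.
#' @return An object of class `biology_summary` (a list of named
#'   `c(mean, se, n)` vectors plus pooled ratios and counts).
#' @export
summarize_biology <- function(data, group) {
  cell <- cohort_subset(data, group)
  fem <- cell$females
  if (nrow(fem) < 1L) {
    condition_stop(sprintf("empty cell %s", format(group)),
                   "lifetab_analysis_error")
  }
  totals <- vapply(fem$census_eggs, sum, 0)
  out <- list(
    group = group,
    n_females = nrow(fem),
    total_fecundity = mean_se(totals),
    daily_fecundity = mean_se(totals / fem$longevity_days),
    longevity = mean_se(fem$longevity_days),
    oviposition = mean_se(fem$oviposition_days),
    post_oviposition = mean_se(fem$post_oviposition_days))

  off <- cell$offspring
  if (nrow(off)) {
    surv_i <- ifelse(off$n_eggs > 0, off$n_adults / off$n_eggs, NA_real_)
    sr_i <- ifelse(off$n_adults > 0, off$n_female_adults / off$n_adults,
                   NA_real_)
    out$survival <- mean_se(surv_i)
    out$sex_ratio <- mean_se(sr_i)
    out$survival_pooled <- sum(off$n_adults) / sum(off$n_eggs)
    out$sex_ratio_pooled <- sum(off$n_female_adults) / sum(off$n_adults)
    out$counts <- c(eggs = sum(off$n_eggs), adults = sum(off$n_adults),
                    female_adults = sum(off$n_female_adults))
  }

  dev <- cell$dev[cell$dev$outcome == "emerged", , drop = FALSE]
  if (nrow(dev)) {
    out$dev_all <- mean_se(dev$dev_days)
    out$dev_female <- mean_se(dev$dev_days[dev$sex == "female"])
    out$dev_male <- mean_se(dev$dev_days[dev$sex == "male"])
  }
  structure(out, class = "biology_summary")
}

#' @export
print.biology_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<biology_summary> %s (n = %d females)\n", format(x$group),
              x$n_females))
  show <- function(lab, ms) {
    if (!is.null(ms)) {
      cat(sprintf("  %-18s %s +/- %s (n = %d)\n", lab,
                  format(ms[["mean"]], digits = digits),
                  format(ms[["se"]], digits = 2), as.integer(ms[["n"]])))
    }
  }
  show("total fecundity", x$total_fecundity)
  show("daily fecundity", x$daily_fecundity)
  show("longevity (d)", x$longevity)
  show("oviposition (d)", x$oviposition)
  show("post-ovip. (d)", x$post_oviposition)
  show("survival", x$survival)
  show("sex ratio", x$sex_ratio)
  if (!is.null(x$survival_pooled)) {
    cat(sprintf("  pooled: survival %.4f (%d/%d), sex ratio %.4f (%d/%d)\n",
                x$survival_pooled, x$counts[["adults"]], x$counts[["eggs"]],
                x$sex_ratio_pooled, x$counts[["female_adults"]],
                x$counts[["adults"]]))
  }
  show("dev (all, d)", x$dev_all)
  show("dev (female, d)", x$dev_female)
  show("dev (male, d)", x$dev_male)
  invisible(x)
}
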