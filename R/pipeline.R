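## End-to-end orchestration: simulate or ingest a study, then emit the
## standard report surfaces as CSV (biology summary; offspring survival
## and sex ratio; development periods; demographic parameters with
## jackknife SEs and Tukey letters) plus a plain-text run log. Output is
## a pure function of (input data, configuration, seed).

#' Pipeline run configuration
#'
#' Exactly one input source: either `input_dir` (three CSVs in the
#' [read_cohort()] schemas) or simulation from the calibrated presets.
#'
#' @param input_dir Directory of an existing study, or `NULL` to
#'   simulate.
#' @param seed Master seed (required when simulating; also recorded for
#'   provenance when reading).
#' @param out_dir Output directory for the report bundle.
#' @param cells data.frame (`treatment`, `host`) of cells to simulate
#'   (default: all eight published cells).
#' @param n_females Families per simulated cell.
#' @param step,age_convention,negg_convention Schedule options, see
#'   [build_life_schedule()].
#' @param alpha Significance level for letter displays.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, seed = 1L, out_dir = NULL,
                       cells = NULL, n_females = 30, step = 1,
                       age_convention = "spread",
                       negg_convention = "initial_females",
                       alpha = 0.05) {
  structure(list(input_dir = input_dir, seed = as.integer(seed),
                 out_dir = out_dir, cells = cells, n_females = n_females,
                 step = step, age_convention = age_convention,
                 negg_convention = negg_convention, alpha = alpha),
            class = "run_config")
}

pct <- function(x) 100 * x

#' Run the full life-table pipeline
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of data.frames (`biology`, `offspring`,
#'   `development`, `params`) plus the `log` lines; written as CSVs and
#'   `run.log` under `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(
    sprintf("lifetab run: %s", if (is.null(config$input_dir)) "simulated input"
            else paste("input dir", config$input_dir)),
    sprintf("seed = %d, step = %g, age_convention = %s, negg_convention = %s, alpha = %g",
            config$seed, config$step, config$age_convention,
            config$negg_convention, config$alpha))

  data <- if (is.null(config$input_dir)) {
    generate_study(config$seed, cells = config$cells,
                   n_females = config$n_females)
  } else {
    read_cohort(config$input_dir)
  }
  cells <- cohort_groups(data)
  log_lines <- c(log_lines,
                 sprintf("loaded %d females in %d cell(s)",
                         nrow(data$females), nrow(cells)))

  biology <- list(); offspring <- list(); development <- list()
  jack <- list()
  for (j in seq_len(nrow(cells))) {
    g <- group_key(cells$treatment[j], cells$host[j],
                   data$treatments, data$hosts)
    key <- format(g)
    s <- tryCatch(summarize_biology(data, g), lifetab_error = function(e) {
      condition_stop(sprintf("stage summarize_biology, cell %s: %s", key,
                             conditionMessage(e)), "lifetab_pipeline_error")
    })
    biology[[key]] <- data.frame(
      treatment = g$treatment, host = g$host, n = s$n_females,
      total_fecundity_mean = s$total_fecundity[["mean"]],
      total_fecundity_se = s$total_fecundity[["se"]],
      daily_fecundity_mean = s$daily_fecundity[["mean"]],
      daily_fecundity_se = s$daily_fecundity[["se"]],
      longevity_mean = s$longevity[["mean"]],
      longevity_se = s$longevity[["se"]],
      oviposition_mean = s$oviposition[["mean"]],
      oviposition_se = s$oviposition[["se"]],
      post_oviposition_mean = s$post_oviposition[["mean"]],
      post_oviposition_se = s$post_oviposition[["se"]])
    offspring[[key]] <- data.frame(
      treatment = g$treatment, host = g$host,
      survival_pct_mean = pct(s$survival[["mean"]]),
      survival_pct_se = pct(s$survival[["se"]]),
      survival_pooled_pct = pct(s$survival_pooled),
      sex_ratio_pct_mean = pct(s$sex_ratio[["mean"]]),
      sex_ratio_pct_se = pct(s$sex_ratio[["se"]]),
      sex_ratio_pooled_pct = pct(s$sex_ratio_pooled),
      n_eggs = s$counts[["eggs"]], n_adults = s$counts[["adults"]],
      n_female_adults = s$counts[["female_adults"]])
    development[[key]] <- data.frame(
      treatment = g$treatment, host = g$host,
      dev_all_mean = s$dev_all[["mean"]], dev_all_se = s$dev_all[["se"]],
      dev_all_n = s$dev_all[["n"]],
      dev_female_mean = s$dev_female[["mean"]],
      dev_female_se = s$dev_female[["se"]],
      dev_female_n = s$dev_female[["n"]],
      dev_male_mean = s$dev_male[["mean"]],
      dev_male_se = s$dev_male[["se"]], dev_male_n = s$dev_male[["n"]])
    jack[[key]] <- tryCatch(
      jackknife_lifetable(data, g, step = config$step,
                          age_convention = config$age_convention,
                          negg_convention = config$negg_convention),
      lifetab_error = function(e) {
        condition_stop(sprintf("stage jackknife, cell %s: %s", key,
                               conditionMessage(e)), "lifetab_pipeline_error")
      })
    log_lines <- c(log_lines, sprintf(
      "cell %s: n = %d, r = %.4f +/- %.4f", key, s$n_females,
      jack[[key]]$r$jk_mean, jack[[key]]$r$jk_se))
  }

  params <- do.call(rbind, lapply(names(jack), function(key) {
    jk <- jack[[key]]
    row <- data.frame(treatment = jk$group$treatment, host = jk$group$host)
    for (p in c("r", "lambda", "R0", "T")) {
      row[[paste0(p, "_mean")]] <- jk[[p]]$jk_mean
      row[[paste0(p, "_se")]] <- jk[[p]]$jk_se
      row[[paste0(p, "_letters")]] <- ""
    }
    row
  }))
  rownames(params) <- NULL

  # Tukey letters on pseudo-values: lower case within each host plant,
  # upper case across both hosts (when both scopes are comparable)
  for (p in c("r", "lambda", "R0", "T")) {
    col <- paste0(p, "_letters")
    for (h in unique(params$host)) {
      idx <- params$host == h
      if (sum(idx) < 2L) next
      sub <- jack[paste0(params$treatment[idx], "/", h)]
      cld <- compare_groups(sub, parameter = p, alpha = config$alpha)
      m <- match(paste0(params$treatment[idx], "/", h), cld$cell)
      params[[col]][idx] <- cld$letters[m]
    }
    if (nrow(params) >= 2L && length(unique(params$host)) > 1L) {
      cld <- compare_groups(jack, parameter = p, alpha = config$alpha)
      m <- match(paste0(params$treatment, "/", params$host), cld$cell)
      params[[col]] <- paste0(params[[col]], toupper(cld$letters[m]))
    }
  }

  bundle <- list(biology = do.call(rbind, c(biology, make.row.names = FALSE)),
                 offspring = do.call(rbind, c(offspring, make.row.names = FALSE)),
                 development = do.call(rbind, c(development, make.row.names = FALSE)),
                 params = params, jackknife = jack, log = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("biology", "offspring", "development", "params")) {
      write.csv(bundle[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  invisible(bundle)
}

## ---- trait-level values for ANOVA ----------------------------------------

#' Per-replicate trait values for group-level statistics
#'
#' Extracts one value per replicate (per female, or per individual for
#' development) together with its treatment and host factors, ready for
#' [two_way_anova()] / [tukey_hsd()]. Proportion traits are
#' arcsine-square-root transformed by default.
#'
#' @param data A `cohort_dataset`.
#' @param response One of `total_fecundity`, `daily_fecundity`,
#'   `longevity`, `oviposition`, `post_oviposition`, `survival`,
#'   `sex_ratio`, `dev_days`.
#' @param transform `"arcsine"` (proportions only) or `"none"`.
#' @return data.frame with `value`, `treatment`, `host`.
#' @export
trait_values <- function(data, response, transform = c("arcsine", "none")) {
  transform <- match.arg(transform)
  stopifnot(inherits(data, "cohort_dataset"))
  fem <- data$females
  if (response == "dev_days") {
    dev <- data$dev[data$dev$outcome == "emerged", , drop = FALSE]
    return(data.frame(value = dev$dev_days, treatment = dev$treatment,
                      host = dev$host))
  }
  if (response %in% c("survival", "sex_ratio")) {
    off <- data$offspring
    m <- match(off$female_id, fem$female_id)
    denom <- if (response == "survival") off$n_eggs else off$n_adults
    num <- if (response == "survival") off$n_adults else off$n_female_adults
    keep <- denom > 0
    p <- num[keep] / denom[keep]
    if (transform == "arcsine") p <- arcsine_sqrt(p)
    return(data.frame(value = p, treatment = fem$treatment[m][keep],
                      host = fem$host[m][keep]))
  }
  value <- switch(
    response,
    total_fecundity = vapply(fem$census_eggs, sum, 0),
    daily_fecundity = vapply(fem$census_eggs, sum, 0) / fem$longevity_days,
    longevity = fem$longevity_days,
    oviposition = fem$oviposition_days,
    post_oviposition = fem$post_oviposition_days,
    condition_stop(sprintf("unknown response '%s'", response),
                   "lifetab_validation_error"))
  data.frame(value = value, treatment = fem$treatment, host = fem$host)
}

## ---- command-line interface ----------------------------------------------

cli_opts <- function(args) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

opt_or <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else opts[[key]]
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `validate`, `schedule`, `demography`, `jackknife`,
#' `anova`, `run`. Outputs are CSVs plus a plain-text log. Examples:
#' \preformatted{
#' lifetab simulate --treatment C2 --host cucumber --seed 42 --out dir/
#' lifetab validate dir/
#' lifetab schedule dir/ --treatment C2 --host cucumber --out schedule.csv
#' lifetab demography schedule.csv
#' lifetab jackknife dir/ --out params.csv
#' lifetab anova dir/ --response total_fecundity --out anova.csv
#' lifetab run --seed 42 --out report/
#' }
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success, 1 on error).
#' @export
lifetab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      cat("usage: lifetab <simulate|validate|schedule|demography|jackknife|anova|run> [options]\n")
      return(invisible(1L))
    }
    verb <- args[1]
    opts <- cli_opts(args[-1])
    switch(
      verb,
      simulate = {
        seed <- as.integer(opt_or(opts, "seed", 1))
        out <- opt_or(opts, "out", ".")
        n <- as.integer(opt_or(opts, "n", 30))
        data <- if (isTRUE(opts$all) ||
                    (is.null(opts$treatment) && is.null(opts$host))) {
          generate_study(seed, n_females = n)
        } else {
          g <- group_key(opts$treatment, opts$host)
          generate_cohort(preset_params(g, n_females = n), seed = seed)
        }
        write_cohort(data, out)
        cat(sprintf("wrote %d females to %s\n", nrow(data$females), out))
      },
      validate = {
        data <- read_cohort(opts$positional[1])
        cat(sprintf("OK: %d females, %d offspring tallies, %d dev records\n",
                    nrow(data$females), nrow(data$offspring), nrow(data$dev)))
      },
      schedule = {
        data <- read_cohort(opts$positional[1])
        g <- group_key(opts$treatment, opts$host)
        sched <- build_life_schedule(
          data, g, step = as.numeric(opt_or(opts, "step", 1)),
          age_convention = opt_or(opts, "convention", "spread"),
          negg_convention = opt_or(opts, "negg", "initial_females"))
        out <- opt_or(opts, "out", "schedule.csv")
        write.csv(as.data.frame(sched), out, row.names = FALSE)
        cat(sprintf("wrote %d pivotal ages to %s\n", length(sched$x), out))
      },
      demography = {
        tab <- read.csv(opts$positional[1])
        sched <- life_schedule(tab$x, tab$lx, tab$mx)
        par <- demographic_params(sched)
        res <- data.frame(r = par$r, lambda = par$lambda, R0 = par$R0,
                          T = par$T, residual = par$residual)
        out <- opts$out
        if (!is.null(out)) write.csv(res, out, row.names = FALSE)
        print(par)
      },
      jackknife = {
        data <- read_cohort(opts$positional[1])
        cells <- cohort_groups(data)
        jk <- lapply(seq_len(nrow(cells)), function(j) {
          jackknife_lifetable(data, group_key(cells$treatment[j],
                                              cells$host[j]))
        })
        names(jk) <- paste0(cells$treatment, "/", cells$host)
        res <- do.call(rbind, lapply(names(jk), function(key) {
          x <- jk[[key]]
          data.frame(cell = key, r = x$r$jk_mean, r_se = x$r$jk_se,
                     lambda = x$lambda$jk_mean, lambda_se = x$lambda$jk_se,
                     R0 = x$R0$jk_mean, R0_se = x$R0$jk_se,
                     T = x$T$jk_mean, T_se = x$T$jk_se)
        }))
        out <- opt_or(opts, "out", "jackknife.csv")
        write.csv(res, out, row.names = FALSE)
        cat(sprintf("wrote %d cells to %s\n", nrow(res), out))
      },
      anova = {
        data <- read_cohort(opts$positional[1])
        response <- opt_or(opts, "response", "total_fecundity")
        tv <- trait_values(data, response)
        tab <- two_way_anova(tv$value, tv$treatment, tv$host,
                             term_names = c("cluster", "host"))
        out <- opts$out
        if (!is.null(out)) {
          write.csv(cbind(term = rownames(tab), as.data.frame(tab)), out,
                    row.names = FALSE)
        }
        print(tab)
      },
      run = {
        cfg <- run_config(
          input_dir = opts$input, seed = as.integer(opt_or(opts, "seed", 1)),
          out_dir = opt_or(opts, "out", "lifetab_report"),
          n_females = as.integer(opt_or(opts, "n", 30)))
        bundle <- run_pipeline(cfg)
        cat(sprintf("report bundle (%d cells) written to %s\n",
                    nrow(bundle$params), cfg$out_dir))
      },
      {
        cat(sprintf("unknown verb '%s'\n", verb))
        return(invisible(1L))
      })
    0L
  }, error = function(e) {
    cat("error:", conditionMessage(e), "\n")
    1L
  })
  invisible(status)
}
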