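#' Session plan
#'
#' The blocked design of one observer's session: every reference numerosity
#' is tested in both an isolated-dots and a connected-dots block, with a fixed
#' number of adaptive trials per block. The default plan (4 numerosities x
#' 2 conditions x 180 trials) totals 1440 trials per subject.
#'
#' @param reference_numerosities Reference numerosities (default
#'   `c(15, 25, 50, 100)`).
#' @param conditions Conditions tested (default
#'   `c("isolated", "connected")`).
#' @param trials_per_cell Trials per numerosity x condition block
#'   (default 180).
#' @param presentation_ms Stimulus duration in ms (metadata only,
#'   default 500).
#' @return A list of class `session_plan` with a `total_trials` field.
#' @export
session_plan <- function(reference_numerosities = c(15, 25, 50, 100),
                         conditions = c("isolated", "connected"),
                         trials_per_cell = 180,
                         presentation_ms = 500) {
  stopifnot(length(reference_numerosities) >= 1,
            all(reference_numerosities >= 2),
            all(conditions %in% c("isolated", "connected")),
            trials_per_cell >= 1)
  structure(list(
    reference_numerosities = as.integer(reference_numerosities),
    conditions = conditions,
    trials_per_cell = as.integer(trials_per_cell),
    presentation_ms = presentation_ms,
    total_trials = length(reference_numerosities) * length(conditions) *
      as.integer(trials_per_cell)
  ), class = "session_plan")
}

#' Full run configuration
#'
#' Bundles every moving part of a simulated experiment. With a fixed `seed`
#' the whole run (cohort, sessions, trial logs) is reproducible.
#'
#' @param cohort A [cohort_spec()].
#' @param plan A [session_plan()].
#' @param geometry A [geometry_config()].
#' @param perturbation A [perturbation_config()].
#' @param quest List of QUEST hyperparameters: `prior_sd_frac`, `sigma_frac`,
#'   `lapse`.
#' @param seed Integer master seed (default 1).
#' @param output_dir Output directory for trial logs, or `NULL` to keep the
#'   run in memory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       plan = session_plan(),
                       geometry = geometry_config(),
                       perturbation = perturbation_config(),
                       quest = list(prior_sd_frac = 0.4, sigma_frac = 0.25,
                                    lapse = 0.02),
                       seed = 1,
                       output_dir = NULL) {
  structure(list(
    cohort = cohort, plan = plan, geometry = geometry,
    perturbation = perturbation, quest = quest,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

.trial_schema <- c("subject_id", "aq", "block", "condition", "reference_n",
                   "probe_n", "reference_side", "chose_probe", "rt_s",
                   "rng_seed")

#' Run a full simulated experiment
#'
#' Samples the cohort, simulates every observer's adaptive session, and
#' (optionally) writes one trial-log CSV per subject plus a JSON manifest
#' recording the configuration hash, per-subject seeds and trial counts.
#' Partial outputs are removed if any stage fails.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `trials` (all subjects' records, one
#'   tibble), `cohort` (list of observers), `cohort_table`, `manifest`, and
#'   `paths` (NULL when `output_dir` is NULL).
#' @export
run_experiment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  cohort <- sample_cohort(cfg$cohort)
  subject_seeds <- sample.int(.Machine$integer.max, length(cohort))
  sessions <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sessions[[i]] <- simulate_session(
      cohort[[i]], plan = cfg$plan, pcfg = cfg$perturbation,
      quest_prior_sd_frac = cfg$quest$prior_sd_frac,
      quest_sigma_frac = cfg$quest$sigma_frac,
      quest_lapse = cfg$quest$lapse,
      seed = subject_seeds[i]
    )
  }
  trials <- do.call(rbind, sessions)
  ctab <- cohort_table(cohort)
  manifest <- list(
    config_hash = config_hash(cfg[c("cohort", "plan", "quest", "perturbation", "seed")]),
    seed = cfg$seed,
    subject_seeds = subject_seeds,
    n_subjects = length(cohort),
    trials_per_subject = cfg$plan$total_trials,
    reference_numerosities = cfg$plan$reference_numerosities,
    conditions = cfg$plan$conditions
  )
  paths <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    ok <- FALSE
    on.exit(if (!ok) unlink(written), add = TRUE)
    paths <- character(length(cohort))
    for (i in seq_along(cohort)) {
      paths[i] <- file.path(cfg$output_dir,
                            sprintf("trials_%s.csv", cohort[[i]]$id))
      utils::write.csv(sessions[[i]], paths[i], row.names = FALSE)
      written <- c(written, paths[i])
    }
    aq_path <- file.path(cfg$output_dir, "cohort.csv")
    utils::write.csv(ctab, aq_path, row.names = FALSE)
    written <- c(written, aq_path)
    man_path <- file.path(cfg$output_dir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, man_path)
    paths <- c(paths, aq_path, man_path)
    ok <- TRUE
  }
  invisible(list(trials = trials, cohort = cohort, cohort_table = ctab,
                 manifest = manifest, paths = paths))
}

#' Read trial logs written by [run_experiment()]
#'
#' @param dir Directory containing `trials_*.csv` files.
#' @return One tibble of all subjects' trials.
#' @export
read_trial_logs <- function(dir) {
  files <- list.files(dir, pattern = "^trials_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no trial logs found in ", dir)
  tibble::as_tibble(do.call(rbind, lapply(files, function(f) {
    utils::read.csv(f, stringsAsFactors = FALSE)
  })))
}

.check_trial_schema <- function(trials) {
  missing <- setdiff(.trial_schema, names(trials))
  if (length(missing) > 0) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(trials$probe_n) || !is.numeric(trials$reference_n)) {
    stop("columns probe_n and reference_n must be numeric")
  }
  if (is.character(trials$chose_probe)) {
    trials$chose_probe <- as.logical(trials$chose_probe)
  }
  if (anyNA(trials$chose_probe)) stop("column chose_probe has missing values")
  trials
}

#' Per-subject psychometric analysis of trial logs
#'
#' Applies reaction-time trimming per subject across the whole session, then
#' fits one cumulative-Gaussian psychometric function per subject x condition
#' x reference numerosity.
#'
#' @param trials Trial tibble conforming to the trial-log schema, or a
#'   directory of trial logs.
#' @param lapse Fixed lapse rate in the fits (default 0).
#' @return A tibble of fits (one row per subject x condition x numerosity)
#'   with columns `subject_id`, `aq`, `condition`, `reference_n`, `pse`,
#'   `sigma`, `jnd`, `wf`, `bias_pct`, `n_trials_used`, `converged`. The
#'   attribute `removed_fraction` records the RT-trim rate.
#' @export
analyze_trials <- function(trials, lapse = 0) {
  if (is.character(trials) && length(trials) == 1) {
    trials <- read_trial_logs(trials)
  }
  trials <- .check_trial_schema(trials)
  trimmed <- trim_rt(trials)
  kept <- trimmed$kept
  cells <- unique(kept[, c("subject_id", "aq", "condition", "reference_n")])
  cells <- cells[order(cells$subject_id, cells$condition, cells$reference_n), ]
  fits <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- kept$subject_id == cells$subject_id[i] &
      kept$condition == cells$condition[i] &
      kept$reference_n == cells$reference_n[i]
    fit <- fit_psychometric(kept[sel, ], reference_n = cells$reference_n[i],
                            lapse = lapse)
    tibble::tibble(
      subject_id = cells$subject_id[i], aq = cells$aq[i],
      condition = cells$condition[i], reference_n = cells$reference_n[i],
      pse = fit$pse, sigma = fit$sigma, jnd = fit$jnd, wf = fit$wf,
      bias_pct = fit$bias_pct, n_trials_used = fit$n_trials_used,
      converged = fit$converged
    )
  })
  out <- do.call(rbind, fits)
  attr(out, "removed_fraction") <- trimmed$removed_fraction
  out
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Group-level statistics report
#'
#' Reproduces the group analysis of the connectedness-bias paradigm from a
#' fits table: per-subject mean connected bias in the low-numerosity regime
#' (default N 15-50) and in the high regime (N = 100); AQ median split;
#' bias-vs-AQ Pearson correlations with Bayes factors per regime; pooled t
#' tests with JZS Bayes factors comparing the AQ groups; a two-way
#' repeated-measures ANOVA on bias (numerosity x condition); baseline
#' (isolated) bias checks; and the Weber-fraction comparison between groups
#' and conditions.
#'
#' @param fits Fits tibble from [analyze_trials()].
#' @param low_regime Numerosities of the low regime (default
#'   `c(15, 25, 50)`).
#' @param high_regime Numerosities of the high regime (default `100`).
#' @return A list of class `numbias_report`; see [write_report_json()].
#' @export
report_stats <- function(fits, low_regime = c(15, 25, 50), high_regime = 100) {
  need <- c("subject_id", "aq", "condition", "reference_n", "bias_pct", "wf")
  missing <- setdiff(need, names(fits))
  if (length(missing) > 0) {
    stop("fits table is missing column(s): ", paste(missing, collapse = ", "))
  }
  subs <- unique(fits$subject_id)
  per_subject <- do.call(rbind, lapply(subs, function(s) {
    f <- fits[fits$subject_id == s, ]
    conn <- f[f$condition == "connected", ]
    iso <- f[f$condition == "isolated", ]
    tibble::tibble(
      subject_id = s,
      aq = f$aq[1],
      bias_low = mean(conn$bias_pct[conn$reference_n %in% low_regime]),
      bias_high = mean(conn$bias_pct[conn$reference_n %in% high_regime]),
      bias_baseline = mean(iso$bias_pct),
      wf_mean = mean(f$wf),
      wf_isolated = mean(iso$wf),
      wf_connected = mean(conn$wf)
    )
  }))
  if (anyNA(per_subject$bias_low) || anyNA(per_subject$bias_high)) {
    stop("missing connected-condition cells for some subjects")
  }
  split <- median_split(per_subject$aq, per_subject$subject_id)
  low_g <- per_subject$subject_id %in% split$low_ids
  regime_stats <- function(bias) {
    ct <- pearson_r(per_subject$aq, bias)
    bf_r <- if (abs(ct$r) >= 1 - 1e-9) {
      warning("correlation is degenerate (|r| = 1); Bayes factor is infinite")
      list(log10_bf10 = Inf)
    } else {
      bf_pearson(ct$r, ct$n)
    }
    tt <- two_sample_t(bias[low_g], bias[!low_g])
    bf_t <- bf_ttest_jzs(tt$t, sum(low_g), sum(!low_g))
    list(
      group_means = list(
        low_aq = list(mean = mean(bias[low_g]), sem = .sem(bias[low_g]),
                      n = sum(low_g)),
        high_aq = list(mean = mean(bias[!low_g]), sem = .sem(bias[!low_g]),
                       n = sum(!low_g))
      ),
      correlation = list(r = ct$r, p = ct$p, n = ct$n,
                         log10_bf = bf_r$log10_bf10),
      group_test = list(t = tt$t, df = tt$df, p = tt$p,
                        log10_bf = bf_t$log10_bf10)
    )
  }
  wf_tt <- two_sample_t(per_subject$wf_mean[low_g], per_subject$wf_mean[!low_g])
  wf_bf <- bf_ttest_jzs(wf_tt$t, sum(low_g), sum(!low_g))
  anova_tab <- rm_anova_2way(data.frame(
    subject = fits$subject_id, A = fits$reference_n, B = fits$condition,
    value = fits$bias_pct
  ))
  base_t <- tryCatch(stats::t.test(per_subject$bias_baseline),
                     error = function(e) NULL)
  fig3a <- stats::aggregate(
    bias_pct ~ reference_n + condition,
    data = transform(as.data.frame(fits),
                     group = ifelse(fits$subject_id %in% split$low_ids,
                                    "low_aq", "high_aq")),
    FUN = mean
  )
  fig3a_g <- stats::aggregate(
    bias_pct ~ reference_n + condition + group,
    data = transform(as.data.frame(fits),
                     group = ifelse(fits$subject_id %in% split$low_ids,
                                    "low_aq", "high_aq")),
    FUN = mean
  )
  wf_table <- stats::aggregate(
    wf ~ condition + group,
    data = transform(as.data.frame(fits),
                     group = ifelse(fits$subject_id %in% split$low_ids,
                                    "low_aq", "high_aq")),
    FUN = mean
  )
  out <- list(
    n_subjects = length(subs),
    split = list(threshold = split$threshold,
                 n_low = length(split$low_ids), n_high = length(split$high_ids)),
    low_regime = regime_stats(per_subject$bias_low),
    high_regime = regime_stats(per_subject$bias_high),
    baseline = list(
      mean_bias_pct = mean(per_subject$bias_baseline),
      sem = .sem(per_subject$bias_baseline),
      t = if (is.null(base_t)) NA else unname(base_t$statistic),
      p = if (is.null(base_t)) NA else base_t$p.value
    ),
    weber = list(
      low_aq_mean = mean(per_subject$wf_mean[low_g]),
      high_aq_mean = mean(per_subject$wf_mean[!low_g]),
      t = wf_tt$t, df = wf_tt$df, p = wf_tt$p, log10_bf = wf_bf$log10_bf10
    ),
    anova_bias = as.data.frame(anova_tab),
    tables = list(
      per_subject = as.data.frame(per_subject),
      bias_by_numerosity = fig3a,
      bias_by_numerosity_group = fig3a_g,
      wf_by_condition_group = wf_table
    )
  )
  class(out) <- "numbias_report"
  out
}

#' @export
print.numbias_report <- function(x, ...) {
  cat(sprintf("Connectedness-bias report: %d subjects (AQ split at %g: %d low / %d high)\n",
              x$n_subjects, x$split$threshold, x$split$n_low, x$split$n_high))
  lr <- x$low_regime
  cat(sprintf("Low numerosities: bias %.1f%% (low AQ) vs %.1f%% (high AQ); t(%d) = %.2f, p = %.3g, logBF = %.2f\n",
              lr$group_means$low_aq$mean, lr$group_means$high_aq$mean,
              lr$group_test$df, lr$group_test$t, lr$group_test$p,
              lr$group_test$log10_bf))
  cat(sprintf("  bias-AQ correlation: r = %.2f, p = %.3g, logBF = %.2f\n",
              lr$correlation$r, lr$correlation$p, lr$correlation$log10_bf))
  hr <- x$high_regime
  cat(sprintf("N = 100: bias %.1f%% vs %.1f%%; t(%d) = %.2f, p = %.3g, logBF = %.2f; r = %.2f, logBF = %.2f\n",
              hr$group_means$low_aq$mean, hr$group_means$high_aq$mean,
              hr$group_test$df, hr$group_test$t, hr$group_test$p,
              hr$group_test$log10_bf, hr$correlation$r, hr$correlation$log10_bf))
  cat(sprintf("Baseline bias: %.2f%% +/- %.2f%% (p = %.3g)\n",
              x$baseline$mean_bias_pct, x$baseline$sem, x$baseline$p))
  cat(sprintf("Weber fractions: %.3f (low AQ) vs %.3f (high AQ); t(%d) = %.2f, logBF = %.2f\n",
              x$weber$low_aq_mean, x$weber$high_aq_mean, x$weber$df,
              x$weber$t, x$weber$log10_bf))
  invisible(x)
}

#' Write a statistics report to JSON
#'
#' @param report A `numbias_report` from [report_stats()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read/write configurations as YAML
#'
#' Round-trips [run_config()]-style lists through YAML files.
#'
#' @param cfg A configuration list.
#' @param path File path.
#' @return `write_config_yaml`: the path invisibly; `read_config_yaml`: the
#'   configuration list.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}
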