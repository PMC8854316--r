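#' Trim trials by reaction time
#'
#' Removes anticipatory or over-late responses: per subject, trials whose
#' reaction time falls outside mean +/- 2 SD of that subject's reaction times
#' are discarded. Mean and SD are computed once over all the subject's trials
#' (a single pass, no iteration). If a subject's reaction times have zero
#' spread nothing is removed.
#'
#' @param trials A trial tibble/data.frame with at least `subject_id` and
#'   `rt_s` columns (>= 3 trials per subject).
#' @param n_sd Trim threshold in SD units (default 2).
#' @return A list with `kept` and `removed` subsets (same columns as input)
#'   and `removed_fraction`.
#' @export
trim_rt <- function(trials, n_sd = 2) {
  stopifnot(all(c("subject_id", "rt_s") %in% names(trials)))
  counts <- table(trials$subject_id)
  if (any(counts < 3)) {
    stop("each subject needs at least 3 trials to estimate the trim window")
  }
  keep <- rep(TRUE, nrow(trials))
  for (s in names(counts)) {
    idx <- which(trials$subject_id == s)
    m <- mean(trials$rt_s[idx])
    sdv <- stats::sd(trials$rt_s[idx])
    if (sdv > 0) {
      keep[idx] <- abs(trials$rt_s[idx] - m) <= n_sd * sdv
    }
  }
  list(
    kept = trials[keep, , drop = FALSE],
    removed = trials[!keep, , drop = FALSE],
    removed_fraction = mean(!keep)
  )
}

.nll_cumgauss <- function(par, x, y, lapse) {
  pse <- par[1]
  sigma <- exp(par[2])
  p <- lapse / 2 + (1 - lapse) * stats::pnorm((x - pse) / sigma)
  p <- pmin(1 - 1e-9, pmax(1e-9, p))
  -sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Fit a cumulative-Gaussian psychometric function to 2AFC trials
#'
#' Maximum-likelihood Bernoulli fit of
#' `P(chose probe | probe = x) = pnorm((x - pse) / sigma)` in linear
#' numerosity (no lapse by default). The median of the fitted function is the
#' PSE; the JND is the numerosity difference between the 50% and 75% points,
#' `sigma * qnorm(0.75)`; the Weber fraction is JND divided by the perceived
#' numerosity (the PSE); the percent bias is
#' `100 * (pse - reference_n) / reference_n`.
#'
#' Optimization is bounded quasi-Newton (L-BFGS-B) on `(pse, log sigma)` with
#' three starting points; the best of the converged starts is returned.
#'
#' @param trials Trial tibble with `probe_n` and `chose_probe` columns (and
#'   `reference_n` if `reference_n` is not given).
#' @param reference_n Reference numerosity; defaults to the unique
#'   `reference_n` of `trials`.
#' @param lapse Fixed lapse rate used in the likelihood (default 0).
#' @return A one-row tibble of class `psychometric_fit` with columns `pse`,
#'   `sigma`, `jnd`, `wf`, `bias_pct`, `n_trials_used`, `converged`,
#'   `loglik`, `reference_n`.
#' @export
fit_psychometric <- function(trials, reference_n = NULL, lapse = 0) {
  stopifnot(all(c("probe_n", "chose_probe") %in% names(trials)))
  if (is.null(reference_n)) {
    reference_n <- unique(trials$reference_n)
    if (length(reference_n) != 1) {
      stop("trials span several reference numerosities; pass reference_n")
    }
  }
  x <- as.numeric(trials$probe_n)
  y <- as.numeric(trials$chose_probe)
  if (length(unique(x)) < 2) {
    stop("need at least 2 distinct probe levels to fit a psychometric function")
  }
  if (all(y == 1) || all(y == 0)) {
    stop("degenerate data: all responses identical; PSE is not estimable")
  }
  rng <- diff(range(x))
  lower <- c(min(x) - 2 * rng, log(1e-3))
  upper <- c(max(x) + 2 * rng, log(10 * max(rng, 1)))
  starts <- list(
    c(stats::median(x), log(max(rng / 4, 0.1))),
    c(mean(x), log(max(stats::sd(x), 0.1))),
    c(reference_n, log(max(0.25 * reference_n, 0.1)))
  )
  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    st <- pmin(upper, pmax(lower, st))
    fit <- tryCatch(
      stats::optim(st, .nll_cumgauss, x = x, y = y, lapse = lapse,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed from every starting point")
  if (!any_conv) {
    warning("psychometric fit did not converge; estimates may be unreliable")
  }
  pse <- best$par[1]
  sigma <- exp(best$par[2])
  jnd <- sigma * stats::qnorm(0.75)
  out <- tibble::tibble(
    pse = pse,
    sigma = sigma,
    jnd = jnd,
    wf = jnd / pse,
    bias_pct = bias_percent(pse, reference_n),
    n_trials_used = length(y),
    converged = any_conv,
    loglik = -best$value,
    reference_n = reference_n
  )
  class(out) <- c("psychometric_fit", class(out))
  out
}

#' Percent bias of a PSE relative to the reference numerosity
#'
#' `100 * (pse - reference_n) / reference_n`; negative values mean the
#' reference appeared less numerous than it was (the probe matched it at a
#' numerosity below the physical reference).
#'
#' @param pse Fitted point of subjective equality.
#' @param reference_n Reference numerosity (> 0).
#' @return Percent bias (numeric).
#' @export
bias_percent <- function(pse, reference_n) {
  stopifnot(reference_n > 0)
  100 * (pse - reference_n) / reference_n
}

#' Pooled psychometric function across subjects
#'
#' Pools trials from one or more subjects sharing a reference numerosity and
#' condition, fits them as one psychometric function, and tabulates the
#' proportion of probe-more-numerous responses per probe level for plotting.
#'
#' @param trials Trial tibble (single condition and reference).
#' @param reference_n Reference numerosity (defaults as in
#'   [fit_psychometric()]).
#' @param lapse Fixed lapse rate (default 0).
#' @return List with `fit` (a `psychometric_fit`) and `curve` (tibble with
#'   `probe_n`, `prop_chose_probe`, `n_trials`).
#' @export
aggregate_curve <- function(trials, reference_n = NULL, lapse = 0) {
  fit <- fit_psychometric(trials, reference_n = reference_n, lapse = lapse)
  agg <- stats::aggregate(
    chose_probe ~ probe_n, data = as.data.frame(trials),
    FUN = function(v) c(mean(v), length(v))
  )
  curve <- tibble::tibble(
    probe_n = agg$probe_n,
    prop_chose_probe = agg$chose_probe[, 1],
    n_trials = as.integer(agg$chose_probe[, 2])
  )
  list(fit = fit, curve = curve[order(curve$probe_n), ])
}
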