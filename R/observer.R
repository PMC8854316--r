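#' Score an autism-spectrum quotient (AQ) answer sheet
#'
#' Standard 50-item scoring: each item scores 1 when the response is in the
#' keyed (ASD-characteristic) direction, whether endorsed slightly or
#' strongly, and 0 otherwise. Totals range 0-50.
#'
#' @param responses Character vector of exactly 50 responses, each one of
#'   `"strongly agree"`, `"slightly agree"`, `"slightly disagree"`,
#'   `"strongly disagree"`.
#' @param key Character vector of 50 keyed directions, each `"agree"` or
#'   `"disagree"`: the direction that scores 1 for that item.
#' @return Integer total score in `[0, 50]`.
#' @export
score_aq <- function(responses, key) {
  levels_ok <- c("strongly agree", "slightly agree",
                 "slightly disagree", "strongly disagree")
  if (length(responses) != 50) {
    stop("an AQ sheet has exactly 50 responses, got ", length(responses))
  }
  if (length(key) != 50 || !all(key %in% c("agree", "disagree"))) {
    stop("key must be 50 values of 'agree' or 'disagree'")
  }
  if (!all(responses %in% levels_ok)) {
    stop("invalid response level(s): ",
         paste(unique(setdiff(responses, levels_ok)), collapse = ", "))
  }
  agreed <- responses %in% c("strongly agree", "slightly agree")
  sum(agreed == (key == "agree"))
}

#' Specification of a synthetic observer cohort
#'
#' Defines the joint distribution of AQ scores, connectedness-induced
#' underestimation biases, Weber fractions and reaction-time parameters for a
#' simulated cohort. AQ scores are drawn from a normal distribution truncated
#' to `[0, 50]` and rounded to integers. Each observer's underestimation of
#' connected patterns is a linear function of the AQ score,
#' `bias = intercept + slope * AQ` (slope negative: higher autistic-like
#' traits, weaker grouping, smaller illusion), clipped to `[0, 0.6]`, with
#' separate lines for the low-numerosity regime (N <= 50) and the
#' high-numerosity regime (N = 100). Weber fractions are matched across the
#' AQ range (lognormal scatter around `weber_mean`).
#'
#' The default intercepts and slopes are calibrated so that, under the default
#' AQ distribution split at 15, the group mean biases are approximately
#' 27% / 13% (low/high AQ) in the low-numerosity regime and 11% / 8% at
#' N = 100.
#'
#' @param n_subjects Number of observers (default 21).
#' @param aq_centre,aq_spread Mean and SD of the truncated-normal AQ
#'   distribution (defaults 15 and 11).
#' @param bias_intercept_low,bias_slope_low Bias line for N <= 50
#'   (proportion and proportion per AQ point).
#' @param bias_intercept_high,bias_slope_high Bias line for N = 100.
#' @param weber_mean Mean Weber fraction (default 0.25).
#' @param weber_cv Lognormal coefficient of variation of observer Weber
#'   fractions (default 0.12).
#' @param lapse Lapse rate of every observer (default 0.02).
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters in log
#'   seconds (defaults log(0.7) and 0.4).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21,
                        aq_centre = 15,
                        aq_spread = 11,
                        bias_intercept_low = 0.3466,
                        bias_slope_low = -0.00925,
                        bias_intercept_high = 0.1264,
                        bias_slope_high = -0.00198,
                        weber_mean = 0.25,
                        weber_cv = 0.12,
                        lapse = 0.02,
                        rt_meanlog = log(0.7),
                        rt_sdlog = 0.4) {
  stopifnot(n_subjects >= 2, aq_spread > 0, weber_mean > 0, weber_cv >= 0,
            lapse >= 0, lapse < 0.5, rt_sdlog > 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    aq_centre = aq_centre, aq_spread = aq_spread,
    bias_intercept_low = bias_intercept_low, bias_slope_low = bias_slope_low,
    bias_intercept_high = bias_intercept_high, bias_slope_high = bias_slope_high,
    weber_mean = weber_mean, weber_cv = weber_cv,
    lapse = lapse, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog
  ), class = "cohort_spec")
}

.rtrunc_aq <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(50, mu, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mu, sd)
  pmin(50L, pmax(0L, as.integer(round(x))))
}

#' Draw a synthetic observer cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of `observer_model` objects, each with fields `id`, `aq`,
#'   `bias_low`, `bias_high`, `weber`, `lapse`, `rt_meanlog`, `rt_sdlog`.
#'   Use [cohort_table()] for a tabular view.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  aq <- .rtrunc_aq(spec$n_subjects, spec$aq_centre, spec$aq_spread)
  clip <- function(x) pmin(0.6, pmax(0, x))
  weber <- spec$weber_mean * exp(stats::rnorm(spec$n_subjects, 0, spec$weber_cv))
  lapply(seq_len(spec$n_subjects), function(i) {
    obs <- list(
      id = sprintf("S%02d", i),
      aq = aq[i],
      bias_low = clip(spec$bias_intercept_low + spec$bias_slope_low * aq[i]),
      bias_high = clip(spec$bias_intercept_high + spec$bias_slope_high * aq[i]),
      weber = weber[i],
      lapse = spec$lapse,
      rt_meanlog = spec$rt_meanlog,
      rt_sdlog = spec$rt_sdlog
    )
    class(obs) <- "observer_model"
    obs
  })
}

#' Tabulate a cohort
#'
#' @param cohort A list of `observer_model`s from [sample_cohort()].
#' @return A tibble with one row per observer.
#' @export
cohort_table <- function(cohort) {
  tibble::tibble(
    subject_id = vapply(cohort, `[[`, "", "id"),
    aq = vapply(cohort, `[[`, 0L, "aq"),
    bias_low = vapply(cohort, `[[`, 0, "bias_low"),
    bias_high = vapply(cohort, `[[`, 0, "bias_high"),
    weber = vapply(cohort, `[[`, 0, "weber"),
    lapse = vapply(cohort, `[[`, 0, "lapse")
  )
}

#' Perceived numerosity of a stimulus for a synthetic observer
#'
#' Isolated patterns are perceived veridically. Connected patterns are
#' underestimated by the observer's bias: `n * (1 - b(n))`, where `b(n)` is
#' `bias_low` for n <= 50 and `bias_high` above (a two-level step, matching
#' the low/high numerosity regimes analysed in this paradigm).
#'
#' @param obs An `observer_model`.
#' @param n Physical numerosity (>= 1).
#' @param condition `"isolated"` or `"connected"`.
#' @return Perceived numerosity (real).
#' @export
perceived_numerosity <- function(obs, n, condition = c("isolated", "connected")) {
  condition <- match.arg(condition)
  stopifnot(n >= 1)
  if (condition == "isolated") return(as.numeric(n))
  b <- if (n <= 50) obs$bias_low else obs$bias_high
  n * (1 - b)
}

#' Simulate one 2AFC response
#'
#' The observer chooses the probe with probability
#' `lapse/2 + (1 - lapse) * pnorm((probe - ref_perceived) / (weber * ref_perceived))`
#' (Weber-scaled decision noise around the perceived reference), and produces
#' a lognormal reaction time.
#'
#' @param obs An `observer_model`.
#' @param probe Probe numerosity (>= 1).
#' @param ref_perceived Perceived numerosity of the reference (> 0).
#' @return List with `chose_probe` (logical) and `rt` (seconds).
#' @export
simulate_response <- function(obs, probe, ref_perceived) {
  stopifnot(probe >= 1, ref_perceived > 0)
  p <- obs$lapse / 2 + (1 - obs$lapse) *
    stats::pnorm((probe - ref_perceived) / (obs$weber * ref_perceived))
  list(
    chose_probe = stats::runif(1) < p,
    rt = stats::rlnorm(1, obs$rt_meanlog, obs$rt_sdlog)
  )
}

#' Simulate a full adaptive 2AFC session for one observer
#'
#' Runs one QUEST-driven block per (reference numerosity x condition) cell of
#' the session plan. QUEST is reinitialized at the start of every block with
#' prior mean at the reference numerosity; each trial's probe is the
#' perturbed, rounded running PSE estimate, the observer's response feeds the
#' posterior update, and the reference side is randomized left/right.
#'
#' @param obs An `observer_model`.
#' @param plan A [session_plan()].
#' @param pcfg A [perturbation_config()].
#' @param quest_prior_sd_frac Prior SD as a fraction of the reference
#'   numerosity (default 0.4).
#' @param quest_sigma_frac QUEST's assumed psychometric slope as a fraction of
#'   the reference numerosity (default 0.25, i.e. an assumed Weber fraction of
#'   about 0.25).
#' @param quest_lapse Assumed lapse rate inside QUEST (default 0.02).
#' @param geometry Optional [geometry_config()]; when supplied with
#'   `generate_stimuli = TRUE`, a reference dot pattern is generated for every
#'   trial (isolated or connected as the block requires), exercising the full
#'   stimulus pipeline. Responses depend only on numerosities, so stimulus
#'   generation is off by default for speed.
#' @param generate_stimuli Logical (default `FALSE`).
#' @param seed Optional integer seed for reproducibility of the whole session.
#' @return A tibble of trial records with columns `subject_id`, `aq`, `block`,
#'   `condition`, `reference_n`, `probe_n`, `reference_side`, `chose_probe`,
#'   `rt_s`, `rng_seed`.
#' @export
simulate_session <- function(obs, plan = session_plan(),
                             pcfg = perturbation_config(),
                             quest_prior_sd_frac = 0.4,
                             quest_sigma_frac = 0.25,
                             quest_lapse = 0.02,
                             geometry = NULL,
                             generate_stimuli = FALSE,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (generate_stimuli && is.null(geometry)) geometry <- geometry_config()
  cells <- expand.grid(
    condition = plan$conditions,
    reference_n = plan$reference_numerosities,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  ntr <- plan$trials_per_cell
  total <- nrow(cells) * ntr
  probe_n <- integer(total)
  chose <- logical(total)
  rt <- numeric(total)
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    ref <- cells$reference_n[ci]
    condition <- cells$condition[ci]
    ref_perc <- perceived_numerosity(obs, ref, condition)
    state <- quest_init(
      prior_mean = ref,
      prior_sd = quest_prior_sd_frac * ref,
      slope_sigma = quest_sigma_frac * ref,
      lapse = quest_lapse
    )
    for (tr in seq_len(ntr)) {
      probe <- next_probe(state, pcfg)
      if (generate_stimuli) {
        if (condition == "connected") place_connected(ref, geometry) else place_isolated(ref, geometry)
        place_isolated(probe, geometry) # the probe is always isolated dots
      }
      resp <- simulate_response(obs, probe, ref_perc)
      state <- quest_update(state, probe, resp$chose_probe)
      row <- row + 1L
      probe_n[row] <- probe
      chose[row] <- resp$chose_probe
      rt[row] <- resp$rt
    }
  }
  tibble::tibble(
    subject_id = obs$id,
    aq = obs$aq,
    block = rep(seq_len(nrow(cells)), each = ntr),
    condition = rep(cells$condition, each = ntr),
    reference_n = rep(cells$reference_n, each = ntr),
    probe_n = probe_n,
    reference_side = sample(c("left", "right"), total, replace = TRUE),
    chose_probe = chose,
    rt_s = rt,
    rng_seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}
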