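#' Initialize a QUEST state
#'
#' Discretized-posterior QUEST for tracking the point of subjective equality
#' (PSE) of a 2AFC numerosity comparison. The posterior over candidate PSE
#' values starts as a (grid-truncated) Gaussian prior. The engine assumes a
#' cumulative-Gaussian psychometric function in linear numerosity with a
#' symmetric lapse rate: at candidate PSE `m`, the probability of choosing
#' the probe at numerosity `x` is
#' `lapse + (1 - 2 * lapse) * pnorm((x - m) / slope_sigma)`
#' (criterion level 0.5: PSE-mode QUEST with guess rate 0).
#'
#' @param prior_mean Prior mean of the PSE, in numerosity units.
#' @param prior_sd Prior SD of the PSE (> 0).
#' @param slope_sigma Assumed Gaussian SD (slope) of the psychometric
#'   function, in numerosity units.
#' @param lapse Assumed lapse rate in `[0, 0.5)` (default 0.02).
#' @param grid_lo,grid_hi Grid limits; default `prior_mean - 4 * prior_sd`
#'   (floored at 1) and `prior_mean + 4 * prior_sd`.
#' @param grid_n Number of grid points (default 201).
#' @return A list of class `quest_state` with elements `grid`, `log_posterior`
#'   (normalized), `slope_sigma`, `lapse`, `response_count`.
#' @export
quest_init <- function(prior_mean, prior_sd, slope_sigma,
                       lapse = 0.02,
                       grid_lo = max(1, prior_mean - 4 * prior_sd),
                       grid_hi = prior_mean + 4 * prior_sd,
                       grid_n = 201) {
  stopifnot(prior_sd > 0, slope_sigma > 0, lapse >= 0, lapse < 0.5,
            grid_hi > grid_lo, grid_n >= 2)
  grid <- seq(grid_lo, grid_hi, length.out = grid_n)
  lp <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  lp <- lp - .logsumexp(lp)
  state <- list(
    grid = grid,
    log_posterior = lp,
    slope_sigma = slope_sigma,
    lapse = lapse,
    response_count = 0L
  )
  class(state) <- "quest_state"
  state
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Posterior mean and SD of a QUEST state
#'
#' @param state A `quest_state`.
#' @return `quest_mean`: the posterior mean PSE; `quest_sd`: the posterior SD.
#' @export
quest_mean <- function(state) {
  w <- exp(state$log_posterior)
  sum(w * state$grid)
}

#' @rdname quest_mean
#' @export
quest_sd <- function(state) {
  w <- exp(state$log_posterior)
  m <- sum(w * state$grid)
  sqrt(sum(w * (state$grid - m)^2))
}

#' Update the QUEST posterior with one trial's response
#'
#' Adds the log-likelihood of the observed response under the assumed
#' psychometric function centred at each grid value, then renormalizes.
#'
#' @param state A `quest_state`.
#' @param probe Probe numerosity shown on the trial. Values outside the grid
#'   range are clamped with a warning.
#' @param chose_probe Logical: did the observer report the probe as more
#'   numerous?
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, probe, chose_probe) {
  stopifnot(inherits(state, "quest_state"), is.logical(chose_probe))
  rng <- range(state$grid)
  if (probe < rng[1] || probe > rng[2]) {
    warning(sprintf("probe %.3g outside QUEST grid [%.3g, %.3g]; clamped",
                    probe, rng[1], rng[2]))
    probe <- min(max(probe, rng[1]), rng[2])
  }
  p <- state$lapse + (1 - 2 * state$lapse) *
    stats::pnorm((probe - state$grid) / state$slope_sigma)
  ll <- if (chose_probe) log(p) else log1p(-p)
  lp <- state$log_posterior + ll
  state$log_posterior <- lp - .logsumexp(lp)
  state$response_count <- state$response_count + 1L
  state
}

#' Probe-perturbation configuration
#'
#' After each trial the running PSE estimate is perturbed by Gaussian noise
#' (default SD 0.5 dots) so that probes span a small range around the PSE,
#' then rounded to an integer numerosity and floored at `min_probe`.
#'
#' @param sd Perturbation SD in dots (default 0.5).
#' @param min_probe Smallest allowed probe numerosity (default 2).
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(sd = 0.5, min_probe = 2) {
  stopifnot(sd >= 0, min_probe >= 1)
  structure(list(sd = sd, min_probe = as.integer(min_probe)),
            class = "perturbation_config")
}

#' Choose the next probe numerosity
#'
#' Returns `round(posterior mean + N(0, sd))`, clamped to at least
#' `min_probe`.
#'
#' @param state A `quest_state`.
#' @param pcfg A [perturbation_config()].
#' @return Integer probe numerosity.
#' @export
next_probe <- function(state, pcfg = perturbation_config()) {
  x <- quest_mean(state) + stats::rnorm(1, 0, pcfg$sd)
  max(pcfg$min_probe, as.integer(round(x)))
}

#' Serialize a QUEST state to JSON
#'
#' @param state A `quest_state`.
#' @param path Optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
quest_to_json <- function(state, path = NULL) {
  js <- jsonlite::toJSON(unclass(state), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a QUEST state from JSON
#'
#' @param path File path or JSON string from [quest_to_json()].
#' @return A `quest_state`.
#' @export
quest_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$response_count <- as.integer(obj$response_count)
  class(obj) <- "quest_state"
  obj
}
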