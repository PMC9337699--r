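# The six fitted observer models: tagged parameter sets, per-trial response
# probabilities in closed form, and stochastic response simulation.

BAYES_MODELS <- c("noisy_bayes", "noisy_bayes_set_rho", "prior_bayes")
HEURISTIC_MODELS <- c("variable_rare", "rare_ball", "guess")
ALL_MODELS <- c(BAYES_MODELS, HEURISTIC_MODELS)

# free-parameter names by model tag
MODEL_PARAMS <- list(
  noisy_bayes = c("a", "rho"),
  noisy_bayes_set_rho = "a",
  prior_bayes = c("a", "z0"),
  variable_rare = c("theta", "p_rare", "p_no"),
  rare_ball = c("p_rare", "p_no"),
  guess = "p_guess")

#' Observer parameter set
#'
#' Tagged parameter container for one of the six observer models.
#' The Bayesian models act on a normalized belief
#' \eqn{m = z_0 + \rho k - (n - k)} (k rare balls out of n) perturbed by
#' zero-mean Gaussian noise with standard deviation \code{a}:
#' \itemize{
#'   \item \code{noisy_bayes}: free rare-ball weight \code{rho} and noise \code{a};
#'   \item \code{noisy_bayes_set_rho}: \code{rho} fixed at the ideal value
#'     [rho_io()], noise \code{a} free;
#'   \item \code{prior_bayes}: \code{rho} fixed at the ideal value, free prior
#'     log odds \code{z0} and noise \code{a}.
#' }
#' The heuristic models ignore likelihoods and respond to the rare-ball count:
#' \itemize{
#'   \item \code{variable_rare}: responds "high" with probability \code{p_rare}
#'     when at least \code{theta} rare balls appear, otherwise "low" with
#'     probability \code{p_no};
#'   \item \code{rare_ball}: the same with \code{theta = 1};
#'   \item \code{guess}: responds "high" with fixed probability \code{p_guess}.
#' }
#'
#' @param model One of \code{noisy_bayes}, \code{noisy_bayes_set_rho},
#'   \code{prior_bayes}, \code{variable_rare}, \code{rare_ball}, \code{guess}.
#' @param ... Named parameters for that model (see above).
#' @return An object of class \code{observer_params}.
#' @export
#' @examples
#' observer_params("noisy_bayes", a = 0.3, rho = 4)
#' observer_params("variable_rare", theta = 2, p_rare = 0.9, p_no = 0.8)
observer_params <- function(model, ...) {
  model <- match.arg(model, ALL_MODELS)
  p <- list(...)
  need <- MODEL_PARAMS[[model]]
  if (!setequal(names(p), need))
    stop(sprintf("model '%s' takes exactly the parameters: %s", model,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!is.null(p$a) && p$a < 0) stop("noise a must be >= 0", call. = FALSE)
  if (!is.null(p$rho) && p$rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (!is.null(p$theta)) {
    if (p$theta < 1 || p$theta != round(p$theta))
      stop("theta must be a positive integer", call. = FALSE)
  }
  for (nm in intersect(names(p), c("p_rare", "p_no", "p_guess")))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("%s must lie in [0, 1]", nm), call. = FALSE)
  structure(c(list(model = model), p), class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  vals <- unlist(x[MODEL_PARAMS[[x$model]]])
  cat(sprintf("<observer %s> %s\n", x$model,
              paste(sprintf("%s = %.4g", names(vals), vals), collapse = ", ")))
  invisible(x)
}

# Vectorized probability of a "high" response for rare-count k out of n.
# Core closed form shared by fitting tables and simulation.
p_high_core <- function(model, par, k, n, block = NULL,
                        noise_scaling = c("trial", "per_ball")) {
  noise_scaling <- match.arg(noise_scaling)
  if (model %in% BAYES_MODELS) {
    rho <- switch(model, noisy_bayes = par$rho, rho_io(block))
    z0 <- if (model == "prior_bayes") par$z0 else 0
    m <- z0 + rho * k - (n - k)
    sd <- if (noise_scaling == "trial") par$a else par$a * sqrt(n)
    len <- max(length(m), length(sd))
    m <- rep_len(m, len)
    sd <- rep_len(sd, len)
    out <- numeric(len)
    pos <- sd > 0
    out[pos] <- stats::pnorm(m[pos] / sd[pos])
    # noiseless step rule; tie tolerance absorbs rounding in rho_io
    out[!pos] <- (m[!pos] > 1e-9) + 0.5 * (abs(m[!pos]) <= 1e-9)
    out
  } else {
    thr <- switch(model, variable_rare = par$theta, rare_ball = 1, guess = NULL)
    if (is.null(thr)) {
      len <- max(length(k), length(par$p_guess))
      return(rep_len(par$p_guess, len))
    }
    len <- max(length(k), length(thr), length(par$p_rare), length(par$p_no))
    trig <- rep_len(k, len) >= rep_len(thr, len)
    ifelse(trig, rep_len(par$p_rare, len), 1 - rep_len(par$p_no, len))
  }
}

#' Response probability of a Bayesian observer
#'
#' Probability that a Bayesian observer responds "high" on each trial. With
#' mean belief \eqn{m = z_0 + \rho k - (n - k)} and Gaussian noise of
#' standard deviation \code{a}, the probability is
#' \eqn{\frac12[1 + \mathrm{erf}(m/\sqrt{2a^2})]}; \code{a = 0} degenerates
#' to the deterministic sign rule with the 0.5 tie convention.
#'
#' @param params An [observer_params()] with a Bayesian model tag.
#' @param trials Trial data frame (needs \code{rare_count} and \code{n}).
#' @param block The [block_config()] the trials belong to (supplies the ideal
#'   rare-ball weight for the set-rho and prior models).
#' @param noise_scaling \code{"trial"} (default): the noise variance
#'   \code{a^2} applies at the trial level, matching the likelihood the
#'   fitting procedure evaluates. \code{"per_ball"}: per-observation noise
#'   summed over the sample, giving trial variance \code{n a^2}.
#' @return Numeric vector of probabilities of a "high" response.
#' @export
bayes_response_prob <- function(params, trials, block,
                                noise_scaling = c("trial", "per_ball")) {
  if (!params$model %in% BAYES_MODELS)
    stop("bayes_response_prob requires a Bayesian model tag", call. = FALSE)
  p_high_core(params$model, params, trials$rare_count, trials$n, block,
              match.arg(noise_scaling))
}

#' Response probability of a heuristic observer
#'
#' Heuristic observers respond to the rare-ball count only, independently of
#' the sample length and of the likelihoods, which is the source of the
#' LLR-independent choice variability ("variance") these strategies produce.
#'
#' @param params An [observer_params()] with a heuristic model tag.
#' @param trials Trial data frame (needs \code{rare_count}).
#' @return Numeric vector of probabilities of a "high" response.
#' @export
heuristic_response_prob <- function(params, trials) {
  if (!params$model %in% HEURISTIC_MODELS)
    stop("heuristic_response_prob requires a heuristic model tag", call. = FALSE)
  p_high_core(params$model, params, trials$rare_count, trials$n)
}

#' Response probability of any observer model
#'
#' Dispatches to [bayes_response_prob()] or [heuristic_response_prob()].
#' @inheritParams bayes_response_prob
#' @export
response_prob <- function(params, trials, block = NULL,
                          noise_scaling = c("trial", "per_ball")) {
  if (params$model %in% BAYES_MODELS)
    bayes_response_prob(params, trials, block, noise_scaling)
  else heuristic_response_prob(params, trials)
}

#' Simulate observer responses
#'
#' Fills the \code{response} column of a trial table by drawing each response
#' independently with the model's per-trial probability of "high".
#'
#' @inheritParams bayes_response_prob
#' @param params An [observer_params()].
#' @param seed Optional integer for reproducibility.
#' @return The trial data frame with responses filled in.
#' @export
simulate_responses <- function(params, trials, block = NULL, seed = NULL,
                               noise_scaling = c("trial", "per_ball")) {
  if (!is.null(seed)) set.seed(seed)
  p <- response_prob(params, trials, block, noise_scaling)
  trials$response <- ifelse(stats::runif(nrow(trials)) < p, "high", "low")
  trials
}
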