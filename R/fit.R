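# Grid-based Bayesian parameter estimation: parameter grids, analytic
# per-trial likelihoods, posteriors, credible regions, and the smoothed
# informative prior built from pilot posteriors.
#
# All six models make the per-trial probability of a "high" response a
# function of the trial's (sample length n, rare count k) class alone, so a
# block's log-likelihood factorizes as
#   loglik(cell) = sum_class [ n_high(class) log p(cell, class)
#                            + n_low(class)  log(1 - p(cell, class)) ].
# The cells x classes probability matrix is data-independent and is
# precomputed once per (model, block); fitting a dataset is then a single
# matrix-vector product, which keeps recovery studies with thousands of
# synthetic datasets cheap.

#' Default parameter grid for a model
#'
#' Axes: noise \code{a} on [0, 1] step 0.01; rare-ball weight \code{rho} on
#' (0, 24.16] step 0.08; prior log odds \code{z0} on [-5, 5] step 0.1;
#' response probabilities on [0, 1] step 0.01; threshold \code{theta} on
#' 1..10. The \code{a} and \code{rho} bounds are the flat-prior ranges used
#' throughout the fitting and identifiability analyses.
#'
#' @param model Model tag.
#' @param a_step,rho_step,z0_step,p_step Grid steps.
#' @param rho_max Upper bound of the rare-ball weight axis.
#' @param theta_max Largest threshold on the grid.
#' @return Named list of strictly increasing axes.
#' @export
param_grid <- function(model, a_step = 0.01, rho_step = 0.08, rho_max = 24.16,
                       z0_step = 0.1, p_step = 0.01, theta_max = 10L) {
  a <- seq(0, 1, by = a_step)
  p <- seq(0, 1, by = p_step)
  switch(match.arg(model, ALL_MODELS),
    noisy_bayes = list(a = a, rho = seq(rho_step, rho_max, by = rho_step)),
    noisy_bayes_set_rho = list(a = a),
    prior_bayes = list(a = a, z0 = seq(-5, 5, by = z0_step)),
    variable_rare = list(theta = seq_len(theta_max), p_rare = p, p_no = p),
    rare_ball = list(p_rare = p, p_no = p),
    guess = list(p_guess = p))
}

grid_cells <- function(axes) {
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(cells) <- names(axes)
  cells
}

# Aggregate responded trials into (n, k) classes with high/low counts.
trial_classes <- function(trials) {
  tr <- trials[!is.na(trials$response), , drop = FALSE]
  if (nrow(tr) == 0L)
    return(data.frame(n = integer(0), k = integer(0),
                      n_high = numeric(0), n_low = numeric(0)))
  key <- paste(tr$n, tr$rare_count)
  agg <- stats::aggregate(cbind(n_high = tr$response == "high",
                                n_low = tr$response == "low"),
                          by = list(key = key), FUN = sum)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  data.frame(n = as.integer(parts[, 1]), k = as.integer(parts[, 2]),
             n_high = agg$n_high, n_low = agg$n_low)
}

# All (n, k) classes a block can produce.
block_class_grid <- function(block) {
  do.call(rbind, lapply(block$sample_lengths, function(n)
    data.frame(n = n, k = 0:n)))
}

# cells x classes matrix of P(high) for a model on a block
class_prob_matrix <- function(model, cells, classes, block,
                              noise_scaling = "trial") {
  out <- matrix(0, nrow = nrow(cells), ncol = nrow(classes))
  par <- as.list(cells)
  for (j in seq_len(nrow(classes)))
    out[, j] <- p_high_core(model, par, classes$k[j], classes$n[j], block,
                            noise_scaling)
  out
}

# Precomputed fitting tables for one model on one block: grid cells plus
# log P(high) and log P(low) floored at the likelihood epsilon.
model_fit_table <- function(model, block, grid = param_grid(model),
                            noise_scaling = "trial") {
  classes <- block_class_grid(block)
  cells <- grid_cells(grid)
  P <- class_prob_matrix(model, cells, classes, block, noise_scaling)
  list(model = model, block = block, axes = grid, cells = cells,
       classes = classes,
       log_hi = log(pmax(P, .lik_eps)),
       log_lo = log(pmax(1 - P, .lik_eps)))
}

block_fit_tables <- function(block, models = ALL_MODELS,
                             noise_scaling = "trial", grids = NULL) {
  stats::setNames(lapply(models, function(m)
    model_fit_table(m, block, grid = grids[[m]] %||% param_grid(m),
                    noise_scaling = noise_scaling)), models)
}

# log-likelihood over grid cells given aggregated class counts
table_loglik <- function(tab, classes) {
  if (nrow(classes) == 0L) return(numeric(nrow(tab$cells)))
  idx <- match(paste(classes$n, classes$k),
               paste(tab$classes$n, tab$classes$k))
  if (anyNA(idx)) stop("trial classes outside the block's class grid", call. = FALSE)
  drop(tab$log_hi[, idx, drop = FALSE] %*% classes$n_high +
         tab$log_lo[, idx, drop = FALSE] %*% classes$n_low)
}

#' Log-likelihood of one trial's response
#'
#' Log of the model's analytic response probability (or its complement for a
#' "low" response). A probability of exactly zero, possible for deterministic
#' heuristics, is floored at 1e-10 per trial so such observers remain
#' fittable; floored trials are reported via the \code{floored} attribute.
#'
#' @param model Model tag.
#' @param params An [observer_params()].
#' @param trial One-row trial data frame with a response.
#' @param block The trial's [block_config()].
#' @return Scalar log-probability.
#' @export
trial_log_likelihood <- function(model, params, trial, block) {
  stopifnot(!is.na(trial$response))
  p <- response_prob(params, trial, block)
  pr <- if (trial$response == "high") p else 1 - p
  out <- log(max(pr, .lik_eps))
  attr(out, "floored") <- pr < .lik_eps
  out
}

#' Fit a grid posterior for one subject-block
#'
#' Cellwise log prior plus summed per-trial log-likelihoods, normalized over
#' the grid. The posterior depends on the trials only through the counts of
#' high/low responses per (sample length, rare count) class and is therefore
#' invariant to trial order. With zero responded trials the posterior equals
#' the prior.
#'
#' @param model Model tag.
#' @param trials Trial data frame for one subject and block (rows with
#'   \code{NA} responses are ignored).
#' @param block The [block_config()].
#' @param prior \code{NULL} for a flat prior, an [informative_prior] (expanded
#'   to the model's grid via [model_prior()]), or a numeric mass vector over
#'   the grid cells.
#' @param grid Parameter grid (defaults to [param_grid()] for the model).
#' @param noise_scaling Passed to the Bayesian likelihoods; see
#'   [bayes_response_prob()].
#' @return Object of class \code{posterior_grid} with the axes, cells,
#'   log-prior, log-likelihood, normalized posterior mass and the log
#'   marginal likelihood (log of the prior-weighted likelihood sum).
#' @export
fit_posterior <- function(model, trials, block, prior = NULL,
                          grid = param_grid(model), noise_scaling = "trial") {
  tab <- model_fit_table(model, block, grid, noise_scaling)
  posterior_from_table(tab, trial_classes(trials), prior)
}

posterior_from_table <- function(tab, classes, prior = NULL) {
  n_cells <- nrow(tab$cells)
  log_prior <- prior_log_mass(prior, tab)
  log_lik <- table_loglik(tab, classes)
  lp <- log_prior + log_lik
  log_marginal <- logsumexp(lp)
  structure(list(model = tab$model, block = tab$block$name, axes = tab$axes,
                 cells = tab$cells, log_prior = log_prior, log_lik = log_lik,
                 post = exp(lp - log_marginal),
                 log_marginal = log_marginal),
            class = "posterior_grid")
}

prior_log_mass <- function(prior, tab) {
  n_cells <- nrow(tab$cells)
  if (is.null(prior)) return(rep(-log(n_cells), n_cells))
  if (inherits(prior, "informative_prior"))
    prior <- model_prior(tab$model, tab$block, prior, tab$axes)
  if (length(prior) != n_cells)
    stop("prior mass does not match the model grid", call. = FALSE)
  if (any(prior < 0) || sum(prior) <= 0)
    stop("prior mass must be nonnegative with positive total", call. = FALSE)
  log(prior / sum(prior))
}

#' @export
print.posterior_grid <- function(x, ...) {
  est <- mle_and_credible(x)
  cat(sprintf("<posterior %s | block %s> %d cells, log marginal = %.3f\n",
              x$model, x$block, nrow(x$cells), x$log_marginal))
  cat("  MLE:", paste(sprintf("%s = %.4g", names(est$estimate), est$estimate),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Point estimate and 95% highest-density credible region
#'
#' The argmax cell of the posterior (ties broken toward the lowest cell
#' index) and the smallest set of grid cells containing at least the
#' requested posterior mass. Per-parameter bounds are the ranges of the
#' included cells.
#'
#' @param posterior A \code{posterior_grid}.
#' @param level Credible mass, default 0.95.
#' @return List with \code{estimate} (named vector), \code{bounds} (matrix of
#'   per-parameter lo/hi), \code{member} (indices of cells in the region) and
#'   \code{mass} actually covered.
#' @export
mle_and_credible <- function(posterior, level = 0.95) {
  post <- posterior$post
  mle_idx <- which.max(post)
  ord <- order(post, decreasing = TRUE)
  csum <- cumsum(post[ord])
  n_in <- which(csum >= level)[1L]
  member <- ord[seq_len(n_in)]
  bounds <- vapply(names(posterior$axes), function(p)
    range(posterior$cells[[p]][member]), numeric(2))
  rownames(bounds) <- c("lo", "hi")
  list(estimate = unlist(posterior$cells[mle_idx, , drop = FALSE]),
       bounds = bounds, member = member, mass = csum[n_in], level = level)
}

#' Is a parameter point inside the credible region?
#'
#' Maps the point to its nearest grid cell and checks membership in the
#' highest-density region.
#'
#' @param posterior A \code{posterior_grid}.
#' @param params Named list/vector of parameter values.
#' @param level Credible mass.
#' @return Logical.
#' @export
in_credible_region <- function(posterior, params, level = 0.95) {
  cred <- mle_and_credible(posterior, level)
  idx <- nearest_cell(posterior$axes, params)
  idx %in% cred$member
}

nearest_cell <- function(axes, params) {
  sub <- lapply(names(axes), function(p)
    which.min(abs(axes[[p]] - params[[p]])))
  names(sub) <- names(axes)
  # cells come from expand.grid: first axis varies fastest
  idx <- 1L
  mult <- 1L
  for (p in names(axes)) {
    idx <- idx + (sub[[p]] - 1L) * mult
    mult <- mult * length(axes[[p]])
  }
  idx
}

#' Posterior mass near a parameter point
#'
#' Total posterior mass of the cells lying within \code{window} of
#' \code{params} in every listed parameter. Used to quantify posterior
#' concentration around the generating parameters.
#'
#' @param posterior A \code{posterior_grid}.
#' @param params Named list/vector of true parameter values.
#' @param window Half-width of the box, in parameter units (default 1).
#' @return Scalar mass in [0, 1].
#' @export
posterior_mass_near <- function(posterior, params, window = 1) {
  keep <- rep(TRUE, nrow(posterior$cells))
  for (p in names(params))
    keep <- keep & abs(posterior$cells[[p]] - params[[p]]) <= window
  sum(posterior$post[keep])
}

# ---- informative prior ------------------------------------------------------

#' Build the informative prior from pilot posteriors
#'
#' Averages flat-prior Noisy Bayesian posteriors from pilot subjects
#' cellwise, then smooths each marginal: the rare-ball-weight marginal is
#' multiplied by a normal density \code{N(mu, sigma^2)} centered at the
#' marginal's argmax (weakening support far from the pilot consensus), and
#' the noise marginal (as a density over \code{a}) is passed through
#' \code{(x + c)/(1 + c L)}, which flattens jagged structure. The smoothed
#' marginals are recombined as a product prior and renormalized; the joint
#' prior is strictly positive on the whole grid.
#'
#' Smoothing constants default to the block-symmetry convention
#' \code{L = 2, c = 5} (symmetric blocks) and \code{L = 1, c = 2}
#' (asymmetric blocks).
#'
#' @param pilot_posteriors List of \code{posterior_grid}s for the Noisy
#'   Bayesian model, one per pilot subject, on a common grid.
#' @param block The [block_config()] the posteriors belong to.
#' @param sigma Standard deviation of the rho filter (rho units); see
#'   [calibrate_rho_sigma()] for the calibration loop that selects it.
#' @param c_const,L_const Constants of the noise-marginal map; \code{NULL}
#'   selects the symmetry-based defaults.
#' @return Object of class \code{informative_prior}.
#' @export
build_informative_prior <- function(pilot_posteriors, block, sigma = 2,
                                    c_const = NULL, L_const = NULL) {
  if (length(pilot_posteriors) < 1L)
    stop("need at least one pilot posterior", call. = FALSE)
  axes <- pilot_posteriors[[1L]]$axes
  if (!setequal(names(axes), c("a", "rho")))
    stop("informative prior is built on the Noisy Bayesian (a, rho) grid",
         call. = FALSE)
  for (p in pilot_posteriors)
    if (!identical(p$axes, axes))
      stop("pilot posteriors must share one grid", call. = FALSE)
  sym <- is_symmetric(block)
  if (is.null(c_const)) c_const <- if (sym) 5 else 2
  if (is.null(L_const)) L_const <- if (sym) 2 else 1
  avg <- Reduce(`+`, lapply(pilot_posteriors, `[[`, "post")) /
    length(pilot_posteriors)
  avg_mat <- matrix(avg, nrow = length(axes$a))  # a varies fastest
  a_marg <- rowSums(avg_mat)
  rho_marg <- colSums(avg_mat)
  # rho: multiply by a normal density centered at the marginal's argmax
  mu <- axes$rho[which.max(rho_marg)]
  rho_sm <- rho_marg * stats::dnorm(axes$rho, mu, sigma)
  rho_sm <- pmax(rho_sm, .Machine$double.xmin)
  rho_sm <- rho_sm / sum(rho_sm)
  # a: map the marginal density through (x + c)/(1 + cL)
  step_a <- if (length(axes$a) > 1L) diff(axes$a[1:2]) else 1
  a_dens <- a_marg / step_a
  a_sm <- (a_dens + c_const) / (1 + c_const * L_const)
  a_sm <- a_sm / sum(a_sm)
  mass <- as.vector(outer(a_sm, rho_sm))
  structure(list(block = block$name, axes = axes, a_mass = a_sm,
                 rho_mass = rho_sm, mass = mass / sum(mass),
                 sigma = sigma, c_const = c_const, L_const = L_const,
                 mu = mu, n_pilot = length(pilot_posteriors)),
            class = "informative_prior")
}

#' @export
print.informative_prior <- function(x, ...) {
  cat(sprintf(
    "<informative prior | block %s> %d pilot posteriors; rho filter N(%.3g, %.3g^2); a map c = %g, L = %g\n",
    x$block, x$n_pilot, x$mu, x$sigma, x$c_const, x$L_const))
  invisible(x)
}

#' Expand a prior to a model's grid
#'
#' The informative prior lives on the Noisy Bayesian (a, rho) grid. The other
#' Bayesian models borrow its noise marginal: the set-rho model uses the
#' a-marginal directly; the prior-Bayesian model crosses the a-marginal with
#' a flat prior over z0. Heuristic models always use flat priors.
#'
#' @param model Model tag.
#' @param block [block_config()] (unused for flat priors; kept for a uniform
#'   interface).
#' @param informative An \code{informative_prior} or \code{NULL} (flat).
#' @param axes The model's grid axes.
#' @return Numeric mass vector over the model's grid cells, summing to 1.
#' @export
model_prior <- function(model, block, informative = NULL,
                        axes = param_grid(model)) {
  n_cells <- prod(vapply(axes, length, integer(1)))
  if (is.null(informative) || !model %in% BAYES_MODELS)
    return(rep(1 / n_cells, n_cells))
  if (!identical(informative$axes$a, axes$a))
    stop("informative prior and model grid disagree on the a axis", call. = FALSE)
  switch(model,
    noisy_bayes = {
      if (!identical(informative$axes$rho, axes$rho))
        stop("informative prior and model grid disagree on the rho axis",
             call. = FALSE)
      informative$mass
    },
    noisy_bayes_set_rho = informative$a_mass,
    prior_bayes = {
      m <- as.vector(outer(informative$a_mass,
                           rep(1 / length(axes$z0), length(axes$z0))))
      m / sum(m)
    })
}

#' Fit pilot posteriors and build per-block informative priors
#'
#' Runs the flat-prior Noisy Bayesian fit on every pilot subject's trials for
#' each block (control trials pooled across pre-test and interludes) and
#' returns the smoothed informative prior per block.
#'
#' @param pilot A pilot \code{cohort}.
#' @param blocks Block list.
#' @param sigma Rho-filter standard deviation.
#' @return Named list of \code{informative_prior}s, one per block.
#' @export
informative_priors_from_pilot <- function(pilot, blocks = study_blocks(),
                                          sigma = 2) {
  stats::setNames(lapply(blocks, function(block) {
    tab <- model_fit_table("noisy_bayes", block)
    posts <- lapply(pilot$subjects$subject_id, function(sid) {
      tr <- pilot$trials[pilot$trials$subject_id == sid &
                           pilot$trials$block == block$name, ]
      posterior_from_table(tab, trial_classes(tr))
    })
    build_informative_prior(posts, block, sigma = sigma)
  }), names(blocks))
}

#' Calibrate the rho-filter width
#'
#' Implements the calibration loop for the informative prior: for each
#' candidate \code{sigma}, rebuild the prior, fit \code{n_datasets} synthetic
#' Noisy Bayesian datasets whose parameters are drawn from that prior, and
#' return the smallest candidate whose median squared error of the recovered
#' rho falls below the target.
#'
#' @param pilot_posteriors Pilot posteriors as in [build_informative_prior()].
#' @param block [block_config()].
#' @param sigmas Candidate standard deviations, tried in order.
#' @param n_datasets Synthetic datasets per candidate.
#' @param target Median squared-error threshold (default 1).
#' @param seed RNG seed.
#' @return List with the selected \code{sigma} and the per-candidate median
#'   MSE table.
#' @export
calibrate_rho_sigma <- function(pilot_posteriors, block,
                                sigmas = c(1, 2, 3, 5, 8), n_datasets = 100L,
                                target = 1, seed = 1L) {
  set.seed(seed)
  tab <- model_fit_table("noisy_bayes", block)
  med <- numeric(length(sigmas))
  for (i in seq_along(sigmas)) {
    prior <- build_informative_prior(pilot_posteriors, block, sigma = sigmas[i])
    med[i] <- stats::median(rho_recovery_errors(block, prior, n_datasets, tab))
    if (med[i] < target)
      return(list(sigma = sigmas[i],
                  table = data.frame(sigma = sigmas[seq_len(i)],
                                     median_mse = med[seq_len(i)])))
  }
  list(sigma = sigmas[which.min(med)],
       table = data.frame(sigma = sigmas, median_mse = med))
}

# squared rho errors for n_datasets synthetic noisy-Bayes subjects with
# parameters drawn from `prior`, fit under `prior`
rho_recovery_errors <- function(block, prior, n_datasets, tab = NULL,
                                n_trials = block$n_trials) {
  if (is.null(tab)) tab <- model_fit_table("noisy_bayes", block)
  prior_mass <- model_prior("noisy_bayes", block, prior, tab$axes)
  vapply(seq_len(n_datasets), function(i) {
    cell <- sample.int(length(prior_mass), 1L, prob = prior_mass)
    truth <- observer_params("noisy_bayes", a = tab$cells$a[cell],
                             rho = tab$cells$rho[cell])
    tr <- sample_block_trials(block, n_trials = n_trials)
    tr <- simulate_responses(truth, tr, block)
    post <- posterior_from_table(tab, trial_classes(tr), prior_mass)
    est <- mle_and_credible(post)$estimate
    (est[["rho"]] - truth$rho)^2
  }, numeric(1))
}
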