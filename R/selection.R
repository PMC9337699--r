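# Marginal likelihoods, log Bayes factors against the Noisy Bayesian
# baseline, subject-level model selection, cross-validation, and the
# model-recovery (identifiability) study.

# fixed declaration order used for tie-breaks in selection
ALT_MODELS <- c("noisy_bayes_set_rho", "prior_bayes", "variable_rare",
                "rare_ball", "guess")

#' Log marginal likelihood of a model on one subject-block
#'
#' Log of the prior-weighted sum of per-cell likelihoods over the model's
#' parameter grid (grid quadrature of the Bayes-factor integral).
#'
#' @inheritParams fit_posterior
#' @param informative Optional [informative_prior] for the block; Bayesian
#'   models then use it (see [model_prior()]), heuristics stay flat.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(model, trials, block, informative = NULL,
                                    grid = param_grid(model)) {
  fit_posterior(model, trials, block, prior = informative,
                grid = grid)$log_marginal
}

#' Log Bayes factor of an alternative model against the Noisy Bayesian baseline
#'
#' \code{log marginal(alt) - log marginal(noisy_bayes)}; positive values
#' favor the alternative. By convention the Noisy Bayesian model is always
#' the baseline (denominator).
#'
#' @param alt_model Alternative model tag.
#' @inheritParams log_marginal_likelihood
#' @export
log_bayes_factor <- function(alt_model, trials, block, informative = NULL) {
  log_marginal_likelihood(alt_model, trials, block, informative) -
    log_marginal_likelihood("noisy_bayes", trials, block, informative)
}

# marginals for all six models from precomputed tables (fast path)
marginals_from_tables <- function(tables, classes, priors) {
  vapply(names(tables), function(m) {
    lp <- prior_log_mass(priors[[m]], tables[[m]]) +
      table_loglik(tables[[m]], classes)
    logsumexp(lp)
  }, numeric(1))
}

table_priors <- function(tables, block, informative = NULL) {
  stats::setNames(lapply(names(tables), function(m)
    model_prior(m, block, informative, tables[[m]]$axes)), names(tables))
}

#' Select the best-fitting model for one subject-block
#'
#' Computes log Bayes factors of the five alternative models against the
#' Noisy Bayesian baseline and applies the selection rule: the alternative
#' with the largest positive log Bayes factor wins; if no alternative has a
#' positive value, the Noisy Bayesian model is selected. Ties are broken
#' toward the model declared earlier in the fixed order (Set rho, Prior,
#' Variable Rare, Rare, Guess). \code{strong_evidence} flags |log BF| > 1
#' for the winning comparison.
#'
#' @param trials Trial data for one subject-block.
#' @param block The [block_config()].
#' @param informative Optional [informative_prior] for the block.
#' @param tables Optional precomputed fit tables (internal fast path).
#' @return List of class \code{model_selection} with \code{log_marginals},
#'   \code{log_bf} (per alternative), \code{selected} and
#'   \code{strong_evidence}.
#' @export
select_model <- function(trials, block, informative = NULL, tables = NULL) {
  if (is.null(tables)) tables <- block_fit_tables(block)
  priors <- table_priors(tables, block, informative)
  lm <- marginals_from_tables(tables, trial_classes(trials), priors)
  log_bf <- lm[ALT_MODELS] - lm[["noisy_bayes"]]
  if (all(log_bf <= 0)) {
    selected <- "noisy_bayes"
    strong <- all(log_bf < -1)
  } else {
    selected <- ALT_MODELS[which.max(log_bf)]
    strong <- log_bf[[selected]] > 1
  }
  structure(list(log_marginals = lm, log_bf = log_bf, selected = selected,
                 strong_evidence = strong, block = block$name),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model selection | block %s> selected: %s%s\n", x$block,
              x$selected, if (x$strong_evidence) " (strong evidence)" else ""))
  print(round(x$log_bf, 3))
  invisible(x)
}

#' Model-recovery (identifiability) study
#'
#' For each generating model, simulates \code{n_datasets} response datasets
#' on each block (42-trial test blocks, 60-trial control), with parameters
#' drawn from the model's fitting prior (the informative prior for Bayesian
#' models, flat priors for heuristics), fits all six models and records two
#' measures: the \emph{pairwise identification} fraction, i.e. how often the
#' Bayes factor against the Noisy Bayesian baseline favors the generating
#' model (for the baseline itself: how often no alternative beats it), and
#' the full selection-rule confusion matrix.
#'
#' @param n_datasets Synthetic datasets per model per block.
#' @param blocks Named list of [block_config()]s.
#' @param informative Named list of [informative_prior]s per block (or
#'   \code{NULL} for flat priors everywhere).
#' @param models Generating models to include.
#' @param seed RNG seed.
#' @return List with \code{identified} (models x blocks matrix of pairwise
#'   identification fractions), \code{confusion} (per-block generating x
#'   selected matrices, rows summing to 1) and \code{n_datasets}.
#' @export
model_recovery_study <- function(n_datasets = 100L, blocks = study_blocks(),
                                 informative = NULL, models = ALL_MODELS,
                                 seed = 1L) {
  set.seed(seed)
  block_names <- vapply(blocks, `[[`, "", "name")
  identified <- matrix(NA_real_, length(models), length(blocks),
                       dimnames = list(models, block_names))
  confusion <- list()
  for (b in seq_along(blocks)) {
    block <- blocks[[b]]
    tables <- block_fit_tables(block)
    priors <- table_priors(tables, block,
                           if (is.null(informative)) NULL
                           else informative[[block_names[b]]])
    conf <- matrix(0, length(models), length(ALL_MODELS),
                   dimnames = list(models, ALL_MODELS))
    for (g in models) {
      hits <- 0L
      for (r in seq_len(n_datasets)) {
        truth <- draw_params_from_prior(g, block, priors[[g]], tables[[g]])
        tr <- sample_block_trials(block)
        tr <- simulate_responses(truth, tr, block)
        lm <- marginals_from_tables(tables, trial_classes(tr), priors)
        log_bf <- lm[ALT_MODELS] - lm[["noisy_bayes"]]
        sel <- if (all(log_bf <= 0)) "noisy_bayes" else
          ALT_MODELS[which.max(log_bf)]
        conf[g, sel] <- conf[g, sel] + 1
        hit <- if (g == "noisy_bayes") all(log_bf <= 0) else log_bf[[g]] > 0
        hits <- hits + hit
      }
      identified[g, b] <- hits / n_datasets
    }
    confusion[[block_names[b]]] <- conf / n_datasets
  }
  list(identified = identified, confusion = confusion,
       n_datasets = n_datasets)
}

# draw generating parameters: Bayesian models sample a grid cell from the
# prior mass; heuristics draw flat (continuous for probabilities, uniform on
# the theta grid)
draw_params_from_prior <- function(model, block, prior_mass, tab) {
  if (model %in% BAYES_MODELS) {
    cell <- sample.int(nrow(tab$cells), 1L, prob = prior_mass)
    vals <- as.list(tab$cells[cell, , drop = FALSE])
    do.call(observer_params, c(list(model = model), vals))
  } else {
    switch(model,
      variable_rare = observer_params(model,
        theta = sample(tab$axes$theta, 1L),
        p_rare = stats::runif(1), p_no = stats::runif(1)),
      rare_ball = observer_params(model, p_rare = stats::runif(1),
                                  p_no = stats::runif(1)),
      guess = observer_params(model, p_guess = stats::runif(1)))
  }
}

#' 10-fold cross-validation of a selected model
#'
#' Shuffles the trials once (reproducibly), splits them into 10 contiguous
#' folds, fits the model on 90% of trials and predicts the most-probable
#' response (at the maximum-posterior parameters) on the held-out 10%,
#' averaging response-match accuracy over folds. A predicted probability of
#' exactly 0.5 scores half a match.
#'
#' @param trials Trial data for one subject-block (>= 10 responded trials).
#' @param block The [block_config()].
#' @param model Model tag to validate.
#' @param informative Optional [informative_prior].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @return Mean held-out accuracy.
#' @export
cross_validate <- function(trials, block, model, informative = NULL,
                           folds = 10L, seed = 1L) {
  tr <- trials[!is.na(trials$response), , drop = FALSE]
  if (nrow(tr) < folds)
    stop(sprintf("cross-validation needs at least %d responded trials", folds),
         call. = FALSE)
  set.seed(seed)
  ord <- sample.int(nrow(tr))
  fold_id <- cut(seq_along(ord), folds, labels = FALSE)
  tab <- model_fit_table(model, block)
  prior <- model_prior(model, block, informative, tab$axes)
  acc <- vapply(seq_len(folds), function(f) {
    test_idx <- ord[fold_id == f]
    train <- tr[-test_idx, , drop = FALSE]
    test <- tr[test_idx, , drop = FALSE]
    post <- posterior_from_table(tab, trial_classes(train), prior)
    est <- mle_and_credible(post)$estimate
    pars <- do.call(observer_params,
                    c(list(model = model), as.list(est)))
    p <- response_prob(pars, test, block)
    pred_match <- ifelse(p == 0.5, 0.5,
                         (p > 0.5) == (test$response == "high"))
    mean(pred_match)
  }, numeric(1))
  mean(acc)
}
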