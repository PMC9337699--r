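# Synthetic-cohort generator: simulated subjects with assigned strategies,
# the full session structure of the study (pre-test, randomized test blocks,
# interspersed control trials) and the exclusion rules.

#' Configure a synthetic cohort
#'
#' Describes how a cohort of simulated subjects is built: how many subjects,
#' which strategy each may use, how their parameters are drawn, and the block
#' and control-trial design of a session.
#'
#' Default parameter distributions (all overridable through
#' \code{param_sampler}): noise \code{a ~ U(0, 1)}; rare-ball weight
#' \code{rho ~ U(1, 24.16)}; prior log odds \code{z0 ~ U(-3, 0)} (low-jar
#' leaning); heuristic response probabilities \code{~ U(0.5, 1)}; threshold
#' \code{theta} uniform on {1, 2, 3}. These spans cover the parameter ranges
#' the fitted models admit while keeping simulated behaviour above chance.
#'
#' @param n_subjects Number of subjects.
#' @param strategy_mix Named probability vector over the six model tags (one
#'   strategy per subject, used in every block), or a named list of such
#'   vectors keyed by block name with a \code{default} entry (strategy drawn
#'   per subject and block; subjects, like humans, may switch strategies
#'   between conditions -- e.g. near-ideal behaviour in the easy control
#'   block but a heuristic under hard asymmetric evidence).
#' @param param_sampler Function \code{(model, block)} returning an
#'   [observer_params()]; defaults to [default_param_sampler()]. Called per
#'   subject and block (fits are per subject-block, and simulated subjects,
#'   like human ones, need not be identically tuned in every block).
#' @param blocks Named list of [block_config()]s; the first must be the
#'   control block used for pre-test and interspersed trials.
#' @param pretest_trials,interlude_trials,n_interludes Control-trial design:
#'   24 pre-test trials and 3 interludes of 12 trials between test blocks.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects,
                          strategy_mix = c(noisy_bayes = 1, noisy_bayes_set_rho = 1,
                                           prior_bayes = 1, variable_rare = 1,
                                           rare_ball = 1, guess = 1) / 6,
                          param_sampler = default_param_sampler,
                          blocks = study_blocks(),
                          pretest_trials = 24L, interlude_trials = 12L,
                          n_interludes = 3L, seed = 1L) {
  check_mix <- function(m) {
    if (length(m) == 0L || sum(m) <= 0)
      stop("strategy_mix must be a non-empty probability vector", call. = FALSE)
    if (!all(names(m) %in% ALL_MODELS))
      stop("unknown model tag in strategy_mix", call. = FALSE)
    m / sum(m)
  }
  strategy_mix <- if (is.list(strategy_mix)) lapply(strategy_mix, check_mix)
                  else check_mix(strategy_mix)
  structure(list(n_subjects = as.integer(n_subjects),
                 strategy_mix = strategy_mix,
                 param_sampler = param_sampler,
                 blocks = blocks,
                 pretest_trials = as.integer(pretest_trials),
                 interlude_trials = as.integer(interlude_trials),
                 n_interludes = as.integer(n_interludes),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default parameter distributions for simulated subjects
#'
#' @param model Model tag.
#' @param block The block the parameters apply to (used only by samplers that
#'   tie parameters to the jar composition).
#' @return An [observer_params()].
#' @export
default_param_sampler <- function(model, block = NULL) {
  switch(model,
    noisy_bayes = observer_params(model, a = stats::runif(1, 0, 1),
                                  rho = stats::runif(1, 1, 24.16)),
    noisy_bayes_set_rho = observer_params(model, a = stats::runif(1, 0, 1)),
    prior_bayes = observer_params(model, a = stats::runif(1, 0, 1),
                                  z0 = stats::runif(1, -3, 0)),
    variable_rare = observer_params(model, theta = sample(1:3, 1),
                                    p_rare = stats::runif(1, 0.5, 1),
                                    p_no = stats::runif(1, 0.5, 1)),
    rare_ball = observer_params(model, p_rare = stats::runif(1, 0.5, 1),
                                p_no = stats::runif(1, 0.5, 1)),
    guess = observer_params(model, p_guess = stats::runif(1, 0.5, 1)))
}

#' Parameter distributions emulating the pilot population
#'
#' The pilot cohort stands in for the study's pilot subjects used to build
#' the informative prior. It draws Noisy Bayesian observers with low decision
#' noise (\code{a ~ U(0.05, 0.4)}) and rare-ball weights below the ideal
#' value in asymmetric blocks (\code{rho ~ U(max(0.3, rho_IO - 4),
#' 0.7 rho_IO)}), reflecting the systematic underweighting of rare balls
#' that characterizes pilot behaviour under asymmetric evidence; in
#' symmetric blocks, where the ideal weight is 1 and mis-scaling in either
#' direction is benign, the range spans both sides of 1
#' (\code{rho ~ U(0.3, 3)}).
#'
#' @inheritParams default_param_sampler
#' @export
pilot_param_sampler <- function(model, block) {
  r <- rho_io(block)
  hi <- if (is_symmetric(block)) 3 else 0.7 * r
  observer_params("noisy_bayes", a = stats::runif(1, 0.05, 0.4),
                  rho = stats::runif(1, min(max(0.3, r - 4), 0.9 * hi), hi))
}

params_row <- function(subject_id, block_name, params) {
  row <- data.frame(subject_id = subject_id, block = block_name,
                    model = params$model,
                    a = NA_real_, rho = NA_real_, z0 = NA_real_,
                    theta = NA_real_, p_rare = NA_real_, p_no = NA_real_,
                    p_guess = NA_real_, stringsAsFactors = FALSE)
  for (nm in MODEL_PARAMS[[params$model]]) row[[nm]] <- params[[nm]]
  row
}

row_to_params <- function(row) {
  vals <- as.list(row[MODEL_PARAMS[[row$model]]])
  do.call(observer_params, c(list(model = row$model), vals))
}

#' Generate a synthetic cohort
#'
#' Builds full sessions for every subject: a strategy drawn from the mix,
#' per-block parameters from the sampler, a pre-test of control trials, the
#' test blocks in randomized order with control interludes between them, and
#' responses simulated from the subject's model. Fully reproducible from the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class \code{cohort}: list with \code{subjects}
#'   (one row per subject: \code{subject_id}, \code{true_model},
#'   \code{excluded}, \code{reason}), \code{params} (one row per
#'   subject-block with the true parameter values) and \code{trials} (one row
#'   per trial, session order, with a \code{segment} column distinguishing
#'   pre-test, test and interlude trials). Truth labels are kept apart from
#'   the trial table so fitting code never sees them.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  control <- config$blocks[[1L]]
  test_blocks <- config$blocks[-1L]
  subjects <- vector("list", config$n_subjects)
  params <- vector("list", config$n_subjects)
  trials <- vector("list", config$n_subjects)
  mix_for <- function(bn) {
    if (!is.list(config$strategy_mix)) return(config$strategy_mix)
    m <- config$strategy_mix[[bn]] %||% config$strategy_mix[["default"]]
    if (is.null(m))
      stop(sprintf("no strategy mix for block %s and no default", bn),
           call. = FALSE)
    m
  }
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", i)
    if (is.list(config$strategy_mix)) {
      models_b <- vapply(names(config$blocks), function(bn) {
        m <- mix_for(bn)
        sample(names(m), 1L, prob = m)
      }, character(1))
      model <- "mixed"
    } else {
      m <- config$strategy_mix
      models_b <- rep(sample(names(m), 1L, prob = m),
                      length(config$blocks))
      names(models_b) <- names(config$blocks)
      model <- models_b[[1L]]
    }
    pars <- lapply(names(config$blocks), function(bn)
      config$param_sampler(models_b[[bn]], config$blocks[[bn]]))
    names(pars) <- names(config$blocks)
    params[[i]] <- do.call(rbind, lapply(names(config$blocks), function(bn)
      params_row(sid, config$blocks[[bn]]$name, pars[[bn]])))
    order_tests <- sample(seq_along(test_blocks))
    segments <- list(list(block = control, n = config$pretest_trials,
                          segment = "pretest"))
    for (j in seq_along(order_tests)) {
      segments <- c(segments, list(list(block = test_blocks[[order_tests[j]]],
                                        n = test_blocks[[order_tests[j]]]$n_trials,
                                        segment = "test")))
      if (j <= config$n_interludes)
        segments <- c(segments, list(list(block = control,
                                          n = config$interlude_trials,
                                          segment = sprintf("interlude%d", j))))
    }
    seg_trials <- lapply(segments, function(sg) {
      tr <- sample_block_trials(sg$block, n_trials = sg$n)
      tr$segment <- sg$segment
      tr <- simulate_responses(pars[[match(sg$block$name,
                                           vapply(config$blocks, `[[`, "", "name"))]],
                               tr, sg$block)
      tr
    })
    sess <- do.call(rbind, seg_trials)
    sess$subject_id <- sid
    sess$trial_index <- seq_len(nrow(sess)) - 1L
    trials[[i]] <- sess
    subjects[[i]] <- data.frame(subject_id = sid, true_model = model,
                                excluded = FALSE, reason = NA_character_,
                                stringsAsFactors = FALSE)
  }
  structure(list(subjects = do.call(rbind, subjects),
                 params = do.call(rbind, params),
                 trials = do.call(rbind, trials),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d trials (%d excluded)\n",
              nrow(x$subjects), nrow(x$trials), sum(x$subjects$excluded)))
  invisible(x)
}

#' Apply the study's exclusion rules
#'
#' Flags subjects who fail the pre-test (below 80% correct on the pre-test
#' control trials, mirroring subjects never admitted to the full task) and
#' inattentive subjects (50% or less correct on at least two of the
#' interspersed control interludes).
#'
#' @param cohort A \code{cohort}.
#' @return The cohort with \code{subjects$excluded} and \code{subjects$reason}
#'   filled in.
#' @export
apply_exclusions <- function(cohort) {
  tr <- cohort$trials
  if (!any(tr$segment == "pretest") || !any(grepl("^interlude", tr$segment)))
    stop("cohort trials are missing control segments", call. = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    mine <- tr[tr$subject_id == sid, ]
    pre <- mine[mine$segment == "pretest", ]
    pre_acc <- mean(pre$response == pre$jar)
    if (pre_acc < 0.8) {
      cohort$subjects$excluded[i] <- TRUE
      cohort$subjects$reason[i] <- "pretest_failure"
      next
    }
    inter <- mine[grepl("^interlude", mine$segment), ]
    accs <- tapply(inter$response == inter$jar, inter$segment, mean)
    if (sum(accs <= 0.5) >= 2L) {
      cohort$subjects$excluded[i] <- TRUE
      cohort$subjects$reason[i] <- "inattentive"
    }
  }
  cohort
}

#' Generate a pilot cohort
#'
#' Convenience wrapper producing the small cohort (default 20 subjects) whose
#' flat-prior posteriors seed [build_informative_prior()]. Uses
#' [pilot_param_sampler()] unless the config says otherwise.
#'
#' @param n_pilot Number of pilot subjects.
#' @param blocks Block list.
#' @param seed Seed for the pilot cohort.
#' @param param_sampler Parameter sampler for pilot subjects.
#' @return A \code{cohort}.
#' @export
generate_pilot <- function(n_pilot = 20L, blocks = study_blocks(), seed = 100L,
                           param_sampler = pilot_param_sampler) {
  cfg <- cohort_config(n_pilot, strategy_mix = c(noisy_bayes = 1),
                       param_sampler = param_sampler, blocks = blocks,
                       seed = seed)
  generate_cohort(cfg)
}
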