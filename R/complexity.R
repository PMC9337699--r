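# Strategy-complexity analysis: plug-in mutual information between
# observations and responses, bootstrap distributions, the rate-distortion
# accuracy bound, and algorithmic operation counts.

#' Plug-in mutual information between observations and responses
#'
#' Empirical mutual information (in bits) between the observation class
#' (rare-ball count, sample length) and the response, from the empirical
#' joint distribution over the responded trials; only observed cells enter
#' the sum. With \code{include_prev = TRUE} the previous response joins the
#' observation variable (the first trial, which has no predecessor, is
#' dropped); subjects with sequential choice dependencies then show a higher
#' value.
#'
#' @param trials Trial data for one subject-block, in presentation order.
#' @param include_prev Include the previous response in the conditioning
#'   variable.
#' @return Mutual information in bits (>= 0).
#' @export
empirical_mi <- function(trials, include_prev = FALSE) {
  tr <- trials[!is.na(trials$response), , drop = FALSE]
  if (nrow(tr) == 0L) stop("no responded trials", call. = FALSE)
  obs <- paste(tr$rare_count, tr$n)
  r <- tr$response
  if (include_prev) {
    if (nrow(tr) < 2L) stop("previous-response MI needs >= 2 trials", call. = FALSE)
    obs <- paste(obs, c(NA, r[-length(r)]))[-1L]
    r <- r[-1L]
  }
  plugin_mi(obs, r)
}

plugin_mi <- function(obs, r) {
  n <- length(r)
  joint <- table(obs, r) / n
  p_obs <- rowSums(joint)
  p_r <- colSums(joint)
  mi <- 0
  for (i in seq_along(p_obs)) for (j in seq_along(p_r)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (p_obs[i] * p_r[j]))
  }
  max(mi, 0)
}

#' Fraction of correct responses
#'
#' @param trials Trial data with responses and true source jars.
#' @export
response_accuracy <- function(trials) {
  tr <- trials[!is.na(trials$response), , drop = FALSE]
  mean(tr$response == tr$jar)
}

#' Bootstrap distributions of MI and accuracy
#'
#' Uniform with-replacement resamples of the responded trials (same size as
#' the original data), with plug-in MI and accuracy computed per resample.
#' When \code{include_prev} is set, the resampling unit is the derived
#' (observation, previous response, response) triple so the sequential
#' pairing is preserved.
#'
#' @param trials Trial data for one subject-block.
#' @param n_boot Number of resamples (default 1000).
#' @param seed RNG seed.
#' @param include_prev Passed to the MI definition.
#' @return Data frame with columns \code{mi} and \code{accuracy}, one row per
#'   resample.
#' @export
bootstrap_mi_accuracy <- function(trials, n_boot = 1000L, seed = 1L,
                                  include_prev = FALSE) {
  set.seed(seed)
  tr <- trials[!is.na(trials$response), , drop = FALSE]
  obs <- paste(tr$rare_count, tr$n)
  r <- tr$response
  correct <- tr$response == tr$jar
  if (include_prev) {
    obs <- paste(obs, c(NA, r[-length(r)]))[-1L]
    correct <- correct[-1L]
    r <- r[-1L]
  }
  n <- length(r)
  out <- matrix(0, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    out[b, 1L] <- plugin_mi(obs[idx], r[idx])
    out[b, 2L] <- mean(correct[idx])
  }
  data.frame(mi = out[, 1L], accuracy = out[, 2L])
}

# ---- rate-distortion accuracy bound ----------------------------------------

# observation classes of a block: p(class) mixes the two jars with the block
# prior and the sample lengths uniformly; Q is the ideal observer's
# probability that "high" is correct given the class.
block_policy_classes <- function(block) {
  out <- do.call(rbind, lapply(block$sample_lengths, function(n) {
    k <- 0:n
    z <- llr_by_count(block, n)
    p_class <- (block$prior_high * stats::dbinom(k, n, block$h_plus) +
                  (1 - block$prior_high) * stats::dbinom(k, n, block$h_minus)) /
      length(block$sample_lengths)
    data.frame(n = n, k = k, p = p_class, z = as.numeric(z))
  }))
  out$q_high <- 1 / (1 + exp(-out$z))
  out
}

#' Ideal response policy of a block
#'
#' The deterministic step policy of the ideal observer over observation
#' classes (rare count, sample length): respond "high" with probability 1
#' where the LLR is positive, 0 where negative, and 0.5 on an exact tie.
#'
#' @param block A [block_config()].
#' @return Data frame with the class probabilities \code{p}, the LLR
#'   \code{z}, the value entries \code{q_high} and the policy column
#'   \code{pi_high}.
#' @export
ideal_policy <- function(block) {
  cl <- block_policy_classes(block)
  cl$pi_high <- as.numeric(cl$z > 1e-12) + 0.5 * (abs(cl$z) <= 1e-12)
  cl
}

#' Mutual information and value of a policy
#'
#' Analytic MI (bits) between observation class and response, and expected
#' accuracy, for a stochastic policy over a block's observation classes in
#' the limit of many trials.
#'
#' @param policy Data frame as returned by [ideal_policy()] (columns
#'   \code{p}, \code{q_high}, \code{pi_high}).
#' @return Named vector \code{c(mi, value)}.
#' @export
policy_mi_value <- function(policy) {
  pi_hi <- clip(policy$pi_high, 0, 1)
  q_r <- sum(policy$p * pi_hi)  # marginal probability of responding high
  term <- function(pi_c, q) ifelse(pi_c > 0, pi_c * log2(pi_c / q), 0)
  mi <- sum(policy$p * (term(pi_hi, q_r) + term(1 - pi_hi, 1 - q_r)))
  value <- sum(policy$p * (pi_hi * policy$q_high +
                             (1 - pi_hi) * (1 - policy$q_high)))
  c(mi = max(mi, 0), value = value)
}

# Maximize V - lambda * I by alternating maximization (exact for this
# convex-dual problem): pi(r|c) proportional to q(r) exp(ln2 * Q(c,r)/lambda),
# q(r) updated to the induced response marginal.
policy_at_lambda <- function(classes, lambda, tol = 1e-13, max_iter = 2000L) {
  q <- c(0.5, 0.5)
  # log-odds form avoids overflow of exp(Q/lambda) at small lambda
  dq <- log(2) * (2 * classes$q_high - 1) / lambda
  for (i in seq_len(max_iter)) {
    pi_hi <- stats::plogis(log(q[1L]) - log(q[2L]) + dq)
    q_new <- c(sum(classes$p * pi_hi), sum(classes$p * (1 - pi_hi)))
    if (max(abs(q_new - q)) < tol) break
    q <- q_new
  }
  classes$pi_high <- pi_hi
  classes
}

#' Rate-distortion accuracy bound
#'
#' Maximum expected accuracy \eqn{V^*} attainable on a block by any
#' stochastic response policy whose mutual information with the observation
#' class equals the budget \code{C}:
#' \deqn{V^* = \max_\pi \sum_c p(c) \sum_r \pi(r|c)\, Q(c, r)
#'   \quad \text{s.t.}\quad I_\pi = C.}
#' The value entries come from the ideal observer,
#' \eqn{Q(c, \mathrm{high}) = 1/(1 + e^{-z})} and its complement for "low";
#' class probabilities mix the jars with the block prior and the sample
#' lengths uniformly. Because the objective is linear and the constraint set
#' convex in the policy, the optimum is found exactly on the dual path: the
#' bound is traced by alternating maximization of \eqn{V - \lambda I} with a
#' bisection on \eqn{\lambda} until \eqn{I_\pi = C} to within \code{tol}.
#' \eqn{V^*(C)} is nondecreasing and concave; at \code{C = 0} it equals the
#' better constant policy and at the MI of the ideal step policy it equals
#' the ideal observer's expected accuracy.
#'
#' @param block A [block_config()].
#' @param C MI budget in bits; must lie in [0, MI of the ideal policy].
#' @param tol Constraint tolerance on the achieved MI (bits).
#' @return List with \code{value} (\eqn{V^*}), the achieved \code{mi}, the
#'   multiplier \code{lambda} and the optimal \code{policy}.
#' @export
accuracy_bound <- function(block, C, tol = 1e-6) {
  classes <- block_policy_classes(block)
  ideal <- ideal_policy(block)
  top <- policy_mi_value(ideal)
  if (C < 0 || C > top[["mi"]] + tol)
    stop(sprintf("MI budget must lie in [0, %.6f] for this block", top[["mi"]]),
         call. = FALSE)
  if (C >= top[["mi"]] - tol)
    return(list(value = top[["value"]], mi = top[["mi"]], lambda = 0,
                policy = ideal))
  if (C <= tol) {
    v0 <- max(sum(classes$p * classes$q_high),
              sum(classes$p * (1 - classes$q_high)))
    classes$pi_high <- as.numeric(sum(classes$p * classes$q_high) >=
                                    sum(classes$p * (1 - classes$q_high)))
    return(list(value = v0, mi = 0, lambda = Inf, policy = classes))
  }
  # I(lambda) decreases in lambda; bracket then bisect
  lo <- 1e-4; hi <- 1
  while (policy_mi_value(policy_at_lambda(classes, hi))[["mi"]] > C && hi < 1e6)
    hi <- hi * 2
  while (policy_mi_value(policy_at_lambda(classes, lo))[["mi"]] < C && lo > 1e-12)
    lo <- lo / 2
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    pol <- policy_at_lambda(classes, mid)
    mv <- policy_mi_value(pol)
    if (abs(mv[["mi"]] - C) < tol) break
    if (mv[["mi"]] > C) lo <- mid else hi <- mid
  }
  list(value = mv[["value"]], mi = mv[["mi"]], lambda = mid, policy = pol)
}

#' Accuracy-bound curve over a grid of MI budgets
#'
#' @param block A [block_config()].
#' @param C_grid MI budgets; defaults to 25 points spanning [0, MI of the
#'   ideal policy].
#' @return Data frame with columns \code{C} and \code{V}.
#' @export
accuracy_bound_curve <- function(block, C_grid = NULL) {
  if (is.null(C_grid)) {
    top <- policy_mi_value(ideal_policy(block))[["mi"]]
    C_grid <- seq(0, top, length.out = 25L)
  }
  data.frame(C = C_grid,
             V = vapply(C_grid, function(C) accuracy_bound(block, C)$value,
                        numeric(1)))
}

#' Algorithmic complexity of a strategy
#'
#' Operation count per trial, split into arithmetic (A), write (W), store
#' (S) and read (R) operations, plus a constant reflexive cost shared by all
#' models (0 by default; it affects no comparison). Heuristic strategies
#' cost the same for every sample length; Bayesian strategies scale with the
#' number of balls:
#' \itemize{
#'   \item guess: read and store the guess probability;
#'   \item rare ball: detect the presence of a rare ball (one max
#'     operation), read the response probability, store both probability
#'     parameters;
#'   \item variable rare ball: additionally count the rare balls and store
#'     the threshold;
#'   \item set rho: one multiplication per ball and n - 1 additions;
#'   \item noisy Bayesian: set rho plus reading and storing the rare-ball
#'     weight;
#'   \item prior Bayesian: noisy Bayesian plus reading and storing the prior.
#' }
#'
#' @param model Model tag.
#' @param n Sample length (used by Bayesian models only).
#' @param c_reflex Constant reflexive cost.
#' @return List with \code{total} and components \code{A}, \code{W},
#'   \code{S}, \code{R}, \code{c_reflex}.
#' @export
algorithmic_complexity <- function(model, n, c_reflex = 0) {
  model <- match.arg(model, ALL_MODELS)
  ops <- switch(model,
    guess = c(A = 0, W = 0, S = 1, R = 1),
    rare_ball = c(A = 1, W = 0, S = 2, R = 1),
    variable_rare = c(A = 2, W = 0, S = 3, R = 1),
    noisy_bayes_set_rho = c(A = 2 * n - 1, W = 0, S = 0, R = 0),
    noisy_bayes = c(A = 2 * n - 1, W = 0, S = 1, R = 1),
    prior_bayes = c(A = 2 * n - 1, W = 0, S = 2, R = 2))
  c(as.list(ops), total = unname(sum(ops)) + c_reflex, c_reflex = c_reflex)
}

#' Complexity results for one subject-block
#'
#' Convenience wrapper assembling MI (with and without the previous
#' response), accuracy, the bound value at the subject's MI, and the
#' algorithmic complexity of the selected model (mean over the block's
#' sample lengths for Bayesian models).
#'
#' @param trials Trial data for one subject-block.
#' @param block The [block_config()].
#' @param selected_model Model tag from [select_model()].
#' @return One-row data frame.
#' @export
complexity_result <- function(trials, block, selected_model) {
  mi <- empirical_mi(trials)
  mi_prev <- tryCatch(empirical_mi(trials, include_prev = TRUE),
                      error = function(e) NA_real_)
  acc <- response_accuracy(trials)
  top <- policy_mi_value(ideal_policy(block))[["mi"]]
  bound <- accuracy_bound(block, min(mi, top))$value
  algc <- mean(vapply(block$sample_lengths, function(n)
    algorithmic_complexity(selected_model, n)$total, numeric(1)))
  data.frame(block = block$name, mi = mi, mi_with_prev = mi_prev,
             accuracy = acc, bound_value = bound,
             algorithmic_complexity = algc,
             selected_model = selected_model)
}
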