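# Mutual information, bootstrap, the rate-distortion accuracy bound, and
# algorithmic operation counts.

test_that("plug-in MI hits its analytic limits", {
  ha <- blocks$HA
  tr <- sim_subject(ha, observer_params("guess", p_guess = 1), seed = 111)
  expect_identical(empirical_mi(tr), 0)  # constant response: zero entropy
  # deterministic response policy: MI equals the empirical response entropy
  tr2 <- sample_block_trials(ha, seed = 112)
  tr2$response <- ifelse(tr2$rare_count >= 1, "high", "low")
  p <- mean(tr2$response == "high")
  expect_equal(empirical_mi(tr2), -p * log2(p) - (1 - p) * log2(1 - p),
               tolerance = 1e-12)
  # bounded above by the response entropy on any dataset
  tr3 <- sim_subject(ha, observer_params("noisy_bayes", a = 0.5, rho = 3),
                     seed = 113)
  p3 <- mean(tr3$response == "high")
  expect_lte(empirical_mi(tr3), -p3 * log2(p3) - (1 - p3) * log2(1 - p3) + 1e-12)
  expect_gte(empirical_mi(tr3), 0)
})

test_that("plug-in MI matches an independent summation oracle to 1e-12", {
  set.seed(114)
  tr <- sim_class_trials(blocks$EA, observer_params("noisy_bayes", a = 0.7,
                                                    rho = 2.2), 300, seed = 115)
  mi_pkg <- empirical_mi(tr)
  # oracle: explicit loops over the empirical joint
  cells <- unique(tr[, c("rare_count", "n", "response")])
  N <- nrow(tr)
  mi <- 0
  for (i in seq_len(nrow(cells))) {
    pj <- sum(tr$rare_count == cells$rare_count[i] & tr$n == cells$n[i] &
                tr$response == cells$response[i]) / N
    po <- sum(tr$rare_count == cells$rare_count[i] & tr$n == cells$n[i]) / N
    pr <- sum(tr$response == cells$response[i]) / N
    mi <- mi + pj * log2(pj / (po * pr))
  }
  expect_equal(mi_pkg, mi, tolerance = 1e-12)
  # conditioning on the previous response can only refine the observation
  # partition of the same (shortened) dataset
  expect_gte(empirical_mi(tr, include_prev = TRUE) + 1e-9,
             empirical_mi(tr[-1L, ]))
})

test_that("bootstrap distributions behave at their edges and are reproducible", {
  ha <- blocks$HA
  tr <- sim_subject(ha, observer_params("guess", p_guess = 1), seed = 116)
  bs <- bootstrap_mi_accuracy(tr, n_boot = 50L, seed = 1L)
  expect_true(all(bs$mi == 0))
  const <- tr; const$jar <- "high"  # constant responses and correctness
  bs_const <- bootstrap_mi_accuracy(const, n_boot = 50L, seed = 1L)
  expect_true(all(bs_const$mi == 0) && all(bs_const$accuracy == 1))
  tr2 <- sim_subject(ha, observer_params("guess", p_guess = 0.6), seed = 117)
  b1 <- bootstrap_mi_accuracy(tr2, n_boot = 100L, seed = 2L)
  b2 <- bootstrap_mi_accuracy(tr2, n_boot = 100L, seed = 2L)
  expect_identical(b1, b2)
  # on sample-independent data the plug-in MI is upward-biased and the
  # bootstrap mean exceeds the already-biased point estimate
  expect_gt(mean(b1$mi), empirical_mi(tr2))
})

test_that("the accuracy bound has the stated endpoints, monotonicity and concavity", {
  for (bn in c("HA", "EA")) {
    block <- blocks[[bn]]
    top <- policy_mi_value(ideal_policy(block))
    # C at the ideal policy's MI returns the ideal observer's accuracy
    at_top <- accuracy_bound(block, top[["mi"]])
    expect_equal(at_top$value, top[["value"]], tolerance = 1e-9)
    # C = 0 returns the better constant policy, evaluated in closed form
    cl <- jarinfer:::block_policy_classes(block)
    v0 <- max(sum(cl$p * cl$q_high), sum(cl$p * (1 - cl$q_high)))
    expect_equal(accuracy_bound(block, 0)$value, v0, tolerance = 1e-12)
    # interior budgets meet the MI constraint to tolerance
    mid <- accuracy_bound(block, top[["mi"]] / 3)
    expect_lt(abs(mid$mi - top[["mi"]] / 3), 1e-5)
    expect_error(accuracy_bound(block, top[["mi"]] + 0.1), "budget")
    curve <- accuracy_bound_curve(block,
                                  seq(0, top[["mi"]], length.out = 12L))
    expect_true(all(diff(curve$V) > -1e-9))           # nondecreasing
    expect_true(all(diff(diff(curve$V)) < 1e-6))      # concave
  }
})

test_that("simulated observers respect the asymptotic accuracy bound", {
  block <- blocks$HA
  top <- policy_mi_value(ideal_policy(block))
  for (pars in list(observer_params("noisy_bayes_set_rho", a = 0.3),
                    observer_params("rare_ball", p_rare = 0.9, p_no = 0.85))) {
    tr <- sim_class_trials(block, pars, 3e4, seed = 118)
    mi <- empirical_mi(tr)
    acc <- response_accuracy(tr)
    bound <- accuracy_bound(block, min(mi, top[["mi"]]))$value
    expect_lte(acc, bound + 0.01)  # small slack for finite-sample MI bias
  }
})

test_that("operation counts reproduce the per-strategy table and its ordering", {
  expect_equal(algorithmic_complexity("guess", 5)$total, 2)       # read + store
  expect_equal(algorithmic_complexity("rare_ball", 5)$total, 4)
  expect_equal(algorithmic_complexity("variable_rare", 5)$total, 6)
  expect_equal(algorithmic_complexity("noisy_bayes_set_rho", 5)$total, 9)
  expect_equal(algorithmic_complexity("noisy_bayes", 5)$total, 11)
  expect_equal(algorithmic_complexity("prior_bayes", 5)$total, 13)
  expect_equal(algorithmic_complexity("guess", 5, c_reflex = 3)$total, 5)
  # Bayesian cost scales with the sample length; heuristics do not
  expect_gt(algorithmic_complexity("noisy_bayes_set_rho", 10)$total,
            algorithmic_complexity("noisy_bayes_set_rho", 2)$total)
  expect_equal(algorithmic_complexity("rare_ball", 10)$total,
               algorithmic_complexity("rare_ball", 2)$total)
  # every Bayesian model's mean cost over {2, 5, 10} exceeds every heuristic's
  mean_cost <- function(m) mean(vapply(c(2, 5, 10), function(n)
    algorithmic_complexity(m, n)$total, numeric(1)))
  bayes <- vapply(c("noisy_bayes", "noisy_bayes_set_rho", "prior_bayes"),
                  mean_cost, numeric(1))
  heur <- vapply(c("variable_rare", "rare_ball", "guess"), mean_cost,
                 numeric(1))
  expect_gt(min(bayes), max(heur))
})

test_that("per-subject complexity rows assemble coherently", {
  ha <- blocks$HA
  tr <- sim_subject(ha, observer_params("noisy_bayes_set_rho", a = 0.2),
                    seed = 119)
  row <- complexity_result(tr, ha, "noisy_bayes_set_rho")
  expect_equal(row$block, "HA")
  expect_gte(row$bound_value, 0.5)
  expect_true(row$mi >= 0 && row$accuracy >= 0 && row$accuracy <= 1)
  expect_equal(row$algorithmic_complexity,
               mean(c(3, 9, 19)))  # 2n - 1 over n in {2, 5, 10}
})
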