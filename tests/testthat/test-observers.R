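# The six observer models: closed-form response probabilities and
# stochastic simulation.

test_that("noisy-Bayes probability reproduces the error-function closed form", {
  skip_if_not_installed("pracma")
  ha <- blocks$HA
  trial <- data.frame(rare_count = 1L, n = 5L)  # sample (-1,-1,+1,-1,-1)
  for (rho in c(1, 2.5, 4, 6)) for (a in c(0.1, 0.5, 1.2)) {
    p <- bayes_response_prob(observer_params("noisy_bayes", a = a, rho = rho),
                             trial, ha)
    expect_lt(abs(p - 0.5 * (1 - pracma::erf((4 - rho) / sqrt(2 * a^2)))),
              1e-12)
  }
  # rho = 4 puts the mean belief at zero: probability one half for any noise
  for (a in c(0.2, 1, 3))
    expect_equal(bayes_response_prob(
      observer_params("noisy_bayes", a = a, rho = 4), trial, ha), 0.5)
  # noiseless limit degenerates to the step rule
  expect_equal(bayes_response_prob(
    observer_params("noisy_bayes", a = 0, rho = 5), trial, ha), 1)
  expect_equal(bayes_response_prob(
    observer_params("noisy_bayes", a = 0, rho = 3), trial, ha), 0)
  expect_equal(bayes_response_prob(
    observer_params("noisy_bayes", a = 0, rho = 4), trial, ha), 0.5)
})

test_that("prior model with a flat prior reduces to the set-rho model", {
  ea <- blocks$EA
  trials <- expand.grid(rare_count = 0:5, n = 5L)
  for (a in c(0, 0.3, 1))
    expect_equal(
      bayes_response_prob(observer_params("prior_bayes", a = a, z0 = 0),
                          trials, ea),
      bayes_response_prob(observer_params("noisy_bayes_set_rho", a = a),
                          trials, ea))
})

test_that("closed-form Bayesian probabilities match Monte-Carlo of the belief", {
  set.seed(41)
  ha <- blocks$HA
  n_mc <- 1e5
  cases <- list(
    list(p = observer_params("noisy_bayes", a = 0.6, rho = 3), k = 1, n = 5),
    list(p = observer_params("noisy_bayes_set_rho", a = 0.4), k = 2, n = 10),
    list(p = observer_params("prior_bayes", a = 0.8, z0 = -1.2), k = 1, n = 2))
  for (cs in cases) {
    rho <- if (cs$p$model == "noisy_bayes") cs$p$rho else rho_io(ha)
    z0 <- if (cs$p$model == "prior_bayes") cs$p$z0 else 0
    m <- z0 + rho * cs$k - (cs$n - cs$k)
    mc <- mean(m + rnorm(n_mc, 0, cs$p$a) > 0)
    closed <- bayes_response_prob(cs$p, data.frame(rare_count = cs$k, n = cs$n), ha)
    expect_lt(abs(mc - closed), 3 * sqrt(closed * (1 - closed) / n_mc) + 1e-4)
  }
})

test_that("noiseless set-rho observer reproduces the ideal choice everywhere", {
  pars <- observer_params("noisy_bayes_set_rho", a = 0)
  for (block in blocks) for (n in 1:10) for (k in 0:n) {
    z <- ideal_belief(block, c(rep(1L, k), rep(-1L, n - k)))
    p <- bayes_response_prob(pars, data.frame(rare_count = k, n = n), block)
    if (abs(z) < 1e-12) expect_equal(p, 0.5)
    else expect_equal(p, as.numeric(z > 0))
  }
})

test_that("Bayesian response probability is nondecreasing in the rare count", {
  for (pars in list(observer_params("noisy_bayes", a = 0.5, rho = 3),
                    observer_params("noisy_bayes_set_rho", a = 0.2),
                    observer_params("prior_bayes", a = 0.7, z0 = -2)))
    for (n in c(2, 5, 10)) {
      p <- bayes_response_prob(pars, data.frame(rare_count = 0:n, n = n),
                               blocks$EA)
      expect_true(all(diff(p) >= 0))
    }
})

test_that("heuristic rules branch on the threshold and ignore sample length", {
  vr <- observer_params("variable_rare", theta = 2, p_rare = 0.9, p_no = 0.8)
  expect_equal(heuristic_response_prob(vr, data.frame(rare_count = 3, n = 10)), 0.9)
  expect_equal(heuristic_response_prob(vr, data.frame(rare_count = 1, n = 10)), 0.2)
  # rare-ball endpoints reproduce the deterministic any-rare-ball rule
  rb <- observer_params("rare_ball", p_rare = 1, p_no = 1)
  expect_equal(heuristic_response_prob(rb, data.frame(rare_count = c(0, 1, 4),
                                                      n = c(5, 5, 10))),
               c(0, 1, 1))
  # guess ignores the sample entirely, including an empty one
  g <- observer_params("guess", p_guess = 0.5)
  expect_equal(heuristic_response_prob(g, data.frame(rare_count = c(0, 0, 5),
                                                     n = c(0, 10, 10))),
               rep(0.5, 3))
  # invariance to n at fixed rare count (the source of LLR-independent variance)
  for (pars in list(vr, rb)) {
    p <- heuristic_response_prob(pars, data.frame(rare_count = 2, n = c(2, 5, 10)))
    expect_equal(length(unique(p)), 1L)
  }
})

test_that("model tags guard their parameter sets and dispatch", {
  expect_error(observer_params("noisy_bayes", a = 0.1), "exactly the parameters")
  expect_error(observer_params("guess", p_guess = 1.2), "0, 1")
  expect_error(observer_params("noisy_bayes", a = -1, rho = 2), ">= 0")
  expect_error(observer_params("variable_rare", theta = 0.5, p_rare = 1, p_no = 1),
               "positive integer")
  g <- observer_params("guess", p_guess = 0.7)
  expect_error(bayes_response_prob(g, data.frame(rare_count = 1, n = 2),
                                   blocks$HA), "Bayesian")
  nb <- observer_params("noisy_bayes", a = 1, rho = 1)
  expect_error(heuristic_response_prob(nb, data.frame(rare_count = 1, n = 2)),
               "heuristic")
})

test_that("response simulation is reproducible and matches its probabilities", {
  tr <- sample_block_trials(blocks$EA, seed = 51)
  g1 <- simulate_responses(observer_params("guess", p_guess = 1), tr, seed = 52)
  expect_true(all(g1$response == "high"))
  pars <- observer_params("noisy_bayes", a = 0.4, rho = 2.5)
  s1 <- simulate_responses(pars, tr, blocks$EA, seed = 53)
  s2 <- simulate_responses(pars, tr, blocks$EA, seed = 53)
  expect_identical(s1$response, s2$response)
  # empirical high-response rate per class matches the closed form
  one <- tr[rep(which(tr$rare_count == 1 & tr$n == 5)[1], 10000), ]
  sim <- simulate_responses(pars, one, blocks$EA, seed = 54)
  p <- bayes_response_prob(pars, one[1, ], blocks$EA)
  expect_lt(abs(mean(sim$response == "high") - p),
            3 * sqrt(p * (1 - p) / 10000))
})
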