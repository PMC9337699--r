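# Grid posteriors: normalization, invariances, oracle equivalence of the
# marginal likelihood, credible regions, informative-prior construction.

test_that("posterior equals the prior with no data and always normalizes", {
  ha <- blocks$HA
  empty <- sample_block_trials(ha, seed = 1)  # responses all NA
  post <- fit_posterior("guess", empty, ha)
  expect_equal(post$post, rep(1 / 101, 101))
  custom <- dnorm(seq(0, 1, 0.01), 0.5, 0.1)
  post2 <- fit_posterior("guess", empty, ha, prior = custom)
  expect_equal(post2$post, custom / sum(custom))
  tr <- sim_subject(ha, observer_params("noisy_bayes", a = 0.3, rho = 3), seed = 2)
  for (m in c("noisy_bayes", "variable_rare", "guess")) {
    p <- fit_posterior(m, tr, ha)
    expect_equal(sum(p$post), 1, tolerance = 1e-10)
  }
})

test_that("posterior is invariant to trial order", {
  ha <- blocks$HA
  tr <- sim_subject(ha, observer_params("rare_ball", p_rare = 0.8, p_no = 0.9),
                    seed = 3)
  p1 <- fit_posterior("rare_ball", tr, ha)
  set.seed(4)
  p2 <- fit_posterior("rare_ball", tr[sample.int(nrow(tr)), ], ha)
  expect_equal(p1$post, p2$post)
  expect_equal(p1$log_marginal, p2$log_marginal)
})

test_that("log marginal likelihood matches an independently coded dense-grid sum", {
  ea <- blocks$EA
  tr <- sim_subject(ea, observer_params("noisy_bayes", a = 0.4, rho = 2), seed = 5)
  grid <- list(a = seq(0.05, 1, by = 0.05), rho = seq(0.25, 6, by = 0.25))
  lm_pkg <- log_marginal_likelihood("noisy_bayes", tr, ea, grid = grid)
  # oracle: plain loops over cells and trials, likelihood written out by hand
  total <- 0
  for (rho in grid$rho) for (a in grid$a) {
    ll <- 0
    for (i in seq_len(nrow(tr))) {
      m <- rho * tr$rare_count[i] - (tr$n[i] - tr$rare_count[i])
      p <- pnorm(m / a)
      pr <- if (tr$response[i] == "high") p else 1 - p
      ll <- ll + log(max(pr, 1e-10))
    }
    total <- total + exp(ll)
  }
  expect_equal(lm_pkg, log(total / (length(grid$a) * length(grid$rho))),
               tolerance = 1e-6)
})

test_that("guess marginal matches the analytic Beta integral", {
  ha <- blocks$HA
  tr <- sim_subject(ha, observer_params("guess", p_guess = 0.7), seed = 6)
  k <- sum(tr$response == "high"); N <- nrow(tr)
  lm_grid <- log_marginal_likelihood("guess", tr, ha)
  # ordered-response likelihood integrated against a flat prior; the grid
  # places probability mass on 101 points, so the estimate carries an
  # O(step) normalization drift (log(1/1.01) ~ -0.01) relative to the
  # continuous integral
  lm_exact <- lbeta(k + 1, N - k + 1)
  expect_lt(abs(lm_grid - lm_exact), 0.02)
  # refining the grid twofold halves that drift
  lm_fine <- log_marginal_likelihood("guess", tr, ha,
                                     grid = list(p_guess = seq(0, 1, 0.005)))
  expect_lt(abs(lm_fine - lm_grid), 5e-3)
  expect_lt(abs(lm_fine - lm_exact), abs(lm_grid - lm_exact))
})

test_that("credible regions degenerate correctly and report their mass", {
  ha <- blocks$HA
  empty <- sample_block_trials(ha, seed = 7)
  # near-delta prior: the region is a single cell
  delta <- c(rep(1e-12, 50), 1, rep(1e-12, 50))
  cred <- mle_and_credible(fit_posterior("guess", empty, ha, prior = delta))
  expect_equal(length(cred$member), 1L)
  expect_equal(unname(cred$estimate), 0.50)
  # uniform posterior: the region must cover at least 95% of cells
  cred_u <- mle_and_credible(fit_posterior("guess", empty, ha))
  expect_gte(length(cred_u$member), ceiling(0.95 * 101))
  expect_gte(cred_u$mass, 0.95)
})

test_that("95% credible regions cover the generating parameters", {
  # Bayesian self-consistency: parameters drawn from the fitting prior fall
  # in the 95% highest-density region in at least ~80% of datasets
  ha <- blocks$HA
  set.seed(8)
  for (model in c("noisy_bayes", "noisy_bayes_set_rho", "prior_bayes",
                  "variable_rare", "rare_ball", "guess")) {
    tab <- jarinfer:::model_fit_table(model, ha)
    hits <- vapply(1:40, function(i) {
      truth <- jarinfer:::draw_params_from_prior(model, ha, NULL, tab)
      tr <- simulate_responses(truth, sample_block_trials(ha), ha)
      post <- jarinfer:::posterior_from_table(tab, jarinfer:::trial_classes(tr))
      in_credible_region(post, truth[jarinfer:::MODEL_PARAMS[[model]]])
    }, logical(1))
    expect_gte(mean(hits), 0.8)
  }
})

test_that("informative prior smooths pilot posteriors as specified", {
  ha <- blocks$HA
  hs <- blocks$HS
  tab <- jarinfer:::model_fit_table("noisy_bayes", ha)
  set.seed(9)
  posts <- lapply(1:4, function(i) {
    tr <- sim_subject(ha, observer_params("noisy_bayes", a = 0.2,
                                          rho = runif(1, 2, 4)), seed = 10 + i)
    jarinfer:::posterior_from_table(tab, jarinfer:::trial_classes(tr))
  })
  prior <- build_informative_prior(posts, ha)
  # symmetry-based constants and strict positivity
  expect_equal(prior$c_const, 2); expect_equal(prior$L_const, 1)
  expect_true(all(prior$mass > 0))
  expect_equal(sum(prior$mass), 1, tolerance = 1e-12)
  prior_sym <- build_informative_prior(posts, hs)
  expect_equal(prior_sym$c_const, 5); expect_equal(prior_sym$L_const, 2)
  # c -> infinity flattens the noise marginal
  flat_a <- build_informative_prior(posts, ha, c_const = 1e9)
  expect_equal(flat_a$a_mass, rep(1 / 101, 101), tolerance = 1e-6)
  # expansion to the other Bayesian models' grids
  expect_equal(model_prior("noisy_bayes_set_rho", ha, prior,
                           list(a = prior$axes$a)), prior$a_mass)
  pb <- model_prior("prior_bayes", ha, prior, param_grid("prior_bayes"))
  expect_equal(sum(pb), 1, tolerance = 1e-12)
  # heuristics stay flat regardless
  expect_equal(model_prior("guess", ha, prior, param_grid("guess")),
               rep(1 / 101, 101))
  expect_error(build_informative_prior(list(), ha), "at least one")
})

test_that("posterior concentration and mass-window utilities agree", {
  ea <- blocks$EA
  truth <- observer_params("noisy_bayes", a = 0.1, rho = rho_io(ea))
  tr <- sim_subject(ea, truth, seed = 20, n_trials = 60L)
  post <- fit_posterior("noisy_bayes", tr, ea)
  mass <- posterior_mass_near(post, list(a = 0.1, rho = truth$rho), window = 1)
  # manual recomputation over the cell table
  keep <- abs(post$cells$a - 0.1) <= 1 & abs(post$cells$rho - truth$rho) <= 1
  expect_equal(mass, sum(post$post[keep]))
  expect_gt(mass, 0.4)
})
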