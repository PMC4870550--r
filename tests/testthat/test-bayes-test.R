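test_that("q updates follow the Beta(1 + eta, 2 - eta) conditional", {
  set.seed(21)
  q1 <- replicate(1e5, sample_q(1))
  q0 <- replicate(1e5, sample_q(0))
  expect_equal(mean(q1), 2/3, tolerance = 0.005)
  expect_equal(mean(q0), 1/3, tolerance = 0.005)
  expect_true(all(q1 > 0 & q1 < 1))
})

test_that("conditional inclusion probability follows the posterior odds", {
  expect_equal(eta_probability(0, 0, 0.5), 0.5)
  expect_equal(eta_probability(log(9), 0, 0.5), 0.9)
  expect_equal(eta_probability(-5, 3, 0.999999), 1, tolerance = 1e-2)
  # equal likelihoods at gamma = 0
  ds <- survival_dataset(c(1, 2, 3), c(1, 1, 0), c(0, 1, 1))
  cb <- build_basis(list(lo = 0, hi = 6), degree = 0, n_basis = 1)
  expect_equal(eta_probability(log_p1(ds, 0, cb), log_p0(ds), 0.5), 0.5)
  set.seed(22)
  draws <- replicate(2000, sample_eta(ds, 0, cb, 0.9))
  expect_equal(mean(draws), 0.9, tolerance = 0.03)
})

test_that("coefficient sweep samples the truncated-normal prior when the
           likelihood carries no information", {
  prior <- prior_spec(sigma2 = 1, L = 10)
  basis <- build_basis(list(lo = 1, hi = 4), degree = 2, n_basis = 3)
  ds <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
  # eta = 0: exact prior draws
  set.seed(23)
  g <- t(replicate(1e4, sample_gamma(ds, list(gamma = rep(0, 3), eta = 0,
                                              q = 0.5), basis, prior)))
  expect_true(all(abs(colMeans(g)) < 3 / sqrt(1e4)))
  expect_equal(unname(apply(g, 2, var)), rep(1, 3), tolerance = 0.05)
  expect_true(all(abs(g) < prior$L))

  # eta = 1 with single-group data: P1 is constant in gamma, so one MH
  # sweep per iteration still targets the prior
  ds0 <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), rep(0, 4))
  set.seed(24)
  st <- list(gamma = rep(0, 3), eta = 1, q = 0.5)
  keep <- matrix(NA_real_, 4e3, 3)
  for (i in seq_len(2e4)) {
    st$gamma <- sample_gamma(ds0, st, basis, prior,
                             mcmc_config(proposal_sd = 1.5))
    if (i > 4e3 && i %% 4 == 0) keep[(i - 4e3) / 4, ] <- st$gamma
  }
  expect_true(all(abs(colMeans(keep)) < 0.06))
  expect_equal(unname(apply(keep, 2, var)), rep(1, 3), tolerance = 0.1)
})

test_that("posterior inclusion probability agrees with the 1-D quadrature
           oracle for a single constant basis", {
  prior <- prior_spec()
  set.seed(25)
  for (i in 1:3) {
    ds <- simulate_survival(hazard_scenario("M1"), 10)
    cb <- build_basis(list(lo = 0, hi = ds$tau), degree = 0, n_basis = 1)
    truth <- oracle_post_eta_1d(ds, cb, prior)
    fit <- bayes_hazard_test(ds, degree = 0, n_basis = 1,
                             interval = list(lo = 0, hi = ds$tau),
                             prior = prior,
                             mcmc = mcmc_config(burn_in = 1000, thin = 5,
                                                n_keep = 2000, seed = i))
    # batch-means Monte-Carlo standard error of the kept conditional probs
    bm <- tapply(fit$kept$condp, rep(1:40, each = 50), mean)
    se <- sd(bm) / sqrt(length(bm))
    expect_lt(abs(fit$post_eta - truth), 3 * max(se, 0.005))
  }
})

test_that("flat likelihoods recover the prior P(eta = 1) = 1/2", {
  # zero events: P1 = P0 = 1 for every gamma
  ds <- survival_dataset(c(1, 2, 3, 4), c(0, 0, 0, 0), c(0, 0, 1, 1))
  fit <- bayes_hazard_test(ds, mcmc = mcmc_config(n_keep = 500, thin = 10,
                                                  seed = 26))
  expect_equal(fit$post_eta, 0.5, tolerance = 0.05)
  expect_false(fit$reject_null)

  # single-group data via an explicit interval: same recovery
  set.seed(260)
  ds0 <- survival_dataset(rexp(30, 0.3), rep(1, 30), rep(0, 30), tau = 1e6)
  fit0 <- bayes_hazard_test(ds0, interval = list(lo = 1, hi = 3),
                            mcmc = mcmc_config(n_keep = 500, thin = 10,
                                               seed = 27))
  expect_equal(fit0$post_eta, 0.5, tolerance = 0.05)
})

test_that("identical seeds give bit-identical chains", {
  set.seed(28)
  ds <- simulate_survival(hazard_scenario("M2"), 80)
  f1 <- bayes_hazard_test(ds, mcmc = mcmc_config(burn_in = 200, thin = 5,
                                                 n_keep = 100, seed = 5))
  f2 <- bayes_hazard_test(ds, mcmc = mcmc_config(burn_in = 200, thin = 5,
                                                 n_keep = 100, seed = 5))
  expect_identical(f1$kept, f2$kept)
  expect_identical(f1$post_eta, f2$post_eta)
})

test_that("cumulative mean of the inclusion probabilities stabilizes", {
  set.seed(29)
  ds <- simulate_survival(hazard_scenario("M1"), 200)
  fit <- bayes_hazard_test(ds, mcmc = mcmc_config(seed = 30))
  tr <- fit$diagnostics$cummean_condp
  half <- tr[(length(tr) / 2):length(tr)]
  expect_lt(max(half) - min(half), 0.05)
})

test_that("posterior inclusion probability trends with sample size", {
  reps <- 20
  post_mean <- function(model, n) {
    scn <- hazard_scenario(model)
    th <- calibrate_censoring(scn)
    mean(vapply(seq_len(reps), function(r) {
      ds <- simulate_survival(scn, n, seed = 3000 + r, theta = th)
      bayes_hazard_test(ds, mcmc = mcmc_config(seed = 4000 + r))$post_eta
    }, numeric(1)))
  }
  m3 <- vapply(c(50, 100, 200), post_mean, numeric(1), model = "M3")
  expect_true(all(diff(m3) >= 0))
  m0 <- vapply(c(50, 100, 200), post_mean, numeric(1), model = "M0")
  expect_true(all(diff(m0) <= 0))
})
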