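test_that("hyperbolic subjective value matches its closed form and limits", {
  expect_equal(subjective_value(20000, 0, 0.01), 20000)
  expect_equal(subjective_value(20000, 100, 0.01), 10000)
  expect_equal(subjective_value(10000, 180, 1e-9), 10000, tolerance = 1e-6)
  # strictly decreasing in delay and in k
  expect_true(all(diff(subjective_value(20000, c(0, 1, 10, 100), 0.05)) < 0))
  expect_lt(subjective_value(20000, 50, 0.05),
            subjective_value(20000, 50, 0.01))
  expect_error(subjective_value(-5, 10, 0.01), "positive")
  expect_error(subjective_value(20000, 10, 1.5), "k must")
})

test_that("softmax choice probability is symmetric, bounded and stable", {
  expect_equal(p_immediate(10000, 10000, 0.5), 0.5)
  expect_equal(p_immediate(10000, 9000, 0), 0.5)
  expect_equal(p_immediate(10000, 9000, 0.001), 1 / (1 + exp(-1)))
  # complement identity over a parameter sweep
  for (mu in c(0, 1e-4, 1e-2, 1)) {
    sv_i <- seq(8000, 12000, by = 500)
    expect_equal(p_immediate(sv_i, 10000, mu) +
                   p_immediate(10000, sv_i, mu),
                 rep(1, length(sv_i)))
  }
  # no overflow at extreme value differences
  expect_equal(p_immediate(1e6, 0, 1), 1)
  expect_equal(p_immediate(0, 1e6, 1), 0)
  expect_true(is.finite(p_immediate(0, 1e6, 1, log.p = TRUE)))
})

test_that("negative log-likelihood equals the per-trial product oracle", {
  fx <- random_trial_fixture(10L, seed = 314L)
  k <- 0.015; mu <- 4e-4
  sv <- fx$delayed_krw / (1 + k * fx$delay_days)
  p_imm <- 1 / (1 + exp(-mu * (10000 - sv)))
  p_obs <- ifelse(fx$choice == "immediate", p_imm, 1 - p_imm)
  expect_equal(negative_log_likelihood(list(k = k, mu = mu), fx),
               -log(prod(p_obs)))
  # mu = 0 makes every trial a coin flip
  expect_equal(negative_log_likelihood(list(k = 0.01, mu = 0), fx),
               10 * log(2))
  # invariant to trial order
  expect_equal(negative_log_likelihood(list(k = k, mu = mu), fx[10:1, ]),
               negative_log_likelihood(list(k = k, mu = mu), fx))
  expect_error(negative_log_likelihood(list(k = k, mu = mu), fx[0, ]),
               "empty")
})

test_that("fit_mle matches a dense grid search on small fixtures", {
  for (seed in c(1L, 2L, 3L)) {
    fx <- random_trial_fixture(12L, seed = 600L + seed)
    fit <- fit_mle(fx, seed = seed)
    grid <- grid_search_nll(fx, n_grid = 120L)
    expect_lte(-fit$log_likelihood, grid$nll + 1e-3)
  }
})

test_that("fit_mle recovers generating parameters and is seed-deterministic", {
  set.seed(99)
  n <- 20L
  lk <- stats::rnorm(n, -2, 0.4)
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- simulate_agent_session(discount_params(10^lk[i], 10^-3.4),
                                seed = 7000L + i)
    f <- fit_mle(s, seed = i)
    if (f$unique) err[i] <- f$log10_k - lk[i]
  }
  expect_lt(stats::median(abs(err), na.rm = TRUE), 0.15)

  s <- fixture_session(seed = 5L)
  f1 <- fit_mle(s, seed = 3L)
  f2 <- fit_mle(s, seed = 3L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$start_optima, f2$start_optima)
})

test_that("one-sided choice patterns and degenerate offers are rejected", {
  s <- generate_session(policy_always("immediate"), seed = 21L)
  f <- fit_mle(s, seed = 1L)
  expect_false(f$unique)
  s2 <- generate_session(policy_always("delayed"), seed = 21L)
  f2 <- fit_mle(s2, seed = 1L)
  expect_false(f2$unique)

  const <- random_trial_fixture(8L, seed = 9L)
  const$delay_days <- 21L
  const$delayed_krw <- 15000
  expect_error(fit_mle(const, seed = 1L), "degenerate")
  expect_error(fit_mle(random_trial_fixture(8L, 9L)[1L, ], seed = 1L),
               "at least 2")
})

test_that("uniqueness check flags likelihood ridges by definition", {
  fake <- structure(list(start_optima = data.frame(
    k = c(0.1, 0.001), mu = c(1e-3, 1e-3),
    log10_k = c(-1, -3), nll = c(100, 100.001),
    convergence = c(0, 0))), class = "itc_fit")
  expect_false(check_unique_solution(fake, nll_tol = 0.01, param_tol = 0.1))
  fake2 <- structure(list(start_optima = data.frame(
    k = c(0.1, 0.1001), mu = c(1e-3, 1e-3),
    log10_k = c(-1, -0.9996), nll = c(100, 100.001),
    convergence = c(0, 0))), class = "itc_fit")
  expect_true(check_unique_solution(fake2))
  # boundary estimates are never unique
  fake3 <- structure(list(start_optima = data.frame(
    k = 0.999, mu = 1e-3, log10_k = log10(0.999), nll = 10,
    convergence = 0)), class = "itc_fit")
  expect_false(check_unique_solution(fake3))
})

test_that("larger discount rates yield weakly more immediate choices", {
  # deterministic offer grid, threshold-free comparison through the model
  offers <- expand.grid(delayed_krw = seq(10300, 29300, by = 1000),
                        delay_days = c(1, 10, 21, 50, 90, 180))
  frac <- function(k) {
    sv <- offers$delayed_krw / (1 + k * offers$delay_days)
    mean(p_immediate(10000, sv, 4e-4))
  }
  ks <- c(0.001, 0.005, 0.02, 0.1, 0.4)
  expect_true(all(diff(vapply(ks, frac, numeric(1L))) > 0))
})
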