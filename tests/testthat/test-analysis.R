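test_that("immediate-choice ratio and effect measures follow their definitions", {
  s <- generate_session(policy_always("immediate"), seed = 1L)
  expect_equal(p_immediate_ratio(s), 1)
  s$choice[1:90] <- "delayed"
  expect_equal(p_immediate_ratio(s), 0.5)
  expect_error(p_immediate_ratio(s[0, ]), "empty")
  # patient threshold agent never takes the immediate option
  pat <- generate_session(policy_threshold(1e-4), seed = 2L)
  expect_equal(p_immediate_ratio(pat), 0)

  mk_fit <- function(log10_k, unique = TRUE) {
    structure(list(log10_k = log10_k, unique = unique), class = "itc_fit")
  }
  pre <- fixture_session(seed = 3L)
  post <- fixture_session(seed = 4L)
  em <- effect_measures(mk_fit(-2), mk_fit(-3), pre, post)
  expect_equal(em$delta_log_k, 1)   # one decade: k 0.01 -> 0.001
  expect_equal(em$delta_p_immediate,
               p_immediate_ratio(pre) - p_immediate_ratio(post))
  em0 <- effect_measures(mk_fit(-2), mk_fit(-2), pre, pre)
  expect_equal(unlist(em0), c(delta_log_k = 0, delta_p_immediate = 0))
  expect_error(effect_measures(mk_fit(-2, unique = FALSE), mk_fit(-2),
                               pre, post), "unique")
})

test_that("MAD filter excludes 3-MAD outliers on the log10 k scale", {
  v <- c(-2, -2.1, -1.9, -2.05, 1)
  expect_identical(mad_filter(v), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mad_filter(rep(-2, 5))))
  expect_true(all(mad_filter(c(-2, -2.05, -1.95))))
  expect_error(mad_filter(c(1, 2)), "at least 3")
})

test_that("bootstrap mean test: identity, determinism and sensitivity", {
  x <- stats::rnorm(20)
  same <- bootstrap_mean_test(x, x, paired = TRUE, B = 500L, seed = 1L)
  expect_equal(same$statistic_observed, 0)
  expect_equal(same$p_value, 1)
  b1 <- bootstrap_mean_test(x, B = 2000L, seed = 42L)
  b2 <- bootstrap_mean_test(x, B = 2000L, seed = 42L)
  expect_identical(b1$p_value, b2$p_value)
  expect_gte(b1$p_value, 1 / 2001)
  # a 2-sd shift at n = 30 is detected essentially always
  hits <- 0L
  for (r in 1:25) {
    set.seed(800L + r)
    x <- stats::rnorm(30); y <- stats::rnorm(30) + 2
    if (bootstrap_mean_test(x, y, B = 1000L, seed = r)$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 24L)
  expect_error(bootstrap_mean_test(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("bootstrap correlation test hits the p floor at |r| = 1 and calibrates", {
  a <- stats::rnorm(12)
  up <- bootstrap_correlation_test(a, a, B = 400L, seed = 2L)
  expect_equal(up$p_value, 1 / 401)
  expect_equal(up$r_observed, 1)
  dn <- bootstrap_correlation_test(a, -a, B = 400L, seed = 2L)
  expect_equal(dn$p_value, 1 / 401)
  expect_equal(dn$r_observed, -1)
  # null calibration at moderate replication
  rej <- 0L
  for (r in 1:100) {
    set.seed(900L + r)
    p <- bootstrap_correlation_test(stats::rnorm(25), stats::rnorm(25),
                                    B = 500L, seed = r)$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej, 1L)
  expect_lte(rej, 11L)
  expect_error(bootstrap_correlation_test(1:5, 1:4), "equal length")
})

test_that("mixed ANOVA matches hand-worked sums of squares and balances", {
  data <- data.frame(
    participant = rep(sprintf("s%d", 1:6), each = 2L),
    group = rep(c("A", "B"), each = 6L),
    phase = rep(c("pre", "post"), 6L),
    value = c(10, 12, 11, 15, 9, 11, 8, 9, 7, 8, 9, 8))
  tab <- mixed_anova(data)
  hand <- mixed_ss_by_hand(data)
  expect_equal(tab$ss[tab$term == "type"], hand$group)
  expect_equal(tab$ss[tab$term == "error_between"], hand$error_between)
  expect_equal(tab$ss[tab$term == "time"], hand$phase)
  expect_equal(tab$ss[tab$term == "time_x_type"], hand$interaction)
  expect_equal(tab$ss[tab$term == "error_within"], hand$error_within)
  expect_equal(sum(tab$ss), hand$total)
  expect_identical(tab$df[tab$term == "type"], 1)
  expect_identical(tab$df[tab$term == "error_between"], 4)

  # a pure time shift loads on the within factor only
  shifted <- data
  shifted$value[shifted$phase == "post"] <-
    shifted$value[shifted$phase == "post"] + 100
  tab2 <- mixed_anova(shifted)
  expect_gt(tab2$F[tab2$term == "time"], tab$F[tab$term == "time"])
  expect_equal(tab2$ss[tab2$term == "time_x_type"],
               tab$ss[tab$term == "time_x_type"])

  expect_error(mixed_anova(data[-1L, ]), "unbalanced")
})

test_that("mixed ANOVA p-values are uniform under a simulated null", {
  ps <- matrix(NA_real_, 60L, 3L)
  for (r in seq_len(60L)) {
    set.seed(1200L + r)
    d <- data.frame(
      participant = rep(sprintf("s%d", 1:20), each = 2L),
      group = rep(c("A", "B"), each = 20L),
      phase = rep(c("pre", "post"), 20L),
      value = stats::rnorm(40))
    tab <- mixed_anova(d)
    ps[r, ] <- tab$p[match(c("type", "time", "time_x_type"), tab$term)]
  }
  for (j in 1:3) {
    expect_gt(stats::ks.test(ps[, j], "punif")$p.value, 0.01)
  }
})

test_that("sliding windows count and average correctly", {
  expect_identical(windowed_accuracy(rep(1, 20))$n_windows, 3L)
  expect_equal(windowed_accuracy(rep(1, 20))$values, rep(1, 3))
  expect_equal(windowed_accuracy(rep(c(0, 1), 15))$values,
               rep(0.5, windowed_accuracy(rep(c(0, 1), 15))$n_windows))
  expect_error(windowed_accuracy(rep(1, 9)), "shorter")
  # window-count formula across a sweep of lengths
  for (n in c(10:40, 95L, 240L, 1000L)) {
    expect_identical(windowed_accuracy(rep(0L, n))$n_windows,
                     as.integer(floor((n - 10) / 5) + 1))
  }
})

test_that("performance slope is the OLS slope per window index", {
  expect_equal(performance_slope(c(0.5, 0.6, 0.7)), 0.1)
  expect_equal(performance_slope(rep(0.4, 8)), 0)
  expect_error(performance_slope(0.5), "at least 2")
})

test_that("quintile bins cover the trace and expose late-bin associations", {
  set.seed(55)
  n <- 40L; L <- 240L
  traces <- matrix(stats::rbinom(n * L, 1L, 0.7), n, L)
  qa <- quintile_bin_association(traces, stats::rnorm(n))
  expect_identical(qa$start, c(1L, 41L, 81L, 121L, 161L))
  expect_identical(qa$end - qa$start + 1L, rep(80L, 5L))
  expect_lt(max(abs(qa$r)), 0.5)   # independent effects: near-zero r
  # effects proportional to late-bin accuracy produce rising correlations
  eff <- rowMeans(traces[, 161:240]) + stats::rnorm(n, 0, 0.01)
  qa2 <- quintile_bin_association(traces, eff)
  expect_gt(qa2$r[5L], qa2$r[1L])
  expect_gt(qa2$r[5L], 0.8)
  expect_error(quintile_bin_association(traces[, 1:5], stats::rnorm(n)),
               "5 bins")
})
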