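# Synthetic cohort generator: complete pre/post ITC studies with known
# ground-truth parameters, group-level intervention effects, and Serial-7s
# accuracy traces with logistic learning curves.

#' Describe a synthetic study cohort
#'
#' Defines the generative conditions of a simulated pre/post intervention
#' study. Per participant, a baseline discount rate is drawn as
#' `log10 k ~ N(log10_k_mean, log10_k_sd)` and an inverse temperature as
#' `log10 mu ~ N(log10_mu_mean, log10_mu_sd)`. The post-session discount
#' rate is `log10 k_post = log10 k_pre - (delta + jitter)`, where `delta` is
#' the group's intervention effect and `jitter ~ N(0, retest_sd)` is
#' idiosyncratic test-retest noise, so the expected pre-minus-post shift in
#' log10 k equals the group effect. Serial-7s accuracy follows the logistic
#' learning curve `p(t) = p0 + (p1 - p0) * (1 - exp(-rate * t))` sampled as
#' Bernoulli trials; individual learning rates are log-normal around
#' `wm_rate`, and `slope_effect_corr` couples (via a Gaussian copula) the
#' learning-rate draw to the individual's post-minus-pre shift.
#'
#' @param groups List of groups, each a list with `label`, `n` (>= 1) and
#'   `delta_log10_k` (additive intervention effect on log10 k, positive =
#'   impulsivity reduced).
#' @param log10_k_mean,log10_k_sd Baseline log10 discount-rate distribution.
#' @param log10_mu_mean,log10_mu_sd log10 inverse-temperature distribution.
#' @param retest_sd Test-retest sd of the individual log10 k shift.
#' @param wm_p0,wm_p1 Initial and asymptotic Serial-7s accuracy, in [0, 1].
#' @param wm_rate Mean learning rate (per trial) of the accuracy curve.
#' @param wm_rate_sd Log-scale sd of individual learning rates.
#' @param wm_trials Serial-7s trials per participant (default 240: two
#'   blocks of 120).
#' @param slope_effect_corr Copula correlation `rho` in [-1, 1] between the
#'   learning-rate draw and the individual intervention shift (0 = none).
#' @param seed Integer seed of the cohort.
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(groups = list(list(label = "intervention", n = 30L,
                                             delta_log10_k = 0),
                                        list(label = "control", n = 30L,
                                             delta_log10_k = 0)),
                          log10_k_mean = -2, log10_k_sd = 0.5,
                          log10_mu_mean = -3.5, log10_mu_sd = 0.3,
                          retest_sd = 0.1,
                          wm_p0 = 0.5, wm_p1 = 0.9,
                          wm_rate = 0.02, wm_rate_sd = 0.3,
                          wm_trials = 240L,
                          slope_effect_corr = 0,
                          seed = 1L) {
  stopifnot(length(groups) >= 1L)
  for (g in groups) {
    if (!all(c("label", "n", "delta_log10_k") %in% names(g))) {
      stop("each group needs fields label, n, delta_log10_k")
    }
    if (g$n < 1L) stop("group '", g$label, "' has n < 1")
  }
  if (anyDuplicated(vapply(groups, `[[`, "", "label"))) {
    stop("group labels must be distinct")
  }
  if (log10_k_sd < 0 || log10_mu_sd < 0 || retest_sd < 0 || wm_rate_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (wm_p0 < 0 || wm_p0 > 1 || wm_p1 < 0 || wm_p1 > 1) {
    stop("wm_p0 and wm_p1 must lie in [0, 1]")
  }
  if (abs(slope_effect_corr) > 1) stop("|slope_effect_corr| must be <= 1")
  if (wm_rate <= 0) stop("wm_rate must be positive")
  structure(list(groups = groups,
                 log10_k_mean = log10_k_mean, log10_k_sd = log10_k_sd,
                 log10_mu_mean = log10_mu_mean, log10_mu_sd = log10_mu_sd,
                 retest_sd = retest_sd,
                 wm_p0 = wm_p0, wm_p1 = wm_p1,
                 wm_rate = wm_rate, wm_rate_sd = wm_rate_sd,
                 wm_trials = as.integer(wm_trials),
                 slope_effect_corr = slope_effect_corr,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Study-shaped cohort presets
#'
#' `"experiment1"` emulates a five-group design (associative memory, its
#' control, working memory, its control, resting) with a global repetition
#' effect, a larger working-memory effect, and a positive coupling between
#' learning slope and effect size. `"experiment2"` emulates the three-group
#' replication (working memory, attention control, resting) with the
#' repetition effect only and no slope-effect coupling.
#'
#' @param name `"experiment1"` or `"experiment2"`.
#' @param seed Cohort seed.
#' @return A [cohort_design()].
#' @export
cohort_design_preset <- function(name = c("experiment1", "experiment2"),
                                 seed = 1L) {
  name <- match.arg(name)
  if (name == "experiment1") {
    cohort_design(
      groups = list(
        list(label = "associative_memory", n = 26L, delta_log10_k = 0.1),
        list(label = "control_am", n = 25L, delta_log10_k = 0.1),
        list(label = "working_memory", n = 24L, delta_log10_k = 0.3),
        list(label = "control_wm", n = 24L, delta_log10_k = 0.1),
        list(label = "rest", n = 26L, delta_log10_k = 0.1)),
      slope_effect_corr = 0.5, seed = seed)
  } else {
    cohort_design(
      groups = list(
        list(label = "working_memory", n = 30L, delta_log10_k = 0.1),
        list(label = "control_wm", n = 30L, delta_log10_k = 0.1),
        list(label = "rest", n = 30L, delta_log10_k = 0.1)),
      slope_effect_corr = 0, seed = seed)
  }
}

#' Simulate one agent's closed-loop staircase session
#'
#' Runs [generate_session()] with choices sampled from the softmax rule at
#' the agent's parameters at every offer.
#'
#' @param params A [discount_params()].
#' @param phase `"pre"` or `"post"`.
#' @param config A [staircase_config()].
#' @param seed Optional session seed.
#' @param participant_id Provenance label.
#' @return A 180-row trial-record data frame (see [generate_session()]).
#' @export
simulate_agent_session <- function(params, phase = "pre",
                                   config = staircase_config(),
                                   seed = NULL, participant_id = "sim") {
  generate_session(policy_softmax(params$k, params$mu), config = config,
                   seed = seed, participant_id = participant_id,
                   phase = phase)
}

#' Simulate a complete synthetic study
#'
#' Generates, for every participant of every group in the design: ground
#' truth parameters, a pre- and a post-intervention 180-trial staircase
#' session, and a Serial-7s accuracy trace. All generating parameters are
#' retained so downstream estimates can be validated against the truth.
#'
#' @param design A [cohort_design()].
#' @param config A [staircase_config()].
#' @return An object of class `"itc_cohort"`: `trials` (all sessions,
#'   stacked), `performance` (per-trial Serial-7s correctness:
#'   `participant_id`, `task`, `block`, `trial_index`, `correct`), `truth`
#'   (one row per participant: group, true parameters, true shift), and the
#'   `design`.
#' @export
simulate_cohort <- function(design, config = staircase_config()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  rho <- design$slope_effect_corr
  trials <- list(); perf <- list(); truth <- list()
  i <- 0L
  for (g in design$groups) {
    for (p in seq_len(g$n)) {
      i <- i + 1L
      id <- sprintf("%s_%02d", g$label, p)
      pre_lk <- stats::rnorm(1L, design$log10_k_mean, design$log10_k_sd)
      pre_lk <- min(max(pre_lk, -6), -0.05)
      lmu <- stats::rnorm(1L, design$log10_mu_mean, design$log10_mu_sd)
      # Gaussian copula between the individual shift jitter and the
      # learning-rate draw
      z1 <- stats::rnorm(1L)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1L)
      shift <- g$delta_log10_k + design$retest_sd * z1
      post_lk <- min(max(pre_lk - shift, -6), -0.05)
      rate <- design$wm_rate *
        exp(design$wm_rate_sd * z2 - design$wm_rate_sd^2 / 2)
      pre <- simulate_agent_session(
        discount_params(10^pre_lk, 10^lmu), phase = "pre", config = config,
        seed = child_seed(design$seed, "session", paste0(id, ":pre")),
        participant_id = id)
      post <- simulate_agent_session(
        discount_params(10^post_lk, 10^lmu), phase = "post", config = config,
        seed = child_seed(design$seed, "session", paste0(id, ":post")),
        participant_id = id)
      set.seed(child_seed(design$seed, "wm_trace", id))
      tt <- seq_len(design$wm_trials)
      p_curve <- design$wm_p0 +
        (design$wm_p1 - design$wm_p0) * (1 - exp(-rate * tt))
      trace <- simulate_serial7s_trace(design$wm_trials, p_curve)
      trials[[i]] <- rbind(pre, post)
      perf[[i]] <- data.frame(
        participant_id = id,
        task = "serial7s",
        block = ifelse(tt <= design$wm_trials / 2, 1L, 2L),
        trial_index = tt,
        correct = trace$correct,
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        participant_id = id,
        group = g$label,
        pre_log10_k = pre_lk,
        post_log10_k = post_lk,
        log10_mu = lmu,
        delta_log10_k_true = pre_lk - post_lk,
        group_delta = g$delta_log10_k,
        wm_rate = rate,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 performance = do.call(rbind, perf),
                 truth = do.call(rbind, truth),
                 design = design),
            class = "itc_cohort")
}
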