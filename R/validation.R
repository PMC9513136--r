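# Self-validation studies: parameter recovery, bootstrap type-I
# calibration, and group-effect recovery on replicate synthetic cohorts.

#' Parameter-recovery study
#'
#' Simulates agents with known (log10 k, log10 mu), runs each through a
#' closed-loop 180-trial staircase session, refits every session by maximum
#' likelihood, and summarises how well the generating discount rates are
#' recovered. Summary statistics (correlation, bias, RMSE) are computed over
#' fits that pass the uniqueness check, mirroring the analysis pipeline's
#' exclusion rule; the per-agent table retains all fits.
#'
#' @param n_agents Number of simulated agents (default 200).
#' @param log10_k_mean,log10_k_sd,log10_mu_mean,log10_mu_sd Generating
#'   parameter distributions.
#' @param n_starts Optimizer starts per fit.
#' @param config A [staircase_config()].
#' @param seed Integer seed; all per-agent streams derive from it via
#'   [child_seed()].
#' @return List: `agents` (data frame: true and estimated parameters,
#'   `unique` flag) and `summary` (`r`, `bias`, `rmse`, `median_abs_err`,
#'   `n_unique`, `n_agents`), the summary computed over unique fits.
#' @export
recovery_study <- function(n_agents = 200L,
                           log10_k_mean = -2, log10_k_sd = 0.5,
                           log10_mu_mean = -3.5, log10_mu_sd = 0.3,
                           n_starts = 10L,
                           config = staircase_config(),
                           seed = 1L) {
  set.seed(child_seed(seed, "recovery_params"))
  lk <- stats::rnorm(n_agents, log10_k_mean, log10_k_sd)
  lk <- pmin(pmax(lk, -6), -0.05)
  lmu <- stats::rnorm(n_agents, log10_mu_mean, log10_mu_sd)
  est_k <- numeric(n_agents); est_mu <- numeric(n_agents)
  uniq <- logical(n_agents)
  for (i in seq_len(n_agents)) {
    s <- simulate_agent_session(
      discount_params(10^lk[i], 10^lmu[i]), config = config,
      seed = child_seed(seed, "recovery_session", i),
      participant_id = sprintf("agent_%03d", i))
    f <- fit_mle(s, n_starts = n_starts,
                 seed = child_seed(seed, "recovery_fit", i))
    est_k[i] <- f$log10_k
    est_mu[i] <- log10(f$params$mu)
    uniq[i] <- f$unique
  }
  agents <- data.frame(agent = seq_len(n_agents),
                       true_log10_k = lk, true_log10_mu = lmu,
                       est_log10_k = est_k, est_log10_mu = est_mu,
                       unique = uniq)
  u <- agents[agents$unique, ]
  err <- u$est_log10_k - u$true_log10_k
  list(agents = agents,
       summary = list(r = stats::cor(u$true_log10_k, u$est_log10_k),
                      bias = mean(err),
                      rmse = sqrt(mean(err^2)),
                      median_abs_err = stats::median(abs(err)),
                      n_unique = nrow(u),
                      n_agents = n_agents))
}

#' Type-I error calibration of the bootstrap mean test
#'
#' Draws replicate pairs of independent standard-normal samples (a true
#' null) and records the bootstrap two-sample p-value of each, giving the
#' empirical rejection rate at `alpha`.
#'
#' @param n_replicates Number of null replicates (default 1,000).
#' @param n Per-group sample size (default 30).
#' @param B Bootstrap iterations per test (default 2,000).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return List: `p_values`, `rejection_rate`, `alpha`, `n_replicates`.
#' @export
bootstrap_type1_study <- function(n_replicates = 1000L, n = 30L, B = 2000L,
                                  alpha = 0.05, seed = 1L) {
  p <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(child_seed(seed, "null_data", r))
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    p[r] <- bootstrap_mean_test(x, y, B = B,
                                seed = child_seed(seed, "null_boot", r))$p_value
  }
  list(p_values = p,
       rejection_rate = mean(p < alpha),
       alpha = alpha,
       n_replicates = n_replicates)
}

#' Group-effect recovery over replicate synthetic cohorts
#'
#' Simulates replicate three-group cohorts in which one group receives an
#' additive intervention effect on log10 k and the others none, runs the
#' full pipeline (fit, exclusion, effect measures, group bootstrap tests) on
#' each, and collects the per-group estimated mean effects and bootstrap
#' p-values. An unbiased pipeline recovers the intervention group's `delta`
#' and yields uniform p-values in the null groups.
#'
#' @param n_replicates Number of replicate cohorts (default 20).
#' @param delta Intervention effect on log10 k (default 0.3).
#' @param n_per_group Participants per group (default 30).
#' @param B Bootstrap iterations inside the pipeline (default 2,000).
#' @param seed Integer seed.
#' @return List: `per_replicate` (replicate, group, n, mean effect,
#'   bootstrap p) and `summary` (`mean_recovered_delta` of the intervention
#'   group, `null_p_values`).
#' @export
effect_recovery_study <- function(n_replicates = 20L, delta = 0.3,
                                  n_per_group = 30L, B = 2000L, seed = 1L) {
  rows <- list()
  for (r in seq_len(n_replicates)) {
    design <- cohort_design(
      groups = list(
        list(label = "intervention", n = n_per_group, delta_log10_k = delta),
        list(label = "control", n = n_per_group, delta_log10_k = 0),
        list(label = "rest", n = n_per_group, delta_log10_k = 0)),
      seed = child_seed(seed, "design", r))
    cfg <- pipeline_config(design = design,
                           analysis = list(B = B),
                           seed = child_seed(seed, "pipeline", r))
    rep_out <- run_pipeline(cfg)
    ge <- rep_out$group_effects
    ge$replicate <- r
    rows[[r]] <- ge[, c("replicate", "group", "n", "mean_delta_log_k",
                        "p_boot")]
  }
  per_replicate <- do.call(rbind, rows)
  intr <- per_replicate[per_replicate$group == "intervention", ]
  nul <- per_replicate[per_replicate$group != "intervention", ]
  list(per_replicate = per_replicate,
       summary = list(mean_recovered_delta = mean(intr$mean_delta_log_k),
                      true_delta = delta,
                      null_p_values = nul$p_boot))
}
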