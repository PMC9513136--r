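# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no files are read.

# Run one arm of the staircase against a deterministic threshold agent and
# return the five offered delayed rewards.
threshold_arm_offers <- function(k, delay, initial,
                                 config = staircase_config()) {
  arms <- init_block()
  idx <- which(vapply(arms, function(a) {
    a$delay_days == delay && a$initial_value == initial
  }, logical(1L)))
  arm <- arms[[idx]]
  pol <- policy_threshold(k)
  offers <- numeric(5L)
  for (t in 1:5) {
    offers[t] <- arm$current_delayed_reward
    off <- list(immediate_krw = 10000,
                delayed_krw = arm$current_delayed_reward,
                delay_days = delay)
    arm <- update_arm(arm, pol(off), config)
  }
  offers
}

# A small, reproducible simulated session
fixture_session <- function(k = 0.01, mu = 3e-4, seed = 42L,
                            participant_id = "p1", phase = "pre") {
  simulate_agent_session(discount_params(k, mu), phase = phase,
                         seed = seed, participant_id = participant_id)
}

# Random small trial fixture (arbitrary offers, agent-generated choices)
random_trial_fixture <- function(n_trials, seed) {
  set.seed(seed)
  delays <- sample(c(1L, 10L, 21L, 50L, 90L, 180L), n_trials, replace = TRUE)
  rewards <- sample(seq(10300, 29300, by = 100), n_trials, replace = TRUE)
  k <- 10^stats::runif(1L, -3, -1)
  mu <- 10^stats::runif(1L, -4, -3)
  sv <- rewards / (1 + k * delays)
  p <- stats::plogis(mu * (10000 - sv))
  data.frame(participant_id = "fx", phase = "pre",
             block = 1L, trial_index = seq_len(n_trials),
             delay_days = delays, immediate_krw = 10000L,
             delayed_krw = rewards, arm_delay = delays,
             arm_initial = 15000L, step = 1L,
             choice = ifelse(stats::runif(n_trials) < p,
                             "immediate", "delayed"),
             stringsAsFactors = FALSE)
}

# Hand-worked mixed-design sums of squares (independent oracle for
# mixed_anova): balanced long data, 2 phases, participants nested in groups.
mixed_ss_by_hand <- function(data) {
  y <- data$value
  grand <- mean(y)
  subj_means <- tapply(y, data$participant, mean)
  group_of <- tapply(as.character(data$group), data$participant,
                     function(g) g[1L])
  group_means <- tapply(y, data$group, mean)
  phase_means <- tapply(y, data$phase, mean)
  cell_means <- tapply(y, list(data$group, data$phase), mean)
  n_subj <- length(subj_means)
  n_per_group <- table(group_of)
  ss_total <- sum((y - grand)^2)
  ss_subjects <- 2 * sum((subj_means - grand)^2)
  ss_group <- 2 * sum(n_per_group[names(group_means)] *
                        (group_means - grand)^2)
  ss_error_between <- ss_subjects - ss_group
  ss_phase <- n_subj * sum((phase_means - grand)^2)
  ss_cells <- sum(outer(n_per_group[rownames(cell_means)], c(1, 1)) *
                    (cell_means - grand)^2)
  ss_interaction <- ss_cells - ss_group - ss_phase
  ss_error_within <- ss_total - ss_subjects - ss_phase - ss_interaction
  list(total = ss_total, group = ss_group,
       error_between = ss_error_between, phase = ss_phase,
       interaction = ss_interaction, error_within = ss_error_within)
}
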