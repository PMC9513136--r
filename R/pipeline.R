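# Configuration, trial-log I/O, seed derivation, and the end-to-end
# simulate -> fit -> exclude -> analyze pipeline.

TRIAL_COLUMNS <- c("participant_id", "phase", "block", "trial_index",
                   "delay_days", "immediate_krw", "delayed_krw",
                   "arm_delay", "arm_initial", "step", "choice")

#' Derive a child seed from a global seed
#'
#' Stable, documented derivation used by every stochastic stage: a
#' polynomial string hash of `(seed, stage, id)` modulo 2^31 - 1, so any
#' single participant or stage can be replayed without rerunning the whole
#' cohort.
#'
#' @param seed Global integer seed.
#' @param stage Stage name, e.g. `"session"`, `"fit"`.
#' @param id Optional identifier (participant, phase, replicate...).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, stage, id = "") {
  key <- paste(seed, stage, id, sep = "|")
  h <- 7
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h + 1)
}

#' Write / read trial logs as CSV
#'
#' Trial logs use a fixed column order (`participant_id`, `phase`, `block`,
#' `trial_index`, `delay_days`, `immediate_krw`, `delayed_krw`, `arm_delay`,
#' `arm_initial`, `step`, `choice`), UTF-8, one row per trial.
#' `read_trials()` validates on load: known choice labels, no duplicate
#' (participant, phase, trial index), and exactly 180 trials per
#' participant-session.
#'
#' @param trials Trial-record data frame.
#' @param path File path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  }
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop("trial file lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!trials$choice %in% c("immediate", "delayed"))
  if (length(bad)) {
    stop("unknown choice label '", trials$choice[bad[1L]], "' at row ",
         bad[1L])
  }
  key <- paste(trials$participant_id, trials$phase, trials$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, phase, trial_index) at row ",
         which(duplicated(key))[1L])
  }
  counts <- table(paste(trials$participant_id, trials$phase, sep = "/"))
  off <- counts != 180L
  if (any(off)) {
    bad_name <- names(counts)[which(off)[1L]]
    stop("session ", bad_name, " has ", counts[which(off)[1L]],
         " trials (expected 180)")
  }
  trials
}

#' Pipeline configuration
#'
#' Bundles all stage settings with their defaults. Every stochastic stage
#' derives its stream from the global `seed` via [child_seed()].
#'
#' @param staircase A [staircase_config()].
#' @param fit List: `n_starts`, `nll_tol`, `param_tol` (see [fit_mle()]).
#' @param analysis List: `B` (bootstrap iterations), `alpha`, `window`,
#'   `step`, `mad_threshold`.
#' @param design A [cohort_design()] (simulated input), or `NULL` when
#'   trials are supplied to [run_pipeline()] directly.
#' @param seed Global integer seed.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(staircase = staircase_config(),
                            fit = list(n_starts = 10L, nll_tol = 0.01,
                                       param_tol = 0.1),
                            analysis = list(B = 10000L, alpha = 0.05,
                                            window = 10L, step = 5L,
                                            mad_threshold = 3),
                            design = cohort_design(),
                            seed = 1L) {
  fit <- utils::modifyList(list(n_starts = 10L, nll_tol = 0.01,
                                param_tol = 0.1), fit)
  analysis <- utils::modifyList(list(B = 10000L, alpha = 0.05,
                                     window = 10L, step = 5L,
                                     mad_threshold = 3), analysis)
  structure(list(staircase = staircase, fit = fit, analysis = analysis,
                 design = design, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with optional keys `staircase` (`exponent_mode`,
#' `floor100`, `min_margin`), `fit`, `analysis`, `design` (`groups` plus the
#' generator fields of [cohort_design()]) and `seed`; unspecified settings
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as a boolean; restore the group-size field
  if (!is.null(y$design$groups)) {
    y$design$groups <- lapply(y$design$groups, function(g) {
      names(g)[names(g) %in% c("FALSE", "false")] <- "n"
      g
    })
  }
  sc <- do.call(staircase_config, utils::modifyList(
    list(), y$staircase[setdiff(names(y$staircase), "seed")] %||% list()))
  design <- if (!is.null(y$design)) do.call(cohort_design, y$design) else
    cohort_design()
  pipeline_config(staircase = sc,
                  fit = y$fit %||% list(),
                  analysis = y$analysis %||% list(),
                  design = design,
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every participant-session in a trial table
#'
#' @param trials Stacked trial records (several participants/phases).
#' @param config A [pipeline_config()] (fit settings and seed are used).
#' @return Data frame with one row per (participant, phase): `k`, `mu`,
#'   `log10_k`, `nll`, `unique`, `converged`.
#' @export
fit_all_sessions <- function(trials, config = pipeline_config()) {
  sessions <- unique(trials[, c("participant_id", "phase")])
  out <- vector("list", nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    id <- sessions$participant_id[i]; ph <- sessions$phase[i]
    sub <- trials[trials$participant_id == id & trials$phase == ph, ]
    fit <- fit_mle(sub,
                   n_starts = config$fit$n_starts,
                   seed = child_seed(config$seed, "fit", paste0(id, ":", ph)),
                   nll_tol = config$fit$nll_tol,
                   param_tol = config$fit$param_tol)
    out[[i]] <- data.frame(participant_id = id, phase = ph,
                           k = fit$params$k, mu = fit$params$mu,
                           log10_k = fit$log10_k,
                           nll = -fit$log_likelihood,
                           unique = fit$unique,
                           converged = fit$converged,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full study pipeline
#'
#' Simulates a cohort from the configured design (or uses a supplied
#' cohort), fits every participant-session, applies the exclusion rules
#' (non-unique MLE solutions, then the MAD outlier filter on the log10 k
#' estimates of each phase), computes per-participant effect measures,
#' per-group bootstrap tests, the time-by-type mixed ANOVA, and the
#' working-memory performance associations. Deterministic given the config
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `"itc_cohort"`; when `NULL` one is
#'   simulated from `config$design`.
#' @param out_dir Optional directory; when given, `trials.csv`,
#'   `performance.csv`, `fits.json`, `truth.json` and `report.json` are
#'   written there.
#' @return A report list: `config` echo, `counts` (exclusion accounting),
#'   `exclusions` (who and by which rule), `effects` (per participant),
#'   `group_effects`, `anova`, `wm_association`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    design <- config$design
    design$seed <- child_seed(config$seed, "cohort")
    cohort <- simulate_cohort(design, config = config$staircase)
  }
  trials <- cohort$trials
  fits <- fit_all_sessions(trials, config)
  wide <- merge(fits[fits$phase == "pre", ],
                fits[fits$phase == "post", ],
                by = "participant_id", suffixes = c("_pre", "_post"))
  wide <- merge(wide, cohort$truth[, c("participant_id", "group")],
                by = "participant_id")

  nonunique <- !(wide$unique_pre & wide$unique_post)
  mad_ok <- rep(FALSE, nrow(wide))
  if (sum(!nonunique) >= 3L) {
    keep <- which(!nonunique)
    mad_ok[keep] <- mad_filter(wide$log10_k_pre[keep],
                               config$analysis$mad_threshold) &
      mad_filter(wide$log10_k_post[keep], config$analysis$mad_threshold)
  } else {
    mad_ok[!nonunique] <- TRUE
  }
  excluded_mad <- !nonunique & !mad_ok
  included <- !nonunique & mad_ok
  exclusions <- data.frame(
    participant_id = wide$participant_id[!included],
    rule = ifelse(nonunique[!included], "nonunique_mle", "mad_outlier"),
    stringsAsFactors = FALSE)

  inc <- wide[included, ]
  p_imm <- function(id, ph) {
    p_immediate_ratio(trials[trials$participant_id == id &
                               trials$phase == ph, ])
  }
  effects <- data.frame(
    participant_id = inc$participant_id,
    group = inc$group,
    delta_log_k = inc$log10_k_pre - inc$log10_k_post,
    delta_p_immediate = vapply(inc$participant_id,
                               function(id) p_imm(id, "pre") -
                                 p_imm(id, "post"), numeric(1L)),
    stringsAsFactors = FALSE)

  B <- config$analysis$B
  group_effects <- do.call(rbind, lapply(split(effects, effects$group),
    function(g) {
      bt <- bootstrap_mean_test(
        g$delta_log_k, B = B,
        seed = child_seed(config$seed, "boot_group", g$group[1L]))
      data.frame(group = g$group[1L], n = nrow(g),
                 mean_delta_log_k = mean(g$delta_log_k),
                 sd_delta_log_k = stats::sd(g$delta_log_k),
                 mean_delta_p_immediate = mean(g$delta_p_immediate),
                 t = bt$statistic_observed, p_boot = bt$p_value,
                 cohen_d = bt$cohen_d,
                 boot_seed = bt$seed,
                 stringsAsFactors = FALSE)
    }))
  rownames(group_effects) <- NULL

  anova_tab <- NULL
  if (length(unique(effects$group)) >= 2L && nrow(inc) >= 4L) {
    long <- rbind(
      data.frame(participant = inc$participant_id, group = inc$group,
                 phase = "pre", value = inc$log10_k_pre),
      data.frame(participant = inc$participant_id, group = inc$group,
                 phase = "post", value = inc$log10_k_post))
    anova_tab <- mixed_anova(long)
  }

  wm <- NULL
  perf <- cohort$performance
  if (!is.null(perf) && nrow(perf)) {
    slopes <- vapply(inc$participant_id, function(id) {
      tr <- perf$correct[perf$participant_id == id]
      performance_slope(windowed_accuracy(tr, config$analysis$window,
                                          config$analysis$step))
    }, numeric(1L))
    accs <- vapply(inc$participant_id, function(id) {
      mean(perf$correct[perf$participant_id == id])
    }, numeric(1L))
    wm <- lapply(split(seq_len(nrow(inc)), inc$group), function(ix) {
      if (length(ix) < 4L) return(NULL)
      g <- inc$group[ix[1L]]
      ct <- bootstrap_correlation_test(
        slopes[ix], effects$delta_log_k[ix], B = B,
        seed = child_seed(config$seed, "boot_slope", g))
      ca <- bootstrap_correlation_test(
        accs[ix], effects$delta_log_k[ix], B = B,
        seed = child_seed(config$seed, "boot_acc", g))
      L <- length(perf$correct[perf$participant_id == inc$participant_id[ix[1L]]])
      traces <- t(vapply(inc$participant_id[ix], function(id) {
        perf$correct[perf$participant_id == id]
      }, numeric(L)))
      list(group = g,
           r_slope = ct$r_observed, p_slope = ct$p_value,
           r_accuracy = ca$r_observed, p_accuracy = ca$p_value,
           quintile_bins = quintile_bin_association(
             traces, effects$delta_log_k[ix]))
    })
    wm <- wm[!vapply(wm, is.null, logical(1L))]
  }

  report <- list(
    seed = config$seed,
    config = list(staircase = unclass(config$staircase),
                  fit = config$fit, analysis = config$analysis),
    counts = list(n_input = nrow(wide),
                  n_excluded_nonunique = sum(nonunique),
                  n_excluded_mad = sum(excluded_mad),
                  n_included = sum(included)),
    exclusions = exclusions,
    fits = fits,
    effects = effects,
    group_effects = group_effects,
    anova = anova_tab,
    wm_association = wm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(perf, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report
}
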