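# Group-level statistics: effect measures, outlier exclusion, bootstrap
# tests, mixed-design ANOVA, sliding-window learning curves, and binned
# performance-effect associations.

#' Fraction of immediate choices in a session
#'
#' @param trials Trial records of one participant-session.
#' @return Proportion of trials on which the immediate option was chosen.
#' @export
p_immediate_ratio <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) stop("empty session")
  mean(trials$choice == "immediate")
}

#' Pre/post intervention effect measures
#'
#' `delta_log_k = log10(k_pre) - log10(k_post)` (positive = post-session
#' discounting shallower, i.e. impulsivity reduced) and
#' `delta_p_immediate = P_pre(immediate) - P_post(immediate)`, its
#' model-agnostic counterpart.
#'
#' @param pre_fit,post_fit `"itc_fit"` objects; both must be flagged unique.
#' @param pre_trials,post_trials The corresponding sessions.
#' @return One-row data frame: `delta_log_k`, `delta_p_immediate`.
#' @export
effect_measures <- function(pre_fit, post_fit, pre_trials, post_trials) {
  if (!isTRUE(pre_fit$unique) || !isTRUE(post_fit$unique)) {
    stop("effect measures require unique MLE solutions in both phases")
  }
  data.frame(
    delta_log_k = pre_fit$log10_k - post_fit$log10_k,
    delta_p_immediate = p_immediate_ratio(pre_trials) -
      p_immediate_ratio(post_trials))
}

#' Median-absolute-deviation outlier mask
#'
#' Flags values further than `threshold` raw median absolute deviations
#' (`MAD = median(|x - median(x)|)`, unscaled) from the median. With
#' `MAD = 0` (all values equal) nothing is excluded.
#'
#' @param values Numeric vector (>= 3 values); in this package applied to
#'   log10 k estimates, the scale of all discounting statistics here.
#' @param threshold Number of MADs (default 3).
#' @return Logical inclusion mask (`TRUE` = keep).
#' @export
mad_filter <- function(values, threshold = 3) {
  if (length(values) < 3L) stop("need at least 3 values")
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  if (mad == 0) return(rep(TRUE, length(values)))
  abs(values - med) <= threshold * mad
}

boot_result <- function(statistic, p, B, seed, method, extra = list()) {
  structure(c(list(statistic_observed = statistic,
                   p_value = p,
                   n_iterations = as.integer(B),
                   seed = as.integer(seed),
                   method = method),
              extra),
            class = "itc_boot")
}

#' @export
print.itc_boot <- function(x, ...) {
  cat(sprintf("bootstrap %s: statistic = %.4g, p = %.4g (B = %d, seed = %d)\n",
              x$method, x$statistic_observed, x$p_value, x$n_iterations,
              x$seed))
  invisible(x)
}

# one-sample shift-to-null bootstrap of the t statistic
boot_t_one_sample <- function(d, B) {
  n <- length(d)
  s <- stats::sd(d)
  if (n < 2L || s == 0) {
    return(list(t = 0, p = 1))
  }
  t_obs <- mean(d) / (s / sqrt(n))
  d0 <- d - mean(d)
  m <- matrix(sample(d0, n * B, replace = TRUE), n, B)
  mb <- colMeans(m)
  vb <- pmax((colMeans(m * m) - mb^2) * n / (n - 1), 0)
  tb <- ifelse(vb > 0, mb / sqrt(vb / n), NA_real_)
  p <- (sum(abs(tb) >= abs(t_obs), na.rm = TRUE) + 1) / (B + 1)
  list(t = t_obs, p = p)
}

#' Bootstrap t-test of means
#'
#' Computes the observed t statistic (paired/one-sample, or two-sample with
#' pooled variance) and a two-sided p-value as the proportion of more
#' extreme t statistics among `B` resamples drawn under the null: each
#' sample is shifted to mean zero and resampled with replacement, and
#' `p = (#{|t*| >= |t_obs|} + 1) / (B + 1)`. Cohen's d is reported as the
#' mean difference over the difference-score sd (paired) or the pooled sd
#' (two-sample).
#'
#' @param x Numeric sample (differences, if `y` is `NULL`).
#' @param y Second sample, or `NULL` for a one-sample test against 0.
#' @param paired If `TRUE`, tests `x - y` against 0 (equal lengths
#'   required).
#' @param B Number of bootstrap iterations (default 10,000).
#' @param seed Integer seed; the p-value is reproducible bit-for-bit.
#' @return An `"itc_boot"` object: `statistic_observed` (t), `p_value`,
#'   `n_iterations`, `seed`, `cohen_d`, `method`.
#' @export
bootstrap_mean_test <- function(x, y = NULL, paired = FALSE, B = 10000L,
                                seed = 1L) {
  if (length(x) == 0L || (!is.null(y) && length(y) == 0L)) {
    stop("samples must be non-empty")
  }
  set.seed(seed)
  if (paired || is.null(y)) {
    if (paired) {
      if (length(x) != length(y)) stop("paired test requires equal lengths")
      d <- x - y
      method <- "paired t"
    } else {
      d <- x
      method <- "one-sample t"
    }
    res <- boot_t_one_sample(d, B)
    dsd <- stats::sd(d)
    cohen <- if (is.na(dsd) || dsd == 0) 0 else mean(d) / dsd
    return(boot_result(res$t, res$p, B, seed, method,
                       list(cohen_d = cohen)))
  }
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0 || is.na(sp2)) {
    return(boot_result(0, 1, B, seed, "two-sample t", list(cohen_d = 0)))
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_obs <- (mean(x) - mean(y)) / se
  x0 <- x - mean(x); y0 <- y - mean(y)
  mx <- matrix(sample(x0, n1 * B, replace = TRUE), n1, B)
  my <- matrix(sample(y0, n2 * B, replace = TRUE), n2, B)
  mbx <- colMeans(mx); mby <- colMeans(my)
  vx <- pmax((colMeans(mx * mx) - mbx^2) * n1 / (n1 - 1), 0)
  vy <- pmax((colMeans(my * my) - mby^2) * n2 / (n2 - 1), 0)
  sp2b <- ((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)
  tb <- ifelse(sp2b > 0,
               (mbx - mby) / sqrt(sp2b * (1 / n1 + 1 / n2)), NA_real_)
  p <- (sum(abs(tb) >= abs(t_obs), na.rm = TRUE) + 1) / (B + 1)
  boot_result(t_obs, p, B, seed, "two-sample t",
              list(cohen_d = (mean(x) - mean(y)) / sqrt(sp2)))
}

#' Bootstrap test of a Pearson correlation
#'
#' The observed statistic is the t transform of Pearson's r,
#' `t = r * sqrt((n - 2) / (1 - r^2))`. The null distribution is built by
#' pair-breaking resampling: `a` and `b` are resampled with replacement
#' independently of each other `B` times, destroying any pairing, and the
#' two-sided p-value is `(#{|t*| >= |t_obs|} + 1) / (B + 1)`. A perfect
#' correlation (|r| = 1) yields the minimum attainable p, `1 / (B + 1)`.
#'
#' @param a,b Equal-length numeric vectors, `n >= 4`.
#' @param B Number of bootstrap iterations (default 10,000).
#' @param seed Integer seed.
#' @return An `"itc_boot"` object with `r_observed` alongside the t
#'   statistic.
#' @export
bootstrap_correlation_test <- function(a, b, B = 10000L, seed = 1L) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 4L) stop("need at least 4 pairs")
  set.seed(seed)
  r_obs <- stats::cor(a, b)
  t_obs <- if (abs(r_obs) >= 1) Inf else r_obs * sqrt((n - 2) / (1 - r_obs^2))
  ma <- matrix(sample(a, n * B, replace = TRUE), n, B)
  mb <- matrix(sample(b, n * B, replace = TRUE), n, B)
  mam <- colMeans(ma); mbm <- colMeans(mb)
  va <- colMeans(ma * ma) - mam^2
  vb <- colMeans(mb * mb) - mbm^2
  denom <- sqrt(pmax(va, 0) * pmax(vb, 0))
  # degenerate resamples carry no correlation
  rb <- ifelse(denom > 0, (colMeans(ma * mb) - mam * mbm) / denom, NA_real_)
  rb <- pmin(pmax(rb, -1), 1)
  tb <- rb * sqrt((n - 2) / (1 - rb^2))
  p <- (sum(abs(tb) >= abs(t_obs), na.rm = TRUE) + 1) / (B + 1)
  boot_result(t_obs, p, B, seed, "correlation",
              list(r_observed = r_obs))
}

#' Mixed-design ANOVA (one within, one between factor)
#'
#' Standard two-way mixed sums-of-squares decomposition with participants
#' nested in groups and a two-level repeated factor, computed through
#' `stats::aov` with an `Error(participant)` stratum. Requires complete,
#' balanced phase data: every participant observed in both phases and
#' belonging to exactly one group.
#'
#' @param data Long data frame with columns `participant`, `group`, `phase`
#'   and `value` (here log10 k).
#' @return Data frame with rows `type` (between), `error_between`, `time`
#'   (within), `time_x_type`, `error_within`; columns `term`, `df`, `ss`,
#'   `ms`, `F`, `p`.
#' @export
mixed_anova <- function(data) {
  need <- c("participant", "group", "phase", "value")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "))
  }
  data$participant <- factor(data$participant)
  data$group <- factor(data$group)
  data$phase <- factor(data$phase)
  tab <- table(data$participant, data$phase)
  if (nlevels(data$phase) != 2L || any(tab != 1L)) {
    stop("unbalanced design: every participant needs exactly one ",
         "observation per phase (two phases)")
  }
  if (any(rowSums(table(data$participant, data$group) > 0) != 1L)) {
    stop("every participant must belong to exactly one group")
  }
  fit <- stats::aov(value ~ group * phase + Error(participant), data = data)
  s <- summary(fit)
  btw <- s[["Error: participant"]][[1L]]
  wtn <- s[["Error: Within"]][[1L]]
  row_of <- function(strat, name) {
    i <- match(name, trimws(rownames(strat)))
    c(df = strat[i, "Df"], ss = strat[i, "Sum Sq"])
  }
  g <- row_of(btw, "group"); eb <- row_of(btw, "Residuals")
  ph <- row_of(wtn, "phase"); ix <- row_of(wtn, "group:phase")
  ew <- row_of(wtn, "Residuals")
  make <- function(term, eff, err) {
    ms <- eff[["ss"]] / eff[["df"]]
    if (is.null(err)) {
      data.frame(term = term, df = eff[["df"]], ss = eff[["ss"]], ms = ms,
                 F = NA_real_, p = NA_real_)
    } else {
      mse <- err[["ss"]] / err[["df"]]
      Fv <- ms / mse
      data.frame(term = term, df = eff[["df"]], ss = eff[["ss"]], ms = ms,
                 F = Fv, p = stats::pf(Fv, eff[["df"]], err[["df"]],
                                       lower.tail = FALSE))
    }
  }
  rbind(make("type", g, eb),
        make("error_between", eb, NULL),
        make("time", ph, ew),
        make("time_x_type", ix, ew),
        make("error_within", ew, NULL))
}

#' Sliding-window accuracy series
#'
#' Bins a binary correctness trace into windows of `window` trials advanced
#' by `step` trials (default 10-trial windows with 5-trial overlap) and
#' reports each window's mean accuracy. The number of windows is
#' `floor((n - window) / step) + 1`.
#'
#' @param trace Numeric/integer 0-1 vector (or logical).
#' @param window Window length in trials (default 10).
#' @param step Window step in trials (default 5).
#' @return An `"accuracy_windows"` list: `values`, `window`, `step`,
#'   `n_windows`, `starts`.
#' @export
windowed_accuracy <- function(trace, window = 10L, step = 5L) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < window) stop("trace shorter than one window")
  starts <- seq(1L, n - window + 1L, by = step)
  values <- vapply(starts,
                   function(s) mean(trace[s:(s + window - 1L)]),
                   numeric(1L))
  structure(list(values = values, window = as.integer(window),
                 step = as.integer(step), n_windows = length(values),
                 starts = starts),
            class = "accuracy_windows")
}

#' Least-squares slope of an accuracy series
#'
#' Ordinary least-squares slope of window accuracy on 0-based window index:
#' the speed of task-performance change.
#'
#' @param series An [windowed_accuracy()] result or a numeric vector of
#'   window means.
#' @return Slope per window index.
#' @export
performance_slope <- function(series) {
  v <- if (inherits(series, "accuracy_windows")) series$values else
    as.numeric(series)
  if (length(v) < 2L) stop("need at least 2 windows")
  idx <- seq_along(v) - 1
  unname(stats::coef(stats::lm(v ~ idx))[2L])
}

#' Binned association between task performance and impulsivity change
#'
#' Divides a task of length `L` into five large overlapping bins (bin size
#' `floor(L/3)`, step `floor(L/6)`, the fifth bin right-anchored to the
#' trace end so all five fit), averages each participant's accuracy within
#' each bin, and correlates it across participants with the impulsivity
#' change `delta_log_k`.
#'
#' @param traces Numeric matrix, one row per participant, `L` columns of 0-1
#'   correctness (or a list of equal-length vectors).
#' @param effects Numeric vector of per-participant `delta_log_k`.
#' @return Data frame with one row per bin: `bin`, `start`, `end`, `r`.
#' @export
quintile_bin_association <- function(traces, effects) {
  if (is.list(traces)) traces <- do.call(rbind, traces)
  traces <- as.matrix(traces)
  if (nrow(traces) != length(effects)) {
    stop("one trace per effect value required")
  }
  L <- ncol(traces)
  size <- as.integer(floor(L / 3))
  step <- as.integer(floor(L / 6))
  if (size < 1L || step < 1L || (3L * step + size) > L) {
    stop("trace length ", L, " does not admit 5 bins of size floor(L/3) ",
         "with step floor(L/6)")
  }
  starts <- c(0L, step, 2L * step, 3L * step, L - size) + 1L
  out <- lapply(seq_along(starts), function(b) {
    s <- starts[b]
    acc <- rowMeans(traces[, s:(s + size - 1L), drop = FALSE])
    data.frame(bin = b, start = s, end = s + size - 1L,
               r = stats::cor(acc, effects))
  })
  do.call(rbind, out)
}
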