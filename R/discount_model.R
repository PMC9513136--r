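# Hyperbolic discounting + softmax choice model and its individual-level
# maximum-likelihood estimator.

#' Discounting parameters
#'
#' @param k Discount rate, dimensionless per day, strictly inside (0, 1).
#' @param mu Inverse temperature, per KRW, `mu >= 0`. It scales subjective
#'   value differences measured in KRW, hence its small typical magnitude
#'   (around 1e-4 to 1e-3).
#' @return An object of class `"discount_params"`.
#' @export
discount_params <- function(k, mu) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (k <= 0 || k >= 1) stop("k must lie strictly inside (0, 1)")
  if (mu < 0) stop("mu must be >= 0")
  structure(list(k = k, mu = mu), class = "discount_params")
}

#' Hyperbolic subjective value
#'
#' `SV = V / (1 + k * D)`: the present subjective value of a reward of `V`
#' KRW delivered after `D` days under hyperbolic discounting with rate `k`.
#'
#' @param V Reward magnitude in KRW, `V > 0`. Vectorised.
#' @param D Delay in days, `D >= 0`. Vectorised.
#' @param k Discount rate in (0, 1).
#' @return Subjective value in KRW.
#' @export
subjective_value <- function(V, D, k) {
  if (any(V <= 0)) stop("reward V must be positive")
  if (any(D < 0)) stop("delay D must be non-negative")
  if (length(k) != 1L || !is.finite(k) || k <= 0 || k >= 1) {
    stop("k must lie strictly inside (0, 1)")
  }
  V / (1 + k * D)
}

#' Softmax probability of choosing the immediate option
#'
#' `P(immediate) = 1 / (1 + exp(-mu * (SV_immediate - SV_delayed)))`.
#' Computed with a numerically stable logistic, so extreme subjective-value
#' differences do not overflow. `mu = 0` yields 0.5 regardless of values.
#'
#' @param sv_immediate,sv_delayed Subjective values in KRW. Vectorised.
#' @param mu Inverse temperature, `mu >= 0`.
#' @param log.p Return log probability instead.
#' @return Probability in (0, 1) (or its log).
#' @export
p_immediate <- function(sv_immediate, sv_delayed, mu, log.p = FALSE) {
  if (length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("mu must be a finite non-negative scalar")
  }
  stats::plogis(mu * (sv_immediate - sv_delayed), log.p = log.p)
}

# Extract the columns the likelihood needs, with light validation.
choice_matrix <- function(trials) {
  need <- c("delay_days", "immediate_krw", "delayed_krw", "choice")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("empty trial list")
  bad <- !trials$choice %in% c("immediate", "delayed")
  if (any(bad)) {
    stop("unknown choice label(s): ",
         paste(unique(trials$choice[bad]), collapse = ", "))
  }
  list(D = as.numeric(trials$delay_days),
       imm = as.numeric(trials$immediate_krw),
       Vd = as.numeric(trials$delayed_krw),
       sgn = ifelse(trials$choice == "immediate", 1, -1))
}

#' Negative log-likelihood of a choice set
#'
#' `-sum(log P(observed choice))` under the hyperbolic + softmax model.
#' Invariant to trial order; finite for finite `mu`.
#'
#' @param params A [discount_params()] (or any list with `k` and `mu`).
#' @param trials Trial records with columns `delay_days`, `immediate_krw`,
#'   `delayed_krw`, `choice`.
#' @return The negative log-likelihood (natural log), a non-negative scalar.
#' @export
negative_log_likelihood <- function(params, trials) {
  cm <- choice_matrix(trials)
  sv_d <- cm$Vd / (1 + params$k * cm$D)
  z <- cm$sgn * params$mu * (cm$imm - sv_d)
  -sum(stats::plogis(z, log.p = TRUE))
}

# Multi-start locations: a Latin square over the plausible (log10 k,
# log10 mu) box with small seeded jitter.
mle_start_grid <- function(n_starts) {
  lk <- seq(-4, -0.5, length.out = n_starts)
  lm <- seq(-5, -2, length.out = n_starts)
  if (n_starts > 1L) lm <- lm[sample.int(n_starts)]
  jit <- function(v, half) v + stats::runif(length(v), -half, half)
  if (n_starts > 1L) {
    lk <- jit(lk, diff(range(lk)) / (2 * (n_starts - 1L)))
    lm <- jit(lm, 1.5 / (n_starts - 1L))
  }
  cbind(log10_k = lk, log10_mu = lm)
}

#' Fit the discounting model to one participant-session by maximum likelihood
#'
#' Minimises the negative log-likelihood with Nelder-Mead from `n_starts`
#' stratified starting points. The search runs in an unconstrained space:
#' `k = plogis(a)` keeps the discount rate inside (0, 1) and `mu = exp(b)`
#' keeps the inverse temperature positive. The best optimum (ties broken by
#' the smaller `k`) is returned together with all per-start optima, and the
#' solution is flagged non-unique when distinct optima tie in likelihood,
#' when the estimate sits on the parameter boundary, or when the participant
#' chose a single option throughout (see [check_unique_solution()]).
#'
#' @param trials Trial records (>= 2 trials, at least two distinct offers).
#' @param n_starts Number of optimizer starts (default 10).
#' @param seed Integer seed controlling start-point jitter; the fit is
#'   deterministic given `seed`.
#' @param nll_tol,param_tol Uniqueness tolerances passed to
#'   [check_unique_solution()].
#' @return An object of class `"itc_fit"`: `params` ([discount_params()]),
#'   `log10_k`, `log_likelihood`, `n_starts`, `converged`, `unique`,
#'   `start_optima` (data frame of per-start optima), `n_trials`.
#' @export
fit_mle <- function(trials, n_starts = 10L, seed = 1L,
                    nll_tol = 0.01, param_tol = 0.1) {
  cm <- choice_matrix(trials)
  if (length(cm$D) < 2L) stop("need at least 2 trials to fit")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  if (nrow(unique(cbind(cm$D, cm$Vd))) < 2L) {
    stop("degenerate input: all trials present the identical offer")
  }
  set.seed(seed)
  obj <- function(theta) {
    k <- stats::plogis(theta[1L])
    mu <- exp(theta[2L])
    z <- cm$sgn * mu * (cm$imm - cm$Vd / (1 + k * cm$D))
    -sum(stats::plogis(z, log.p = TRUE))
  }
  starts <- mle_start_grid(n_starts)
  opt <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    theta0 <- c(stats::qlogis(10^starts[s, 1L]), log(10^starts[s, 2L]))
    res <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-10))
    k_hat <- stats::plogis(res$par[1L])
    opt[[s]] <- data.frame(k = k_hat,
                           mu = exp(res$par[2L]),
                           log10_k = log10(k_hat),
                           nll = res$value,
                           convergence = res$convergence)
  }
  optima <- do.call(rbind, opt)
  ord <- order(optima$nll, optima$k)
  optima <- optima[ord, , drop = FALSE]
  rownames(optima) <- NULL
  best <- optima[1L, ]
  fit <- structure(list(params = discount_params(best$k, best$mu),
                        log10_k = best$log10_k,
                        log_likelihood = -best$nll,
                        n_starts = n_starts,
                        converged = best$convergence == 0,
                        unique = NA,
                        start_optima = optima,
                        n_trials = length(cm$D)),
                   class = "itc_fit")
  one_sided <- length(unique(cm$sgn)) == 1L
  fit$unique <- !one_sided &&
    check_unique_solution(fit, nll_tol = nll_tol, param_tol = param_tol)
  fit
}

#' Is the maximum-likelihood solution unique?
#'
#' Flags fits whose likelihood surface does not identify the discount rate:
#' returns `FALSE` when two converged optima have a negative log-likelihood
#' within `nll_tol` of the best but discount rates further than `param_tol`
#' apart in log10 units, or when the best estimate sits at the edge of the
#' admissible (0, 1) range for `k` (below 10^-4.5 or above 0.995), where the
#' staircase carries no information about its exact value.
#'
#' @param fit An `"itc_fit"` from [fit_mle()] (needs >= 1 start optimum;
#'   ridge detection requires >= 2).
#' @param nll_tol Likelihood tie tolerance (natural-log units).
#' @param param_tol Discount-rate tolerance in log10 units.
#' @return Logical.
#' @export
check_unique_solution <- function(fit, nll_tol = 0.01, param_tol = 0.1) {
  optima <- fit$start_optima
  conv <- optima[optima$convergence == 0, , drop = FALSE]
  if (nrow(conv) == 0L) return(FALSE)
  best <- conv[which.min(conv$nll), ]
  if (best$log10_k < -4.5 || best$k > 0.995) return(FALSE)
  near <- conv$nll <= best$nll + nll_tol
  !any(abs(conv$log10_k[near] - best$log10_k) > param_tol)
}

#' Dense grid search of the likelihood surface
#'
#' Brute-force reference minimiser: evaluates the negative log-likelihood on
#' a regular grid in (log10 k, log10 mu) and returns the grid minimum. Meant
#' as an independent check of [fit_mle()] on small fixtures, not as an
#' estimator.
#'
#' @param trials Trial records.
#' @param log10_k_range,log10_mu_range Numeric length-2 ranges.
#' @param n_grid Points per axis (default 200).
#' @return List with `k`, `mu`, `log10_k`, `log10_mu`, `nll`.
#' @export
grid_search_nll <- function(trials,
                            log10_k_range = c(-4, 0),
                            log10_mu_range = c(-5, -1),
                            n_grid = 200L) {
  cm <- choice_matrix(trials)
  lk <- seq(log10_k_range[1L], log10_k_range[2L], length.out = n_grid)
  lm <- seq(log10_mu_range[1L], log10_mu_range[2L], length.out = n_grid)
  ks <- 10^lk
  # rows: k grid, cols: trials
  dv <- outer(ks, seq_along(cm$D),
              function(k, j) cm$imm[j] - cm$Vd[j] / (1 + k * cm$D[j]))
  dv <- sweep(dv, 2L, cm$sgn, `*`)
  best <- list(nll = Inf)
  for (j in seq_along(lm)) {
    mu <- 10^lm[j]
    nll <- -rowSums(stats::plogis(mu * dv, log.p = TRUE))
    i <- which.min(nll)
    if (nll[i] < best$nll) {
      best <- list(k = ks[i], mu = mu, log10_k = lk[i], log10_mu = lm[j],
                   nll = nll[i])
    }
  }
  best
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "ITC hyperbolic-softmax fit: k = %.5g (log10 k = %.3f), mu = %.4g\n",
    x$params$k, x$log10_k, x$params$mu))
  cat(sprintf("  logLik = %.3f over %d trials; %d starts; unique: %s\n",
              x$log_likelihood, x$n_trials, x$n_starts, x$unique))
  invisible(x)
}
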