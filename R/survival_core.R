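# Kaplan-Meier estimation, step-function quantiles, two-sample log-rank test
# and Cox partial-likelihood fitting. These primitives are written out in full
# because the log-rank statistic doubles as the split criterion of the
# survival trees and must be callable tens of thousands of times per run.

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of a right-censored time-to-event sample
#' with a Greenwood-variance confidence band. Ties between events and
#' censorings at the same time are handled events-first (the standard
#' product-limit convention): an observation censored at `t` is still at risk
#' for events occurring at `t`.
#'
#' @param time positive event/censoring times (days).
#' @param event event indicator, 1 = converted/observed, 0 = right-censored.
#' @param conf_level confidence level for the pointwise band (default 0.95).
#'
#' @return An object of class `km_curve`: a list with `time` (unique event
#'   times, increasing), `n_risk`, `n_event`, `surv`, `lower`, `upper`
#'   (plain Greenwood band, clipped to `[0, 1]`), `n_total` and `conf_level`.
#' @examples
#' km <- km_estimate(c(1, 2, 2, 3, 4), c(1, 0, 1, 1, 0))
#' km$surv   # 0.8 0.6 0.3
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  check_surv_input(time, event)
  if (conf_level <= 0 || conf_level >= 1) {
    stop("'conf_level' must be in (0, 1)", call. = FALSE)
  }
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) {
    out <- list(
      time = numeric(0), n_risk = integer(0), n_event = integer(0),
      surv = numeric(0), lower = numeric(0), upper = numeric(0),
      n_total = n, conf_level = conf_level
    )
    class(out) <- "km_curve"
    return(out)
  }
  # pos[i]: index of the last event time <= time[i]; time[i] >= ut[j] <=> pos[i] >= j
  pos <- findInterval(time, ut)
  n_risk <- rev(cumsum(rev(tabulate(pos, nbins = length(ut)))))
  n_event <- tabulate(pos[event == 1], nbins = length(ut))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood plain (linear) band: S +/- z * S * sqrt(sum d / (n (n - d)))
  gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1)))
  gw[n_risk == n_event] <- Inf # variance of log S undefined once S hits 0
  se <- surv * sqrt(gw)
  se[surv == 0] <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(
    time = ut, n_risk = n_risk, n_event = n_event, surv = surv,
    lower = pmax(surv - z * se, 0), upper = pmin(surv + z * se, 1),
    n_total = n, conf_level = conf_level
  )
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier curve: n = %d, %d event times, %.0f%% Greenwood band\n",
    x$n_total, length(x$time), 100 * x$conf_level
  ))
  med <- quantile_time(x, 0.5)
  cat(
    " median time:",
    if (is.na(med)) "not reached" else format(med), "\n"
  )
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(
    time = x$time, n_risk = x$n_risk, n_event = x$n_event,
    surv = x$surv, lower = x$lower, upper = x$upper
  )
}

#' Time at which a given fraction has converted
#'
#' Step-function quantile of a Kaplan-Meier curve: the smallest observed
#' event time `t` with `S(t) <= 1 - p`. With `p = 0.5` this is the median
#' time to conversion; with `p = 0.25` it is the time at which the estimated
#' probability of having converted reaches 25% (reported as "Q3" in clinical
#' summaries, and used as the reference when the median is not reached).
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param p converted fraction, in (0, 1).
#' @return The quantile time in the units of the input, or `NA_real_` when
#'   the curve never drops to `1 - p` (quantile not reached).
#' @export
quantile_time <- function(curve, p) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("'p' must be a single number in (0, 1)", call. = FALSE)
  }
  hit <- which(curve$surv <= 1 - p + 1e-12)
  if (length(hit) == 0L) NA_real_ else curve$time[hit[1L]]
}

#' Maximum Greenwood confidence half-width over an interval
#'
#' Utility mirroring the robustness check used when a cohort is too censored
#' for its median to be reached: the maximal half-width of the Kaplan-Meier
#' confidence band over `[0, t_max]` (smaller means a better-determined
#' curve).
#'
#' @param curve a `km_curve`.
#' @param t_max right end of the interval (same units as the curve).
#' @return the maximum of `(upper - lower) / 2` over event times in the
#'   interval; 0 if the interval contains no event time.
#' @export
max_ci_half_width <- function(curve, t_max) {
  stopifnot(inherits(curve, "km_curve"), is.numeric(t_max), t_max > 0)
  keep <- curve$time <= t_max
  if (!any(keep)) return(0)
  max((curve$upper[keep] - curve$lower[keep]) / 2)
}

#' Two-sample log-rank test
#'
#' Standard (unweighted) log-rank test comparing the survival distributions
#' of two right-censored samples, with the hypergeometric variance at each
#' event time and a chi-square(1) reference distribution.
#'
#' @param time_a,event_a times and event indicators of the first group.
#' @param time_b,event_b times and event indicators of the second group.
#' @return An object of class `logrank_test`: list with `statistic`,
#'   `p_value`, `observed` and `expected` (length-2, per group), `n`.
#' @examples
#' lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 0))
#' lr$p_value
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  check_surv_input(time_a, event_a)
  check_surv_input(time_b, event_b)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  if (!any(event == 1)) {
    stop("log-rank statistic undefined: no events in the pooled sample",
      call. = FALSE
    )
  }
  grp <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  tab <- logrank_table(time, event, grp)
  stat <- if (tab$var_sum <= 0) 0 else (tab$obs1 - tab$exp1)^2 / tab$var_sum
  out <- list(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    observed = c(tab$obs1, tab$obs_total - tab$obs1),
    expected = c(tab$exp1, tab$obs_total - tab$exp1),
    n = c(length(time_a), length(time_b))
  )
  class(out) <- "logrank_test"
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chisq = %.4g on 1 df, p = %.4g\n  n = (%d, %d), observed = (%.0f, %.0f), expected = (%.2f, %.2f)\n",
    x$statistic, x$p_value, x$n[1], x$n[2],
    x$observed[1], x$observed[2], x$expected[1], x$expected[2]
  ))
  invisible(x)
}

# Observed/expected/variance tabulation shared by logrank_test and the tree
# split scan. Returns sums over distinct event times for group 1 (grp TRUE).
logrank_table <- function(time, event, grp) {
  d <- event == 1
  ut <- sort(unique(time[d]))
  k <- length(ut)
  pos <- findInterval(time, ut)
  n_at <- rev(cumsum(rev(tabulate(pos, nbins = k))))
  n1_at <- rev(cumsum(rev(tabulate(pos[grp], nbins = k))))
  d_at <- tabulate(pos[d], nbins = k)
  d1_at <- tabulate(pos[d & grp], nbins = k)
  frac <- n1_at / n_at
  v <- d_at * frac * (1 - frac) * (n_at - d_at) / pmax(n_at - 1, 1)
  v[n_at <= 1] <- 0
  list(
    obs1 = sum(d1_at), exp1 = sum(d_at * frac),
    obs_total = sum(d_at), var_sum = sum(v)
  )
}

# Fast scalar log-rank statistic for the split search. `grp` logical.
# Returns 0 for degenerate tabulations (no events, one-sided risk sets).
lr_stat <- function(time, event, grp) {
  if (!any(event == 1) || all(grp) || !any(grp)) return(0)
  tab <- logrank_table(time, event, grp)
  if (tab$var_sum <= 0) return(0)
  (tab$obs1 - tab$exp1)^2 / tab$var_sum
}

#' Cox proportional-hazards fit by partial likelihood
#'
#' Maximizes the Cox partial likelihood with Breslow handling of tied event
#' times by Newton-Raphson with step halving, to a gradient max-norm below
#' `tol` or `max_iter` iterations. Used in the pipeline to adjust subgroup
#' effects for the number of comorbidities.
#'
#' @param time positive times; @param event 0/1 indicators.
#' @param x covariate matrix (or vector for a single covariate); columns must
#'   be non-constant and linearly independent.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `cox_fit`: `coef`, `hazard_ratio = exp(coef)`,
#'   `se`, `z`, `p_value` (Wald), `loglik` (partial, at the optimum),
#'   `loglik_null`, `iter`, `converged`.
#' @export
cox_fit <- function(time, event, x, tol = 1e-8, max_iter = 100L) {
  check_surv_input(time, event)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(time)) {
    stop("covariate matrix has ", nrow(x), " rows but ", length(time),
      " observations",
      call. = FALSE
    )
  }
  if (any(apply(x, 2, function(col) diff(range(col)) == 0))) {
    stop("degenerate design: constant covariate column", call. = FALSE)
  }
  if (qr(x)$rank < ncol(x)) {
    stop("degenerate design: linearly dependent covariate columns",
      call. = FALSE
    )
  }
  if (sum(event) < ncol(x)) {
    stop("fewer events than covariates", call. = FALSE)
  }

  # sort by time; tied event times grouped for the Breslow denominator
  o <- order(time)
  time <- time[o]; event <- event[o]; x <- x[o, , drop = FALSE]
  p <- ncol(x)
  d <- event == 1
  ut <- unique(time[d]) # already sorted
  pos <- findInterval(time, ut) # risk set at ut[j] = {i : pos[i] >= j}
  k <- length(ut)
  d_at <- tabulate(pos[d], nbins = k)
  grad0 <- colSums(x[d, , drop = FALSE]) # sum of x over all events

  partial_ll <- function(beta) {
    eta <- drop(x %*% beta)
    shift <- max(eta)
    s0 <- rev_cumsum_by(exp(eta - shift), pos, k)
    sum(eta[d]) - sum(d_at * (log(s0) + shift))
  }

  beta <- rep(0, p)
  ll <- partial_ll(beta)
  loglik_null <- ll
  converged <- FALSE
  iter <- 0L
  vmat <- diag(p)
  while (iter <= max_iter) {
    eta <- drop(x %*% beta)
    th <- exp(eta - max(eta))
    mom <- cox_moments(x, th, pos, k)
    mu <- mom$s1 / mom$s0 # k x p weighted covariate means over risk sets
    grad <- grad0 - colSums(d_at * mu)
    for (a in seq_len(p)) {
      for (b in seq_len(p)) {
        vmat[a, b] <- sum(d_at * (mom$s2[, (a - 1L) * p + b] / mom$s0 -
          mu[, a] * mu[, b]))
      }
    }
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    if (iter == max_iter) break
    step <- tryCatch(solve(vmat, grad),
      error = function(e) grad / max(diag(vmat), 1)
    )
    # step halving so the partial likelihood never decreases
    ll_new <- -Inf
    for (h in 0:30) {
      cand <- beta + step / 2^h
      ll_new <- partial_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    beta <- cand
    ll <- ll_new
    iter <- iter + 1L
  }
  vmat_inv <- tryCatch(solve(vmat), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vmat_inv), 0))
  z <- beta / se
  out <- list(
    coef = stats::setNames(beta, colnames(x)),
    hazard_ratio = stats::setNames(exp(beta), colnames(x)),
    se = stats::setNames(se, colnames(x)),
    z = z,
    p_value = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(x)),
    loglik = ll, loglik_null = loglik_null,
    iter = iter, converged = converged
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox partial-likelihood fit (%s, %d iterations)\n",
    if (x$converged) "converged" else "NOT CONVERGED", x$iter
  ))
  print(data.frame(
    coef = x$coef, HR = x$hazard_ratio, se = x$se, p = x$p_value
  ))
  invisible(x)
}

# S0, S1, S2 risk-set moments at each distinct event time (Breslow).
# th: exp(eta) per observation sorted by time; pos: event-time interval index.
cox_moments <- function(x, th, pos, k) {
  p <- ncol(x)
  s0 <- rev_cumsum_by(th, pos, k)
  s1 <- matrix(0, k, p)
  s2 <- matrix(0, k, p * p)
  for (a in seq_len(p)) {
    s1[, a] <- rev_cumsum_by(th * x[, a], pos, k)
    for (b in seq_len(p)) {
      s2[, (a - 1) * p + b] <- rev_cumsum_by(th * x[, a] * x[, b], pos, k)
    }
  }
  list(s0 = s0, s1 = s1, s2 = s2)
}

# sum of w over observations with pos >= j, for j = 1..k
rev_cumsum_by <- function(w, pos, k) {
  keep <- pos >= 1L
  sums <- numeric(k)
  if (any(keep)) {
    agg <- rowsum(w[keep], pos[keep])
    sums[as.integer(rownames(agg))] <- agg
  }
  rev(cumsum(rev(sums)))
}

# rowsum of a matrix by integer group 1..k with zero-filled missing groups
rowsum_by <- function(m, g, k) {
  out <- matrix(0, k, ncol(m))
  agg <- rowsum(m, g)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input", call. = FALSE)
  if (length(time) != length(event)) {
    stop("'time' and 'event' lengths differ", call. = FALSE)
  }
  if (anyNA(time) || anyNA(event)) {
    stop("missing values in survival input", call. = FALSE)
  }
  if (any(time <= 0)) stop("all times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) {
    stop("'event' must be coded 0/1", call. = FALSE)
  }
  invisible(TRUE)
}
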