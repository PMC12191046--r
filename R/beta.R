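#' Beta prior/posterior parameters
#'
#' Constructs a `beta_params` object, the pseudo-count parameterization
#' `beta(alpha, beta)` used throughout the package for response and toxicity
#' probabilities. `alpha` counts events (responders or toxicities), `beta`
#' counts non-events; the effective sample size (ESS) of the distribution is
#' `alpha + beta` and its mean is `alpha / (alpha + beta)`.
#'
#' @param alpha Positive event pseudo-count.
#' @param beta Positive non-event pseudo-count.
#' @return An object of class `beta_params`.
#' @examples
#' beta_params(8.5, 12.5)
#' @seealso [prior_from_mean()], [update_beta()]
#' @export
beta_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0 || beta <= 0)
    stop("beta parameters must be strictly positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("beta(%g, %g)  mean = %.4g  ESS = %g\n",
              x$alpha, x$beta, posterior_mean(x), ess(x)))
  invisible(x)
}

#' @export
format.beta_params <- function(x, ...) sprintf("beta(%g, %g)", x$alpha, x$beta)

is_beta_params <- function(x) inherits(x, "beta_params")

#' Effective sample size of a beta distribution
#'
#' The ESS `alpha + beta` quantifies a prior's informational weight relative
#' to observed patients: a posterior mean gives weight `n / (n + ESS)` to the
#' sample proportion and `ESS / (n + ESS)` to the prior mean.
#'
#' @param p A [beta_params()] object.
#' @return The effective sample size, a positive number.
#' @export
ess <- function(p) {
  stopifnot(is_beta_params(p))
  p$alpha + p$beta
}

#' Elicit a beta prior from its mean and effective sample size
#'
#' Standard operational-prior construction for small trials: elicit the
#' expert's mean probability, fix the ESS at a small value (typically 1, at
#' most 2, so that the data dominate), and solve `mean = alpha/(alpha+beta)`,
#' `ess = alpha + beta` for the pseudo-counts.
#'
#' @param mean Prior mean, strictly inside (0, 1). Degenerate endpoint means
#'   are rejected rather than clamped.
#' @param ess Effective sample size, a positive number.
#' @return A [beta_params()] object with `alpha = mean * ess`,
#'   `beta = (1 - mean) * ess`.
#' @examples
#' prior_from_mean(0.40, 1)   # beta(0.40, 0.60)
#' prior_from_mean(0.80, 1)   # optimistic mean, ESS still 1
#' @export
prior_from_mean <- function(mean, ess) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(ess), length(ess) == 1L)
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("prior mean must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(ess) || ess <= 0)
    stop("prior effective sample size must be positive", call. = FALSE)
  beta_params(mean * ess, (1 - mean) * ess)
}

#' Binomial count data
#'
#' `events` out of `total` evaluated patients. Also accepts the compact
#' "x/n" string form used in trial reports, e.g. `binom_count("8/20")`.
#'
#' @param events Non-negative integer count of patients with the outcome, or
#'   a single "x/n" string.
#' @param total Non-negative integer count of evaluated patients (omitted
#'   when `events` is an "x/n" string).
#' @return An object of class `binom_count` with fields `events` and `total`.
#' @examples
#' binom_count(8, 20)
#' binom_count("9/10")
#' @export
binom_count <- function(events, total) {
  if (is.character(events)) {
    stopifnot(length(events) == 1L, missing(total))
    parts <- strsplit(trimws(events), "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("count string must have the form \"x/n\"", call. = FALSE)
    events <- as.numeric(parts[1L])
    total <- as.numeric(parts[2L])
  }
  stopifnot(is.numeric(events), length(events) == 1L,
            is.numeric(total), length(total) == 1L)
  if (is.na(events) || is.na(total) ||
      events != round(events) || total != round(total))
    stop("counts must be integers", call. = FALSE)
  if (events < 0 || total < 0 || events > total)
    stop("need 0 <= events <= total", call. = FALSE)
  structure(list(events = as.integer(events), total = as.integer(total)),
            class = "binom_count")
}

#' @export
print.binom_count <- function(x, ...) {
  cat(sprintf("%d/%d\n", x$events, x$total))
  invisible(x)
}

as_binom_count <- function(x, total = NULL) {
  if (inherits(x, "binom_count")) return(x)
  if (is.character(x)) return(binom_count(x))
  if (!is.null(total)) return(binom_count(x, total))
  stop("cannot interpret binomial count", call. = FALSE)
}

#' Conjugate beta-binomial posterior update
#'
#' For `X` events in `n` patients with probability `theta ~ beta(a, b)`, the
#' posterior is `beta(a + X, b + n - X)`.
#'
#' @param prior A [beta_params()] prior.
#' @param data A [binom_count()] object, or an "x/n" string.
#' @return The posterior [beta_params()].
#' @examples
#' update_beta(beta_params(0.5, 0.5), binom_count(8, 20))  # beta(8.5, 12.5)
#' @export
update_beta <- function(prior, data) {
  stopifnot(is_beta_params(prior))
  data <- as_binom_count(data)
  beta_params(prior$alpha + data$events,
              prior$beta + data$total - data$events)
}

#' Posterior (or prior) mean of a beta distribution
#'
#' @param p A [beta_params()] object.
#' @return `alpha / (alpha + beta)`.
#' @examples
#' posterior_mean(beta_params(8.5, 12.5))  # 8.5/21 = 0.405
#' @export
posterior_mean <- function(p) {
  stopifnot(is_beta_params(p))
  p$alpha / (p$alpha + p$beta)
}

#' Shrinkage weights of the posterior mean
#'
#' The posterior mean is the weighted average
#' `w_data * (X/n) + w_prior * prior mean` with `w_data = n / (n + ESS)` and
#' `w_prior = ESS / (n + ESS)`: Bayesian estimators shrink the empirical rate
#' toward the prior mean, the more so the larger the prior ESS.
#'
#' @param prior A [beta_params()] prior.
#' @param data A [binom_count()] object or "x/n" string. With `n = 0` the
#'   weights are defined as `(0, 1)`.
#' @return Named numeric vector `c(weight_data, weight_prior)` summing to 1.
#' @export
shrinkage_weights <- function(prior, data) {
  stopifnot(is_beta_params(prior))
  data <- as_binom_count(data)
  n <- data$total
  e <- ess(prior)
  c(weight_data = n / (n + e), weight_prior = e / (n + e))
}

#' Interval summary
#'
#' A `level` credible interval `[lower, upper]`:
#' `Pr(lower < theta < upper | data) = level`.
#'
#' @param level Probability in (0, 1).
#' @param lower,upper Interval endpoints, `lower <= upper`.
#' @return An object of class `cred_interval`.
#' @export
cred_interval <- function(level, lower, upper) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1,
            is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, lower <= upper)
  structure(list(level = level, lower = lower, upper = upper),
            class = "cred_interval")
}

#' @export
print.cred_interval <- function(x, digits = 2, ...) {
  cat(sprintf("%g%% CrI [%.*f, %.*f]\n", 100 * x$level,
              digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Equal-tailed credible interval for a beta parameter
#'
#' Endpoints are the `(1 - level)/2` and `1 - (1 - level)/2` beta quantiles,
#' so the interval is equal-tailed (not highest posterior density), matching
#' the convention used throughout for reporting.
#'
#' @param p A [beta_params()] object.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return A [cred_interval()].
#' @examples
#' credible_interval(beta_params(8.5, 12.5))  # [0.21, 0.62]
#' @export
credible_interval <- function(p, level = 0.95) {
  stopifnot(is_beta_params(p), is.numeric(level), length(level) == 1L,
            level > 0, level < 1)
  a <- (1 - level) / 2
  cred_interval(level,
                stats::qbeta(a, p$alpha, p$beta),
                stats::qbeta(1 - a, p$alpha, p$beta))
}

#' Posterior tail probability of a beta parameter
#'
#' `Pr(theta > threshold | p)` (`direction = "above"`) or
#' `Pr(theta < threshold | p)` (`direction = "below"`); the two sum to one
#' for this continuous distribution. These tail probabilities are the raw
#' material of the posterior stopping criteria.
#'
#' @param p A [beta_params()] object.
#' @param threshold Probability threshold in \[0, 1\].
#' @param direction `"above"` or `"below"`.
#' @return A probability.
#' @examples
#' tail_probability(beta_params(5.3, 3.7), 0.30, "above")
#' @export
tail_probability <- function(p, threshold, direction = c("above", "below")) {
  stopifnot(is_beta_params(p), is.numeric(threshold),
            length(threshold) == 1L, threshold >= 0, threshold <= 1)
  direction <- match.arg(direction)
  stats::pbeta(threshold, p$alpha, p$beta,
               lower.tail = (direction == "below"))
}

# ---- exponential-gamma machinery for event times ---------------------------

#' Gamma parameters for an exponential event-rate
#'
#' Conjugate prior/posterior for the hazard `lambda` of exponentially
#' distributed event times: `lambda ~ gamma(shape, rate)` with `rate` in
#' units of follow-up time.
#'
#' @param shape Positive shape parameter.
#' @param rate Positive rate parameter (per unit follow-up time).
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(shape, rate) {
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (shape <= 0 || rate <= 0)
    stop("gamma parameters must be strictly positive", call. = FALSE)
  structure(list(shape = shape, rate = rate), class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf("gamma(%g, %g)  mean hazard = %.4g\n",
              x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

#' Event-time data summary
#'
#' `n_events` observed events over `total_time` patient-time units of
#' follow-up (censored follow-up included in `total_time`).
#'
#' @param n_events Non-negative integer event count.
#' @param total_time Non-negative total follow-up time; must be positive
#'   whenever `n_events > 0`.
#' @return An object of class `event_time_data`.
#' @export
event_time_data <- function(n_events, total_time) {
  stopifnot(is.numeric(n_events), length(n_events) == 1L,
            n_events >= 0, n_events == round(n_events),
            is.numeric(total_time), length(total_time) == 1L,
            total_time >= 0)
  if (n_events > 0 && total_time <= 0)
    stop("total_time must be positive when events were observed",
         call. = FALSE)
  structure(list(n_events = as.integer(n_events), total_time = total_time),
            class = "event_time_data")
}

#' Conjugate exponential-gamma update
#'
#' With event times exponential(`lambda`) and `lambda ~ gamma(shape, rate)`,
#' observing `d` events over total follow-up `T` gives posterior
#' `gamma(shape + d, rate + T)`. Used for preliminary median PFS/OS
#' estimation alongside the binary-endpoint machinery.
#'
#' @param prior A [gamma_params()] prior.
#' @param data An [event_time_data()] summary.
#' @return The posterior [gamma_params()].
#' @export
update_gamma_exponential <- function(prior, data) {
  stopifnot(inherits(prior, "gamma_params"), inherits(data, "event_time_data"))
  gamma_params(prior$shape + data$n_events, prior$rate + data$total_time)
}

#' Equal-tailed credible interval for the median event time
#'
#' The median of an exponential(`lambda`) time is `log(2) / lambda`; the
#' transform is decreasing, so the interval endpoints are
#' `log(2) / (upper, lower hazard quantiles)` — swapped relative to the
#' hazard interval.
#'
#' @param p A [gamma_params()] posterior for the hazard.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return A [cred_interval()] for the median event time, in the follow-up
#'   time units of `p`.
#' @export
median_survival_interval <- function(p, level = 0.95) {
  stopifnot(inherits(p, "gamma_params"), level > 0, level < 1)
  a <- (1 - level) / 2
  cred_interval(level,
                log(2) / stats::qgamma(1 - a, p$shape, rate = p$rate),
                log(2) / stats::qgamma(a, p$shape, rate = p$rate))
}
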