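# Posterior comparison of arms: distribution of theta_E - theta_S for two
# independent beta posteriors, computed by deterministic quadrature.

#' CDF of the difference of two independent beta random variables
#'
#' Computes `Pr(theta_E - theta_S <= d | data)` for independent posteriors
#' `theta_E ~ postE`, `theta_S ~ postS`. Conditioning on `theta_S = v`,
#' the probability is `E_S[F_E(v + d)]`; substituting the quantile transform
#' `v = Q_S(u)` gives the smooth bounded integrand
#' `integral_0^1 F_E(Q_S(u) + d) du`, evaluated by adaptive quadrature
#' (absolute tolerance 1e-10). The quantile substitution avoids the endpoint
#' density singularities that non-informative priors (e.g. beta(0.5, 0.5)
#' posteriors) would otherwise place at 0 and 1.
#'
#' @param postE,postS [beta_params()] posteriors for the experimental and
#'   comparison arm.
#' @param d Difference threshold in \[-1, 1\].
#' @return `Pr(theta_E - theta_S <= d)`.
#' @examples
#' difference_cdf(beta_params(7.5, 8.5), beta_params(3.5, 12.5), 0)
#' @export
difference_cdf <- function(postE, postS, d) {
  stopifnot(is_beta_params(postE), is_beta_params(postS),
            is.numeric(d), length(d) == 1L, d >= -1, d <= 1)
  if (d >= 1) return(1)
  if (d <= -1) return(0)
  f <- function(u) {
    v <- stats::qbeta(u, postS$alpha, postS$beta) + d
    stats::pbeta(pmin(pmax(v, 0), 1), postE$alpha, postE$beta)
  }
  stats::integrate(f, 0, 1, abs.tol = 1e-10, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' Posterior improvement probability Pr(theta_E > theta_S + delta)
#'
#' The posterior probability that arm E improves on arm S by at least the
#' margin `delta` in event probability — the quantity used to judge whether
#' an experimental arm is promising (typical margins: `delta` = 0.15 or
#' 0.20).
#'
#' @inheritParams difference_cdf
#' @param delta Improvement margin; usually in \[0, 1\], negative allowed.
#' @return `1 - difference_cdf(postE, postS, delta)`.
#' @examples
#' # 7/15 responses on E vs 3/15 on S, beta(0.5, 0.5) priors:
#' improvement_probability(beta_params(7.5, 8.5), beta_params(3.5, 12.5), 0.20)
#' @export
improvement_probability <- function(postE, postS, delta = 0.15) {
  1 - difference_cdf(postE, postS, delta)
}

#' Equal-tailed credible interval for theta_E - theta_S
#'
#' Endpoints solve `difference_cdf = (1 - level)/2` and `1 - (1 - level)/2`
#' by bisection on \[-1, 1\] to absolute tolerance 1e-7 (at most 200 steps).
#'
#' @inheritParams difference_cdf
#' @param level Credibility level in (0, 1); default 0.95.
#' @return A [cred_interval()] for the difference.
#' @examples
#' difference_interval(beta_params(10.5, 5.5), beta_params(3.5, 12.5))
#' @export
difference_interval <- function(postE, postS, level = 0.95) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  target <- c((1 - level) / 2, 1 - (1 - level) / 2)
  solve_one <- function(p) {
    lo <- -1; hi <- 1
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (difference_cdf(postE, postS, mid) < p) lo <- mid else hi <- mid
      if (hi - lo < 1e-7) break
    }
    if (hi - lo >= 1e-7)
      stop("difference quantile bisection failed to converge", call. = FALSE)
    (lo + hi) / 2
  }
  cred_interval(level, solve_one(target[1L]), solve_one(target[2L]))
}

#' Posterior mean of theta_E - theta_S
#'
#' By linearity of expectation, the difference of the two posterior means.
#'
#' @inheritParams difference_cdf
#' @return A number in \[-1, 1\].
#' @export
difference_mean <- function(postE, postS) {
  posterior_mean(postE) - posterior_mean(postS)
}

#' Arm posterior
#'
#' A labelled [beta_params()] posterior, the unit of [compare_arms()].
#'
#' @param label Arm name (unique within a comparison set).
#' @param params A [beta_params()] posterior.
#' @return An object of class `arm_posterior`.
#' @export
arm_posterior <- function(label, params) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is_beta_params(params))
  structure(list(label = label, params = params), class = "arm_posterior")
}

#' Pairwise posterior comparison of arms against a reference
#'
#' For each non-reference arm, computes the posterior mean, equal-tailed
#' credible interval and improvement probabilities of
#' `theta_arm - theta_reference`, in input order.
#'
#' @param arms List of [arm_posterior()] objects (labels unique).
#' @param reference Label of the reference (control) arm.
#' @param deltas Improvement margins; default `c(0.15, 0.20)`.
#' @param level Credibility level; default 0.95.
#' @return A data frame of class `arm_comparison` with columns `contrast`,
#'   `mean`, `lower`, `upper`, and one `pr_improve_<delta>` column per
#'   margin.
#' @examples
#' arms <- list(
#'   arm_posterior("S",  update_beta(beta_params(0.5, 0.5), "5/9")),
#'   arm_posterior("E1", update_beta(beta_params(0.5, 0.5), "9/10")),
#'   arm_posterior("E2", update_beta(beta_params(0.5, 0.5), "10/11")))
#' compare_arms(arms, reference = "S", deltas = 0.15)
#' @export
compare_arms <- function(arms, reference, deltas = c(0.15, 0.20),
                         level = 0.95) {
  stopifnot(is.list(arms), length(arms) >= 2L,
            all(vapply(arms, inherits, logical(1L), "arm_posterior")),
            is.numeric(deltas), length(deltas) >= 1L)
  labels <- vapply(arms, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("arm labels must be unique", call. = FALSE)
  if (!reference %in% labels)
    stop(sprintf("reference arm '%s' not found", reference), call. = FALSE)
  ref <- arms[[match(reference, labels)]]$params
  others <- arms[labels != reference]
  rows <- lapply(others, function(a) {
    ci <- difference_interval(a$params, ref, level)
    probs <- vapply(deltas, function(d)
      improvement_probability(a$params, ref, d), numeric(1L))
    out <- data.frame(contrast = paste0(a$label, " - ", reference),
                      mean = difference_mean(a$params, ref),
                      lower = ci$lower, upper = ci$upper,
                      stringsAsFactors = FALSE)
    out[paste0("pr_improve_", format(deltas, trim = TRUE))] <-
      as.list(probs)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "deltas") <- deltas
  class(out) <- c("arm_comparison", "data.frame")
  out
}

#' @export
print.arm_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Posterior comparisons (%g%% CrI)\n",
              100 * attr(x, "level")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Stratum weight for a post-stratified comparison
#'
#' One stratum's contribution: its population weight and the two arms'
#' within-stratum event probabilities, each given either as a
#' [beta_params()] posterior or as a known numeric probability.
#'
#' @param weight Stratum weight in \[0, 1\]; weights sum to 1 across strata.
#' @param armE,armS [beta_params()] or a known probability in \[0, 1\].
#' @return An object of class `stratum_weight`.
#' @export
stratum_weight <- function(weight, armE, armS) {
  stopifnot(is.numeric(weight), length(weight) == 1L,
            weight >= 0, weight <= 1)
  chk <- function(x) {
    if (is_beta_params(x)) return(x)
    stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x <= 1)
    x
  }
  structure(list(weight = weight, armE = chk(armE), armS = chk(armS)),
            class = "stratum_weight")
}

stratum_mean <- function(x) if (is_beta_params(x)) posterior_mean(x) else x

#' Post-stratified weighted between-arm difference
#'
#' When treatment arms are imbalanced across strata, a fair overall
#' comparison averages the within-stratum differences with the stratum
#' population weights: `mean = sum_s w_s (mean_E,s - mean_S,s)`. The
#' credible interval is obtained from seeded Monte-Carlo draws of the
#' weighted difference (known probabilities contribute as constants).
#'
#' @param strata List of [stratum_weight()] objects; weights must sum to 1
#'   (tolerance 1e-9).
#' @param level Credibility level for the interval; default 0.95.
#' @param n_draws Number of Monte-Carlo draws; default 1e6.
#' @param seed Integer seed for the draws; default 1.
#' @return List with elements `mean` and `interval` (a [cred_interval()];
#'   degenerate when all strata carry known probabilities).
#' @examples
#' # two strata, known rates: overall Pr(event, E) contribution
#' post_stratified_difference(list(
#'   stratum_weight(0.20, 0.50, 0.60),
#'   stratum_weight(0.80, 0.25, 0.30)))$mean
#' @export
post_stratified_difference <- function(strata, level = 0.95,
                                       n_draws = 1e6, seed = 1L) {
  stopifnot(is.list(strata), length(strata) >= 1L,
            all(vapply(strata, inherits, logical(1L), "stratum_weight")))
  w <- vapply(strata, `[[`, numeric(1L), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("stratum weights must sum to 1", call. = FALSE)
  m <- sum(w * (vapply(strata, function(s) stratum_mean(s$armE), numeric(1L)) -
                vapply(strata, function(s) stratum_mean(s$armS), numeric(1L))))
  draw <- function(x, n) {
    if (is_beta_params(x)) stats::rbeta(n, x$alpha, x$beta) else rep(x, n)
  }
  any_random <- any(vapply(strata, function(s)
    is_beta_params(s$armE) || is_beta_params(s$armS), logical(1L)))
  if (any_random) {
    interval <- with_seed(seed, {
      diff <- rep(0, n_draws)
      for (s in strata)
        diff <- diff +
          s$weight * (draw(s$armE, n_draws) - draw(s$armS, n_draws))
      a <- (1 - level) / 2
      q <- stats::quantile(diff, c(a, 1 - a), names = FALSE)
      cred_interval(level, q[1L], q[2L])
    })
  } else {
    interval <- cred_interval(level, m, m)
  }
  list(mean = m, interval = interval)
}

# Evaluate code under a fixed RNG seed, restoring the caller's global RNG
# state afterwards so seeded package internals never disturb user code.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}
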