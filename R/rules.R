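# Posterior-probability stopping rules and their equivalent integer
# trigger boundaries.

#' Monitoring schedule
#'
#' The interim per-arm sample sizes at which a stopping rule is applied.
#' Looks are interim only: the final per-arm sample size `n_max` is not a
#' stopping look unless listed explicitly.
#'
#' @param looks Strictly increasing positive integers, all `<= n_max`.
#' @param n_max Per-arm maximum sample size.
#' @return An object of class `monitoring_schedule`.
#' @examples
#' monitoring_schedule(c(4, 8, 12), 16)
#' @export
monitoring_schedule <- function(looks, n_max) {
  stopifnot(is.numeric(looks), length(looks) >= 1L,
            all(looks == round(looks)), all(looks > 0),
            all(diff(looks) > 0),
            is.numeric(n_max), length(n_max) == 1L,
            n_max == round(n_max), n_max > 0, all(looks <= n_max))
  structure(list(looks = as.integer(looks), n_max = as.integer(n_max)),
            class = "monitoring_schedule")
}

#' Decision-cutoff specification
#'
#' Either a constant cutoff `c`, or the sample-size-dependent family
#' `alpha * (n / n_max)^beta` whose parameters are calibrated to achieve
#' target early-stopping probabilities. `beta = 0` recovers a constant
#' cutoff `alpha`.
#'
#' @param kind `"constant"` or `"power"`.
#' @param c Constant cutoff in (0, 1) (`kind = "constant"`).
#' @param alpha Scale in (0, 1\] (`kind = "power"`).
#' @param beta Non-negative exponent (`kind = "power"`).
#' @return An object of class `cutoff_spec`.
#' @examples
#' cutoff_spec("constant", c = 0.90)
#' cutoff_spec("power", alpha = 0.95, beta = 0.1)
#' @export
cutoff_spec <- function(kind = c("constant", "power"), c = NULL,
                        alpha = NULL, beta = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    stopifnot(is.numeric(c), length(c) == 1L)
    if (c <= 0 || c >= 1)
      stop("constant cutoff must lie in (0, 1)", call. = FALSE)
    structure(list(kind = kind, c = c), class = "cutoff_spec")
  } else {
    stopifnot(is.numeric(alpha), length(alpha) == 1L,
              is.numeric(beta), length(beta) == 1L)
    if (alpha <= 0 || alpha > 1 || beta < 0)
      stop("need 0 < alpha <= 1 and beta >= 0", call. = FALSE)
    structure(list(kind = kind, alpha = alpha, beta = beta),
              class = "cutoff_spec")
  }
}

#' @export
print.cutoff_spec <- function(x, ...) {
  if (x$kind == "constant") cat(sprintf("cutoff c = %g\n", x$c))
  else cat(sprintf("cutoff %g * (n/N)^%g\n", x$alpha, x$beta))
  invisible(x)
}

#' Evaluate a decision cutoff at an interim sample size
#'
#' @param spec A [cutoff_spec()].
#' @param n Interim sample size, `0 < n <= n_max`.
#' @param n_max Maximum per-arm sample size.
#' @return The cutoff, a probability in (0, 1); an out-of-range result is a
#'   configuration error.
#' @export
cutoff_at <- function(spec, n, n_max) {
  stopifnot(inherits(spec, "cutoff_spec"), n > 0, n <= n_max)
  val <- if (spec$kind == "constant") spec$c
         else spec$alpha * (n / n_max)^spec$beta
  if (val <= 0 || val >= 1)
    stop("cutoff evaluates outside (0, 1)", call. = FALSE)
  val
}

new_rule <- function(type, prior, limit, unacceptable, cutoff, schedule,
                     comparator = NULL) {
  stopifnot(is_beta_params(prior),
            is.numeric(limit), length(limit) == 1L, limit > 0, limit < 1,
            inherits(cutoff, "cutoff_spec"),
            inherits(schedule, "monitoring_schedule"))
  if (!is.null(unacceptable)) {
    stopifnot(is.numeric(unacceptable), length(unacceptable) == 1L)
    ok <- if (type == "safety") unacceptable > limit else unacceptable < limit
    if (!ok)
      stop(sprintf("for a %s rule the unacceptable probability must be %s the limit",
                   type, if (type == "safety") "above" else "below"),
           call. = FALSE)
  }
  if (!is.null(comparator)) stopifnot(is_beta_params(comparator))
  structure(list(type = type, prior = prior, limit = limit,
                 unacceptable = unacceptable, cutoff = cutoff,
                 schedule = schedule, comparator = comparator),
            class = c(paste0(type, "_rule"), "srct_rule"))
}

#' Posterior safety stopping rule
#'
#' Stops accrual to an arm when the posterior probability that its toxicity
#' probability exceeds the acceptable limit is large:
#' `Pr(theta_Tox > limit | data) > cutoff` (fixed-limit variant), or, with a
#' `comparator` beta distribution playing the role of the limit,
#' `Pr(theta_Tox > theta_comparator | data) > cutoff`. The comparator is
#' never updated by trial data. The inequality is strict: a posterior
#' probability exactly equal to the cutoff does not stop.
#'
#' @param limit Largest acceptable toxicity probability (the fixed threshold
#'   theta-star).
#' @param schedule A [monitoring_schedule()].
#' @param cutoff A [cutoff_spec()]; default constant 0.90.
#' @param prior Beta prior on the monitored arm's toxicity probability;
#'   default `prior_from_mean(limit, 1)`, the non-informative ESS-1 prior
#'   centered at the limit.
#' @param unacceptable Optional unacceptably large toxicity probability
#'   (theta-double-star, `> limit`), used by [calibrate_cutoff()].
#' @param comparator Optional [beta_params()] random comparator with mean
#'   approximately equal to `limit` (e.g. `beta(200, 800)` for a limit of
#'   0.20).
#' @return An object of class `safety_rule`.
#' @examples
#' # the cell-therapy trial's rule: stop if Pr(theta > 0.30 | data) > 0.90,
#' # looks at 4, 8, 12 of 16
#' safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16))
#' @export
safety_rule <- function(limit, schedule, cutoff = cutoff_spec("constant", 0.90),
                        prior = prior_from_mean(limit, 1),
                        unacceptable = NULL, comparator = NULL) {
  new_rule("safety", prior, limit, unacceptable, cutoff, schedule, comparator)
}

#' Posterior futility stopping rule
#'
#' Stops accrual when the posterior probability that the arm's response
#' probability falls below the smallest acceptable value is large:
#' `Pr(theta_Res < limit | data) > cutoff`. Strict inequality.
#'
#' @param limit Smallest acceptable response probability.
#' @param schedule A [monitoring_schedule()].
#' @param cutoff A [cutoff_spec()]; default constant 0.90.
#' @param prior Beta prior on the monitored response probability; default
#'   `prior_from_mean(limit, 1)`.
#' @param unacceptable Optional unacceptably small response probability
#'   (`< limit`).
#' @return An object of class `futility_rule`.
#' @export
futility_rule <- function(limit, schedule,
                          cutoff = cutoff_spec("constant", 0.90),
                          prior = prior_from_mean(limit, 1),
                          unacceptable = NULL) {
  new_rule("futility", prior, limit, unacceptable, cutoff, schedule)
}

#' @export
print.srct_rule <- function(x, ...) {
  cat(sprintf("%s rule: Pr(theta %s %s | data) > cutoff\n",
              x$type, if (x$type == "safety") ">" else "<",
              if (is.null(x$comparator)) format(x$limit)
              else format(x$comparator)))
  cat("  prior:", format(x$prior), "\n")
  cat("  looks:", paste(x$schedule$looks, collapse = ", "),
      "of", x$schedule$n_max, "\n")
  print(x$cutoff)
  invisible(x)
}

# Posterior stopping criterion value for observed events/total.
rule_criterion <- function(rule, events, total) {
  post <- update_beta(rule$prior, binom_count(events, total))
  if (rule$type == "safety") {
    if (is.null(rule$comparator))
      tail_probability(post, rule$limit, "above")
    else
      improvement_probability(post, rule$comparator, 0)
  } else {
    tail_probability(post, rule$limit, "below")
  }
}

check_look <- function(rule, data) {
  if (!data$total %in% rule$schedule$looks)
    stop(sprintf("sample size %d is not a scheduled look (%s)",
                 data$total, paste(rule$schedule$looks, collapse = ", ")),
         call. = FALSE)
}

#' Evaluate a safety rule on interim data
#'
#' @param rule A [safety_rule()].
#' @param data A [binom_count()] of toxicities out of evaluated patients;
#'   `total` must be one of the scheduled looks.
#' @return `TRUE` if accrual should stop.
#' @examples
#' r <- safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16))
#' safety_stop(r, binom_count(3, 4))  # TRUE
#' safety_stop(r, binom_count(2, 4))  # FALSE
#' @export
safety_stop <- function(rule, data) {
  stopifnot(inherits(rule, "safety_rule"))
  data <- as_binom_count(data)
  check_look(rule, data)
  rule_criterion(rule, data$events, data$total) >
    cutoff_at(rule$cutoff, data$total, rule$schedule$n_max)
}

#' Evaluate a futility rule on interim data
#'
#' @param rule A [futility_rule()].
#' @param data A [binom_count()] of responses out of evaluated patients;
#'   `total` must be one of the scheduled looks.
#' @return `TRUE` if accrual should stop for futility.
#' @export
futility_stop <- function(rule, data) {
  stopifnot(inherits(rule, "futility_rule"))
  data <- as_binom_count(data)
  check_look(rule, data)
  rule_criterion(rule, data$events, data$total) >
    cutoff_at(rule$cutoff, data$total, rule$schedule$n_max)
}

#' Integer trigger boundaries equivalent to a posterior stopping rule
#'
#' The posterior criterion is monotone in the observed event count, so at
#' each look it is exactly equivalent to comparing the count against an
#' integer trigger: for a safety rule, stop iff events >= trigger (the
#' smallest count whose criterion strictly exceeds the cutoff); for a
#' futility rule, stop iff events <= trigger (the largest triggering
#' count). A look at which no count in `0..look_n` triggers is marked
#' unreachable (`NA`).
#'
#' @param rule A [safety_rule()] or [futility_rule()].
#' @return A data frame of class `boundary_table` with columns `look_n`,
#'   `trigger` (integer or `NA`), and `criterion` (the posterior criterion
#'   value at the trigger).
#' @examples
#' boundary_table(safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16)))
#' # triggers 3/4, 5/8, 6/12
#' @export
boundary_table <- function(rule) {
  stopifnot(inherits(rule, "srct_rule"))
  looks <- rule$schedule$looks
  n_max <- rule$schedule$n_max
  rows <- lapply(looks, function(n) {
    cut <- cutoff_at(rule$cutoff, n, n_max)
    crit <- vapply(0:n, function(x) rule_criterion(rule, x, n), numeric(1L))
    hit <- which(crit > cut)
    if (rule$type == "safety") {
      trig <- if (length(hit)) min(hit) - 1L else NA_integer_
    } else {
      trig <- if (length(hit)) max(hit) - 1L else NA_integer_
    }
    data.frame(look_n = n, trigger = trig,
               criterion = if (is.na(trig)) NA_real_ else crit[trig + 1L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "type") <- rule$type
  attr(out, "n_max") <- n_max
  class(out) <- c("boundary_table", "data.frame")
  out
}

#' @export
print.boundary_table <- function(x, ...) {
  type <- attr(x, "type")
  cat(sprintf("%s boundary (stop if events %s trigger):\n", type,
              if (type == "safety") ">=" else "<="))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  cat(boundary_text(x), "\n")
  invisible(x)
}

#' Protocol-ready text for a boundary table
#'
#' @param x A [boundary_table()].
#' @return A single string, e.g. `"stop if >= 3/4, 5/8, 6/12"`.
#' @export
boundary_text <- function(x) {
  stopifnot(inherits(x, "boundary_table"))
  reach <- !is.na(x$trigger)
  cmp <- if (attr(x, "type") == "safety") ">=" else "<="
  if (!any(reach)) return("rule cannot trigger at any look")
  paste0("stop if ", cmp, " ",
         paste(sprintf("%d/%d", x$trigger[reach], x$look_n[reach]),
               collapse = ", "))
}
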