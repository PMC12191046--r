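# Sample-size exploration for candidate (N, K, n) designs, and the small
# CSV interfaces shared with the command-line entry point.

#' Explore candidate per-arm sample sizes with hypothetical future data
#'
#' The heuristic sample-size approach for a small randomized trial: rather
#' than a power calculation, examine what posterior precision each feasible
#' per-arm sample size `n` would deliver, by computing the credible interval
#' for `theta_E - theta_S` and the improvement probabilities
#' `Pr(theta_E > theta_S + delta | data)` that one or two hypothetical
#' future datasets would produce.
#'
#' Hypothetical data are given either as explicit per-candidate counts
#' (`events_e`, `events_s`) or as a single fraction pair (`frac`) scaled to
#' each candidate `n`; a scaling that does not give whole event counts is an
#' error rather than being rounded, so rows stay exactly reproducible.
#'
#' @param n_per_arm Integer vector of candidate per-arm sample sizes.
#' @param k_arms Number of arms (used only to report `N = K * n`).
#' @param events_e,events_s Hypothetical event counts for the experimental
#'   and reference arm, one per candidate (recycled if length 1).
#' @param frac Alternative to explicit counts: `c(e, s)` fractions scaled
#'   to each `n`.
#' @param deltas Improvement margins; default 0.15.
#' @param level Credibility level; default 0.95.
#' @param priorE,priorS Beta priors; default `beta(0.5, 0.5)`.
#' @return A data frame with columns `n_per_arm`, `n_total`, `data` (the
#'   "e/n vs s/n" label), `lower`, `upper`, `width`, and one
#'   `pr_improve_<delta>` column per margin.
#' @examples
#' explore_designs(c(10, 15, 20), k_arms = 3,
#'                 events_e = c(6, 10, 14), events_s = c(3, 5, 7))
#' @export
explore_designs <- function(n_per_arm, k_arms = 2L,
                            events_e = NULL, events_s = NULL, frac = NULL,
                            deltas = 0.15, level = 0.95,
                            priorE = beta_params(0.5, 0.5),
                            priorS = beta_params(0.5, 0.5)) {
  stopifnot(is.numeric(n_per_arm), length(n_per_arm) >= 1L,
            all(n_per_arm == round(n_per_arm)), all(n_per_arm > 0),
            is.numeric(deltas), length(deltas) >= 1L)
  if (!is.null(frac)) {
    stopifnot(length(frac) == 2L, all(frac >= 0), all(frac <= 1))
    events_e <- frac[1L] * n_per_arm
    events_s <- frac[2L] * n_per_arm
    bad <- abs(events_e - round(events_e)) > 1e-9 |
           abs(events_s - round(events_s)) > 1e-9
    if (any(bad))
      stop(sprintf("fractions are not representable at n = %s",
                   paste(n_per_arm[bad], collapse = ", ")), call. = FALSE)
    events_e <- round(events_e); events_s <- round(events_s)
  }
  if (is.null(events_e) || is.null(events_s))
    stop("supply events_e/events_s or frac", call. = FALSE)
  events_e <- rep_len(events_e, length(n_per_arm))
  events_s <- rep_len(events_s, length(n_per_arm))
  rows <- lapply(seq_along(n_per_arm), function(i) {
    n <- n_per_arm[i]
    postE <- update_beta(priorE, binom_count(events_e[i], n))
    postS <- update_beta(priorS, binom_count(events_s[i], n))
    ci <- difference_interval(postE, postS, level)
    probs <- vapply(deltas, function(d)
      improvement_probability(postE, postS, d), numeric(1L))
    out <- data.frame(
      n_per_arm = n, n_total = as.integer(k_arms * n),
      data = sprintf("%d/%d vs %d/%d", events_e[i], n, events_s[i], n),
      lower = ci$lower, upper = ci$upper, width = ci$upper - ci$lower,
      stringsAsFactors = FALSE)
    out[paste0("pr_improve_", format(deltas, trim = TRUE))] <- as.list(probs)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read per-arm binomial counts from CSV
#'
#' Expected columns: `arm`, `events`, `total`, and optionally `prior_mean`
#' and `prior_ess` (defaults 0.5 and 1: the non-informative beta(0.5, 0.5)).
#'
#' @param path CSV file path.
#' @return List of [arm_posterior()] objects (posteriors after the conjugate
#'   update).
#' @export
read_arm_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm", "events", "total")
  if (!all(need %in% names(df)) || nrow(df) == 0L)
    stop("counts CSV needs non-empty columns arm, events, total",
         call. = FALSE)
  if (!"prior_mean" %in% names(df)) df$prior_mean <- 0.5
  if (!"prior_ess" %in% names(df)) df$prior_ess <- 1
  lapply(seq_len(nrow(df)), function(i) {
    prior <- prior_from_mean(df$prior_mean[i], df$prior_ess[i])
    arm_posterior(df$arm[i],
                  update_beta(prior, binom_count(df$events[i], df$total[i])))
  })
}

#' Write a data frame to CSV at full precision
#'
#' Numeric columns are written with full double precision (the
#' human-readable report files round to 2 decimals separately).
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
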