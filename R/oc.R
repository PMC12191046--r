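# Operating characteristics: exact single-arm stopping probabilities by
# cohort-path dynamic programming, full-trial Monte Carlo with enrichment,
# cutoff calibration, and the synthetic patient-level trial generator.

#' Exact single-arm operating characteristics
#'
#' Computes the early-stopping probability and the distribution of the
#' attained per-arm sample size for a boundary table applied to cohorts of
#' independent binary outcomes with true event probability `true_p`. The
#' computation is an exact dynamic program over (look, cumulative event
#' count) with binomial cohort increments — no simulation error.
#'
#' @param boundary A [boundary_table()].
#' @param true_p True event probability of the monitored outcome.
#' @param n_max Per-arm maximum sample size; defaults to the boundary's.
#' @param cohort_sizes Cohort sizes summing to `n_max`; the looks must align
#'   with cumulative cohort sizes. Default: the gaps between successive
#'   looks and `n_max`.
#' @return An object of class `arm_oc`: a list with `p_stop`, the total
#'   early-stopping probability; `stop_distribution`, named probabilities of
#'   the attained sample size (mass at `n_max` includes trials that never
#'   stop); `quartiles`, from [sample_size_quartiles()]; and `true_p`.
#' @examples
#' b <- boundary_table(safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16)))
#' exact_arm_oc(b, true_p = 0.30)
#' @export
exact_arm_oc <- function(boundary, true_p, n_max = attr(boundary, "n_max"),
                         cohort_sizes = NULL) {
  stopifnot(inherits(boundary, "boundary_table"),
            is.numeric(true_p), length(true_p) == 1L,
            true_p >= 0, true_p <= 1)
  looks <- boundary$look_n
  if (is.null(cohort_sizes)) cohort_sizes <- diff(c(0L, looks, n_max))
  cohort_sizes <- cohort_sizes[cohort_sizes > 0L]
  cum <- cumsum(cohort_sizes)
  if (cum[length(cum)] != n_max)
    stop("cohort sizes must sum to n_max", call. = FALSE)
  if (!all(looks %in% cum))
    stop("looks must align with cumulative cohort sizes", call. = FALSE)
  type <- attr(boundary, "type")

  state <- 1            # P(continuing with cumulative count = 0..n_seen)
  n_seen <- 0L
  stop_mass <- stats::setNames(numeric(length(looks)), looks)
  for (m in cohort_sizes) {
    inc <- stats::dbinom(0:m, m, true_p)
    new <- numeric(n_seen + m + 1L)
    for (x in seq_along(state)) {
      if (state[x] > 0)
        new[x:(x + m)] <- new[x:(x + m)] + state[x] * inc
    }
    state <- new
    n_seen <- n_seen + m
    li <- match(n_seen, looks)
    if (!is.na(li)) {
      trig <- boundary$trigger[li]
      if (!is.na(trig)) {
        counts <- 0:n_seen
        hit <- if (type == "safety") counts >= trig else counts <= trig
        stop_mass[li] <- sum(state[hit])
        state[hit] <- 0
      }
    }
  }
  dist <- c(stop_mass, stats::setNames(sum(state), n_max))
  # a look scheduled at n_max itself contributes to p_stop but not to a
  # smaller attained sample size
  if (as.character(n_max) %in% names(stop_mass)) {
    dist <- stop_mass
    dist[as.character(n_max)] <-
      dist[as.character(n_max)] + sum(state)
  }
  oc <- structure(list(p_stop = sum(stop_mass),
                       stop_distribution = dist,
                       quartiles = NULL,
                       true_p = true_p,
                       n_max = n_max),
                  class = "arm_oc")
  oc$quartiles <- sample_size_quartiles(oc)
  oc
}

#' @export
print.arm_oc <- function(x, digits = 3, ...) {
  cat(sprintf("Pr(stop early) = %.*f at true p = %g\n",
              digits, x$p_stop, x$true_p))
  cat("attained sample size distribution:\n")
  print(round(x$stop_distribution, digits))
  cat("quartiles:", paste(x$quartiles, collapse = ", "), "\n")
  invisible(x)
}

#' Quartiles of the attained per-arm sample size
#'
#' The q-th quartile is the smallest attainable sample size whose cumulative
#' probability reaches q, for q = 0.25, 0.50, 0.75.
#'
#' @param oc An [exact_arm_oc()] result, or any list with a
#'   `stop_distribution` of named probabilities.
#' @return Integer vector `c(q25, q50, q75)`.
#' @export
sample_size_quartiles <- function(oc) {
  dist <- oc$stop_distribution
  stopifnot(abs(sum(dist) - 1) < 1e-9)
  sizes <- as.integer(names(dist))
  o <- order(sizes)
  sizes <- sizes[o]
  cum <- cumsum(dist[o])
  vapply(c(0.25, 0.50, 0.75),
         function(q) sizes[which(cum >= q - 1e-12)[1L]],
         integer(1L))
}

#' Calibrate a decision cutoff against exact operating characteristics
#'
#' Scans a grid of cutoff specifications for the rule and returns the one
#' that, among members keeping the early-stopping probability at the
#' acceptable limit (`true_p = limit`) at or below
#' `p_stop_max_at_limit`, maximizes the stopping probability at the
#' unacceptable value (`true_p = unacceptable`). Ties are broken toward the
#' larger cutoff at the first look (fewer stops at the limit). If no grid
#' member satisfies the constraint, the member closest to feasibility is
#' returned with `feasible = FALSE`.
#'
#' @param rule_template A [safety_rule()] or [futility_rule()] with
#'   `unacceptable` set; its cutoff is replaced by each grid member.
#' @param grid List of [cutoff_spec()] objects.
#' @param p_stop_max_at_limit Largest tolerated stopping probability when
#'   the true probability equals the rule's limit.
#' @param p_stop_min_at_unacceptable Optional desired minimum stopping
#'   probability at the unacceptable value; reported via the `meets_power`
#'   flag.
#' @param cohort_sizes Passed to [exact_arm_oc()].
#' @return List with `cutoff` (the selected [cutoff_spec()]), `boundary`,
#'   `oc_at_limit` and `oc_at_unacceptable` (exact [exact_arm_oc()]
#'   results), `feasible`, `meets_power`, and the full `grid_summary` data
#'   frame.
#' @export
calibrate_cutoff <- function(rule_template, grid,
                             p_stop_max_at_limit,
                             p_stop_min_at_unacceptable = NULL,
                             cohort_sizes = NULL) {
  stopifnot(inherits(rule_template, "srct_rule"), is.list(grid),
            length(grid) >= 1L,
            all(vapply(grid, inherits, logical(1L), "cutoff_spec")))
  if (is.null(rule_template$unacceptable))
    stop("rule_template must specify the unacceptable probability",
         call. = FALSE)
  eval_one <- function(spec) {
    r <- rule_template
    r$cutoff <- spec
    b <- boundary_table(r)
    list(spec = spec, boundary = b,
         at_limit = exact_arm_oc(b, rule_template$limit,
                                 cohort_sizes = cohort_sizes),
         at_unacc = exact_arm_oc(b, rule_template$unacceptable,
                                 cohort_sizes = cohort_sizes))
  }
  evals <- lapply(grid, eval_one)
  p_lim <- vapply(evals, function(e) e$at_limit$p_stop, numeric(1L))
  p_unacc <- vapply(evals, function(e) e$at_unacc$p_stop, numeric(1L))
  first_cut <- vapply(evals, function(e)
    cutoff_at(e$spec, rule_template$schedule$looks[1L],
              rule_template$schedule$n_max), numeric(1L))
  feasible_set <- which(p_lim <= p_stop_max_at_limit)
  if (length(feasible_set)) {
    best <- feasible_set[order(-p_unacc[feasible_set],
                               -first_cut[feasible_set])][1L]
    feasible <- TRUE
  } else {
    best <- which.min(p_lim - p_stop_max_at_limit)
    feasible <- FALSE
    warning("no grid member satisfies the stopping-probability constraint; ",
            "returning the closest", call. = FALSE)
  }
  sel <- evals[[best]]
  meets_power <- if (is.null(p_stop_min_at_unacceptable)) NA
                 else p_unacc[best] >= p_stop_min_at_unacceptable
  list(cutoff = sel$spec, boundary = sel$boundary,
       oc_at_limit = sel$at_limit, oc_at_unacceptable = sel$at_unacc,
       feasible = feasible, meets_power = meets_power,
       grid_summary = data.frame(
         member = seq_along(grid),
         p_stop_at_limit = p_lim,
         p_stop_at_unacceptable = p_unacc))
}

# ---- multi-arm trial design & simulation -----------------------------------

#' Arm scenario: assumed true event probabilities
#'
#' @param label Arm label.
#' @param true_p_tox,true_p_res True toxicity and response probabilities.
#' @return An object of class `arm_scenario`.
#' @export
arm_scenario <- function(label, true_p_tox, true_p_res) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(true_p_tox), true_p_tox >= 0, true_p_tox <= 1,
            is.numeric(true_p_res), true_p_res >= 0, true_p_res <= 1)
  structure(list(label = label, true_p_tox = true_p_tox,
                 true_p_res = true_p_res), class = "arm_scenario")
}

#' Multi-arm trial design
#'
#' A balanced design for a small randomized comparative trial: `K` arms
#' (reference first), `n_per_arm` patients each (total `N = K * n_per_arm`),
#' permuted-block randomization, per-arm posterior monitoring rules, and
#' enrichment — on an arm's early termination its unused patient slots are
#' re-randomized in balanced blocks over the surviving arms so the total
#' sample size is preserved.
#'
#' @param arms Character vector of arm labels, the reference (control) arm
#'   first.
#' @param n_per_arm Maximum per-arm sample size.
#' @param block_size Randomization block size; must be divisible by the
#'   number of arms.
#' @param safety_rules Named list of [safety_rule()] objects, one per
#'   monitored arm (typically all non-reference arms); may be `NULL`.
#' @param futility_rules Named list of [futility_rule()] objects, or `NULL`.
#' @param enrichment Re-randomize a terminated arm's remaining slots over
#'   the surviving arms (default `TRUE`). With `FALSE` the terminated arm's
#'   remaining slots are simply not enrolled.
#' @param response_prior Beta prior used for the final posterior-mean
#'   response comparison that selects the best experimental arm; default
#'   `beta(0.5, 0.5)`.
#' @param selection_delta Optional margin: the selected arm's posterior mean
#'   response must exceed the reference's by more than this; default `NULL`
#'   (no reference comparison, the surviving experimental arm with the
#'   larger posterior mean is selected; ties go to the earlier-listed arm).
#' @return An object of class `trial_design`.
#' @examples
#' sched <- monitoring_schedule(c(4, 8, 12), 16)
#' rules <- list(E1 = safety_rule(0.30, sched), E2 = safety_rule(0.30, sched))
#' trial_design(c("S", "E1", "E2"), 16, 6, safety_rules = rules)
#' @export
trial_design <- function(arms, n_per_arm, block_size,
                         safety_rules = NULL, futility_rules = NULL,
                         enrichment = TRUE,
                         response_prior = beta_params(0.5, 0.5),
                         selection_delta = NULL) {
  stopifnot(is.character(arms), length(arms) >= 2L, !anyDuplicated(arms),
            is.numeric(n_per_arm), n_per_arm == round(n_per_arm),
            n_per_arm > 0,
            is.numeric(block_size), block_size == round(block_size),
            block_size > 0, is_beta_params(response_prior))
  if (block_size %% length(arms) != 0L)
    stop("block_size must be divisible by the number of arms", call. = FALSE)
  if ((length(arms) * n_per_arm) %% block_size != 0L)
    stop("total sample size must be a whole number of blocks", call. = FALSE)
  chk_rules <- function(rules, cls) {
    if (is.null(rules)) return(invisible())
    stopifnot(is.list(rules), !is.null(names(rules)),
              all(names(rules) %in% arms),
              all(vapply(rules, inherits, logical(1L), cls)))
  }
  chk_rules(safety_rules, "safety_rule")
  chk_rules(futility_rules, "futility_rule")
  structure(list(arms = arms, n_per_arm = as.integer(n_per_arm),
                 block_size = as.integer(block_size),
                 safety_rules = safety_rules,
                 futility_rules = futility_rules,
                 enrichment = isTRUE(enrichment),
                 response_prior = response_prior,
                 selection_delta = selection_delta),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("trial design: %d arms (%s), n = %d per arm, N = %d, blocks of %d\n",
              length(x$arms), paste(x$arms, collapse = ", "),
              x$n_per_arm, length(x$arms) * x$n_per_arm, x$block_size))
  if (!is.null(x$safety_rules))
    cat("  safety-monitored arms:",
        paste(names(x$safety_rules), collapse = ", "), "\n")
  if (!is.null(x$futility_rules))
    cat("  futility-monitored arms:",
        paste(names(x$futility_rules), collapse = ", "), "\n")
  cat("  enrichment:", x$enrichment, "\n")
  invisible(x)
}

scenario_table <- function(scenario, arms) {
  stopifnot(is.list(scenario),
            all(vapply(scenario, inherits, logical(1L), "arm_scenario")))
  labs <- vapply(scenario, `[[`, character(1L), "label")
  if (!setequal(labs, arms) || anyDuplicated(labs))
    stop("scenario must cover every design arm exactly once", call. = FALSE)
  idx <- match(arms, labs)
  data.frame(label = arms,
             p_tox = vapply(scenario, `[[`, numeric(1L), "true_p_tox")[idx],
             p_res = vapply(scenario, `[[`, numeric(1L), "true_p_res")[idx],
             stringsAsFactors = FALSE)
}

# Precompute each monitored arm's integer boundaries once per design; the
# patient loop then only compares counts against triggers.
design_boundaries <- function(design) {
  boundaries <- list()
  for (a in names(design$safety_rules))
    boundaries[[a]]$safety <- list(
      table = boundary_table(design$safety_rules[[a]]),
      looks = design$safety_rules[[a]]$schedule$looks)
  for (a in names(design$futility_rules))
    boundaries[[a]]$futility <- list(
      table = boundary_table(design$futility_rules[[a]]),
      looks = design$futility_rules[[a]]$schedule$looks)
  boundaries
}

# Run one trial; returns patient table and per-arm outcome summary.
# Assumes the RNG is already seeded.
run_one_trial <- function(design, sc, boundaries = design_boundaries(design)) {
  arms <- design$arms
  n_arms <- length(arms)
  N <- n_arms * design$n_per_arm
  per_block <- design$block_size %/% n_arms
  assign_seq <- as.vector(replicate(N %/% design$block_size,
    sample(rep(arms, per_block))))
  block_of <- rep(seq_len(N %/% design$block_size), each = design$block_size)

  # outcome streams: the j-th patient ever assigned to an arm gets the j-th
  # draw of that arm's stream (an arm can exceed n_per_arm under enrichment)
  tox_draws <- lapply(seq_len(n_arms), function(k)
    stats::rbinom(N, 1L, sc$p_tox[k]))
  res_draws <- lapply(seq_len(n_arms), function(k)
    stats::rbinom(N, 1L, sc$p_res[k]))
  names(tox_draws) <- names(res_draws) <- arms

  n_enr <- stats::setNames(integer(n_arms), arms)
  n_tox <- stats::setNames(integer(n_arms), arms)
  n_res <- stats::setNames(integer(n_arms), arms)
  dropped <- stats::setNames(logical(n_arms), arms)
  stop_at <- stats::setNames(rep(NA_integer_, n_arms), arms)
  stop_reason <- stats::setNames(rep(NA_character_, n_arms), arms)
  pat_arm <- character(N); pat_tox <- integer(N); pat_res <- integer(N)
  pos <- 1L
  terminated <- FALSE

  crosses <- function(tab, x, n) {
    i <- match(n, tab$look_n)
    trig <- tab$trigger[i]
    if (is.na(trig)) return(FALSE)
    if (attr(tab, "type") == "safety") x >= trig else x <= trig
  }

  while (pos <= length(assign_seq) && !terminated) {
    arm <- assign_seq[pos]
    tox <- tox_draws[[arm]][n_enr[arm] + 1L]
    res <- res_draws[[arm]][n_enr[arm] + 1L]
    n_enr[arm] <- n_enr[arm] + 1L
    n_tox[arm] <- n_tox[arm] + tox
    n_res[arm] <- n_res[arm] + res
    pat_arm[pos] <- arm; pat_tox[pos] <- tox; pat_res[pos] <- res
    b <- boundaries[[arm]]
    stop_now <- FALSE
    if (!is.null(b$safety) && n_enr[arm] %in% b$safety$looks &&
        crosses(b$safety$table, n_tox[arm], n_enr[arm])) {
      stop_now <- TRUE
      stop_reason[arm] <- "safety"
    } else if (!is.null(b$futility) && n_enr[arm] %in% b$futility$looks &&
               crosses(b$futility$table, n_res[arm], n_enr[arm])) {
      stop_now <- TRUE
      stop_reason[arm] <- "futility"
    }
    if (stop_now) {
      dropped[arm] <- TRUE
      stop_at[arm] <- n_enr[arm]
      survivors <- arms[!dropped]
      exp_survivors <- setdiff(survivors, arms[1L])
      if (length(exp_survivors) == 0L) {
        terminated <- TRUE
      } else if (pos < length(assign_seq)) {
        if (design$enrichment) {
          tail_len <- length(assign_seq) - pos
          new_bs <- max(length(survivors),
                        (design$block_size %/% n_arms) * length(survivors))
          n_full <- tail_len %/% new_bs
          rem <- tail_len - n_full * new_bs
          new_tail <- character(0)
          if (n_full > 0)
            new_tail <- as.vector(replicate(n_full,
              sample(rep(survivors, new_bs %/% length(survivors)))))
          if (rem > 0)
            new_tail <- c(new_tail,
              sample(rep(survivors, new_bs %/% length(survivors)))[seq_len(rem)])
          assign_seq <- c(assign_seq[seq_len(pos)], new_tail)
        } else {
          keep <- assign_seq[(pos + 1L):length(assign_seq)] != arm
          assign_seq <- c(assign_seq[seq_len(pos)],
                          assign_seq[(pos + 1L):length(assign_seq)][keep])
        }
      }
    }
    pos <- pos + 1L
  }

  # final selection among surviving experimental arms
  exp_arms <- arms[-1L]
  survivors <- exp_arms[!dropped[exp_arms]]
  selected <- "none"
  if (length(survivors)) {
    pm <- vapply(survivors, function(a)
      posterior_mean(update_beta(design$response_prior,
                                 binom_count(n_res[a], n_enr[a]))),
      numeric(1L))
    best <- survivors[which.max(pm)]   # which.max ties -> earliest listed
    if (!is.null(design$selection_delta)) {
      ref <- arms[1L]
      pm_ref <- posterior_mean(update_beta(design$response_prior,
                                           binom_count(n_res[ref],
                                                       n_enr[ref])))
      if (max(pm) > pm_ref + design$selection_delta) selected <- best
    } else {
      selected <- best
    }
  }

  n_pat <- pos - 1L
  patients <- data.frame(id = seq_len(n_pat),
                         block = block_of[seq_len(n_pat)],
                         arm = pat_arm[seq_len(n_pat)],
                         tox = pat_tox[seq_len(n_pat)],
                         res = pat_res[seq_len(n_pat)],
                         stringsAsFactors = FALSE)
  list(patients = patients, n_enrolled = n_enr, n_tox = n_tox,
       n_res = n_res, dropped = dropped, stop_at = stop_at,
       stop_reason = stop_reason, selected = selected,
       total_enrolled = sum(n_enr))
}

#' Simulate a multi-arm trial design
#'
#' Seeded Monte Carlo of the full trial: patients accrue through the
#' permuted-block randomization, each monitored arm's rules are evaluated
#' whenever its evaluated count reaches a scheduled look (outcomes are
#' treated as immediately evaluable), a stopped arm's remaining slots are
#' re-randomized in balanced blocks over the surviving arms (enrichment),
#' the trial terminates if no experimental arm survives, and at the end the
#' surviving experimental arm with the larger posterior mean response
#' probability is selected. Per-simulation RNG streams are derived from
#' `seed` by counter, so results are reproducible and independent of
#' `n_sims`.
#'
#' @param design A [trial_design()].
#' @param scenario List of [arm_scenario()] objects covering every arm.
#' @param n_sims Number of simulated trials.
#' @param seed Integer root seed.
#' @return An object of class `trial_oc`: per-arm stopping probabilities,
#'   mean enrolled counts, selection probabilities (including `"none"`),
#'   and the distribution of the total enrolled sample size.
#' @examples
#' sched <- monitoring_schedule(c(4, 8, 12), 16)
#' des <- trial_design(c("S", "E1", "E2"), 16, 6,
#'   safety_rules = list(E1 = safety_rule(0.30, sched),
#'                       E2 = safety_rule(0.30, sched)))
#' sc <- list(arm_scenario("S", 0.30, 0.25),
#'            arm_scenario("E1", 0.30, 0.50),
#'            arm_scenario("E2", 0.30, 0.50))
#' simulate_trial(des, sc, n_sims = 200, seed = 7)
#' @export
simulate_trial <- function(design, scenario, n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            is.numeric(n_sims), n_sims >= 1L)
  sc <- scenario_table(scenario, design$arms)
  arms <- design$arms
  boundaries <- design_boundaries(design)
  stop_count <- stats::setNames(numeric(length(arms)), arms)
  sel_count <- stats::setNames(numeric(length(arms) + 1L),
                               c(arms, "none"))
  enrolled_sum <- stats::setNames(numeric(length(arms)), arms)
  totals <- integer(n_sims)
  # per-simulation streams indexed by counter: the i-th sub-seed is the same
  # whatever n_sims is, and sub-streams are decorrelated by the draw itself
  sub_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, n_sims, replace = TRUE))
  for (i in seq_len(n_sims)) {
    r <- with_seed(sub_seeds[i], run_one_trial(design, sc, boundaries))
    stop_count <- stop_count + r$dropped
    sel_count[r$selected] <- sel_count[r$selected] + 1
    enrolled_sum <- enrolled_sum + r$n_enrolled
    totals[i] <- r$total_enrolled
  }
  tot_tab <- table(totals) / n_sims
  structure(list(n_sims = as.integer(n_sims), seed = as.integer(seed),
                 p_stop = stop_count / n_sims,
                 selection = sel_count / n_sims,
                 mean_enrolled = enrolled_sum / n_sims,
                 total_n_distribution = tot_tab,
                 scenario = sc),
            class = "trial_oc")
}

#' @export
print.trial_oc <- function(x, digits = 3, ...) {
  cat(sprintf("trial operating characteristics (%d simulations, seed %d)\n",
              x$n_sims, x$seed))
  cat("per-arm Pr(stop early):\n"); print(round(x$p_stop, digits))
  cat("selection probabilities:\n"); print(round(x$selection, digits))
  cat("mean enrolled per arm:\n"); print(round(x$mean_enrolled, digits))
  invisible(x)
}

#' Generate a synthetic patient-level trial dataset
#'
#' Runs one seeded trial under the design and scenario and returns the
#' patient-level table — the package's fixture generator. The table is
#' truncated at any triggered stop, exactly as a real trial's dataset
#' would be.
#'
#' @inheritParams simulate_trial
#' @param seed Integer seed; identical seeds give byte-identical tables.
#' @return A data frame with one row per enrolled patient: `id`, `block`,
#'   `arm`, `tox`, `res`.
#' @export
generate_trial_dataset <- function(design, scenario, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  sc <- scenario_table(scenario, design$arms)
  with_seed(seed, run_one_trial(design, sc))$patients
}
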