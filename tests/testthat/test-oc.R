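test_that("exact stopping probabilities match hand enumeration for the comparator rule", {
  bt <- boundary_table(comparator_rule())
  # oracle: P(X1 >= 4) + sum_{x1 <= 3} P(x1) P(X2 >= 6 - x1), X ~ Bin(8, p)
  enum <- function(p) {
    p1 <- sum(dbinom(4:8, 8, p))
    p2 <- sum(vapply(0:3, function(x1)
      dbinom(x1, 8, p) * sum(dbinom(max(6 - x1, 0):8, 8, p)), numeric(1)))
    p1 + p2
  }
  oc20 <- exact_arm_oc(bt, 0.20)
  expect_equal(oc20$p_stop, enum(0.20), tolerance = 1e-12)
  expect_lt(abs(oc20$p_stop - 0.106317), 1e-5)
  oc40 <- exact_arm_oc(bt, 0.40)
  expect_equal(oc40$p_stop, enum(0.40), tolerance = 1e-12)
  expect_lt(abs(oc40$p_stop - 0.697945), 1e-5)
  # no events possible, triggers >= 1: the rule can never fire
  expect_equal(exact_arm_oc(bt, 0)$p_stop, 0)
})

test_that("the dynamic program matches exhaustive 2^n path enumeration", {
  r <- safety_rule(0.30, monitoring_schedule(c(3, 6, 9), 12))
  bt <- boundary_table(r)
  for (p in c(0.15, 0.4, 0.62)) {
    oracle <- brute_force_oc(bt, p, 12)
    oc <- exact_arm_oc(bt, p)
    expect_equal(oc$stop_distribution, oracle, tolerance = 1e-12)
  }
  fut <- futility_rule(0.5, monitoring_schedule(c(4, 8), 10))
  btf <- boundary_table(fut)
  oracle <- brute_force_oc(btf, 0.3, 10)
  expect_equal(exact_arm_oc(btf, 0.3)$stop_distribution, oracle,
               tolerance = 1e-12)
})

test_that("cell-trial OCs: stopping probabilities and exact sample-size quartiles", {
  bt <- boundary_table(cell_trial_rule())
  res <- lapply(c(0.30, 0.40, 0.50, 0.60), function(p) exact_arm_oc(bt, p))
  p_stop <- vapply(res, `[[`, numeric(1), "p_stop")
  expect_equal(p_stop, c(0.167, 0.394, 0.658, 0.864), tolerance = 1e-3)
  # quartiles of the exact attained-sample-size distribution
  expect_equal(res[[1]]$quartiles, c(16L, 16L, 16L))
  expect_equal(res[[3]]$quartiles, c(4L, 12L, 16L))
  # at p = 0.40 the cumulative mass at n = 8 is 0.2499789, a knife-edge
  # below 0.25, so the exact first quartile is 12
  cum8 <- sum(res[[2]]$stop_distribution[c("4", "8")])
  expect_lt(cum8, 0.25)
  expect_gt(cum8, 0.2499)
  expect_equal(res[[2]]$quartiles, c(12L, 16L, 16L))
  # at p = 0.60, P(N <= 12) = p_stop = 0.864 >= 0.75, so q75 is 12
  expect_equal(res[[4]]$quartiles, c(4L, 8L, 12L))

  # degenerate: no stopping mass puts all quartiles at n_max
  oc0 <- exact_arm_oc(bt, 0)
  expect_equal(oc0$quartiles, c(16L, 16L, 16L))
})

test_that("stopping probability is non-decreasing in the true toxicity probability", {
  bt <- boundary_table(cell_trial_rule())
  ps <- vapply(seq(0.05, 0.95, by = 0.05),
               function(p) exact_arm_oc(bt, p)$p_stop, numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("cutoff calibration selects the reference 0.90 rule from a grid", {
  grid <- lapply(c(0.80, 0.85, 0.90, 0.95),
                 function(c) cutoff_spec("constant", c = c))
  res <- calibrate_cutoff(comparator_rule(), grid,
                          p_stop_max_at_limit = 0.11,
                          p_stop_min_at_unacceptable = 0.65)
  expect_true(res$feasible)
  expect_true(res$meets_power)
  # feasible members are c = 0.90 and 0.95; 0.90 stops more often at the
  # unacceptable toxicity rate
  expect_equal(res$cutoff$c, 0.90)
  expect_equal(res$oc_at_limit$p_stop, 0.1063, tolerance = 1e-3)
  expect_equal(res$oc_at_unacceptable$p_stop, 0.698, tolerance = 1e-3)

  one <- calibrate_cutoff(comparator_rule(), grid[3],
                          p_stop_max_at_limit = 0.11)
  expect_equal(one$cutoff$c, 0.90)

  expect_warning(
    infeasible <- calibrate_cutoff(comparator_rule(), grid,
                                   p_stop_max_at_limit = 0),
    "no grid member")
  expect_false(infeasible$feasible)
})

cell_design <- function() {
  sched <- monitoring_schedule(c(4, 8, 12), 16)
  trial_design(c("S", "E1", "E2"), 16, 6,
               safety_rules = list(E1 = safety_rule(0.30, sched),
                                   E2 = safety_rule(0.30, sched)))
}

cell_scenario <- function(p_tox) {
  list(arm_scenario("S", p_tox, 0.25),
       arm_scenario("E1", p_tox, 0.50),
       arm_scenario("E2", p_tox, 0.50))
}

test_that("trial simulation is seed-reproducible and respects disabled rules", {
  des <- cell_design()
  sc <- cell_scenario(0.3)
  a <- simulate_trial(des, sc, n_sims = 50, seed = 5)
  b <- simulate_trial(des, sc, n_sims = 50, seed = 5)
  expect_identical(a$p_stop, b$p_stop)
  expect_identical(a$selection, b$selection)

  no_rules <- trial_design(c("S", "E1", "E2"), 16, 6)
  oc <- simulate_trial(no_rules, sc, n_sims = 30, seed = 2)
  expect_equal(unname(oc$p_stop), c(0, 0, 0))
  expect_true(all(as.integer(names(oc$total_n_distribution)) == 48L))
  expect_equal(unname(oc$mean_enrolled), c(16, 16, 16))
})

test_that("simulated per-arm stopping matches the exact computation", {
  bt <- boundary_table(cell_trial_rule())
  exact <- exact_arm_oc(bt, 0.5)$p_stop
  oc <- simulate_trial(cell_design(), cell_scenario(0.5),
                       n_sims = 3000, seed = 17)
  se <- sqrt(exact * (1 - exact) / 3000)
  expect_lt(abs(oc$p_stop[["E1"]] - exact), 3 * se)
  expect_lt(abs(oc$p_stop[["E2"]] - exact), 3 * se)
})

test_that("enrichment preserves the total sample size while any arm survives", {
  des <- cell_design()
  sc <- cell_scenario(0.55)   # frequent stops exercise the replanning
  totals <- integer(0)
  selections <- character(0)
  for (s in 1:120) {
    set.seed(s)
    r <- srctdesign:::run_one_trial(des,
                                    srctdesign:::scenario_table(sc, des$arms))
    totals <- c(totals, r$total_enrolled)
    both_dropped <- all(r$dropped[c("E1", "E2")])
    expect_lte(r$total_enrolled, 48L)
    if (!both_dropped) expect_equal(r$total_enrolled, 48L)
    if (both_dropped) expect_identical(r$selected, "none")
    selections <- c(selections, r$selected)
  }
  expect_true(any(selections != "none"))
})

test_that("synthetic patient tables are reproducible, balanced, and correctly rated", {
  des <- cell_design()
  sc <- cell_scenario(0.2)
  d1 <- generate_trial_dataset(des, sc, seed = 5)
  d2 <- generate_trial_dataset(des, sc, seed = 5)
  expect_identical(d1, d2)
  d3 <- generate_trial_dataset(des, sc, seed = 6)
  expect_false(identical(d1, d3))

  # with no stopping rules, per-arm counts are balanced at block boundaries
  free <- trial_design(c("S", "E1", "E2"), 16, 6)
  d <- generate_trial_dataset(free, sc, seed = 9)
  expect_equal(nrow(d), 48L)
  for (k in c(12, 24, 36, 48)) {
    counts <- table(d$arm[seq_len(k)])
    expect_true(all(counts == k / 3))
  }

  # empirical event rates match the scenario over a large generated cohort
  big <- trial_design(c("S", "E"), 5000, 2)
  bd <- generate_trial_dataset(
    big, list(arm_scenario("S", 0.10, 0.30), arm_scenario("E", 0.25, 0.55)),
    seed = 33)
  for (a in c("S", "E")) {
    sub <- bd[bd$arm == a, ]
    p_tox <- if (a == "S") 0.10 else 0.25
    p_res <- if (a == "S") 0.30 else 0.55
    expect_lt(abs(mean(sub$tox) - p_tox),
              3 * sqrt(p_tox * (1 - p_tox) / nrow(sub)))
    expect_lt(abs(mean(sub$res) - p_res),
              3 * sqrt(p_res * (1 - p_res) / nrow(sub)))
  }
})
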