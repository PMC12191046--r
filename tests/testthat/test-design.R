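test_that("sample-size exploration reproduces the candidate-design table", {
  tab <- explore_designs(c(10, 15, 20), k_arms = 3,
                         events_e = c(6, 10, 14), events_s = c(3, 5, 7),
                         deltas = 0.15)
  expect_equal(tab$n_total, c(30L, 45L, 60L))
  expect_equal(round(tab$lower, 2), c(-0.13, -0.02, 0.04))
  expect_equal(round(tab$upper, 2), c(0.63, 0.61, 0.60))
  expect_equal(round(tab$pr_improve_0.15, 2), c(0.74, 0.84, 0.90))
  # identical hypothetical arms: interval symmetric about 0, Pr(delta=0) = 0.5
  same <- explore_designs(12, events_e = 6, events_s = 6, deltas = 0)
  expect_equal(same$lower, -same$upper, tolerance = 1e-5)
  expect_equal(same$pr_improve_0, 0.5, tolerance = 1e-8)
})

test_that("fractions scale to candidate sizes and reject non-integer scalings", {
  tab <- explore_designs(c(10, 20), frac = c(0.6, 0.3), deltas = 0.15)
  expect_equal(tab$data, c("6/10 vs 3/10", "12/20 vs 6/20"))
  expect_error(explore_designs(c(10, 15), frac = c(0.25, 0.1)),
               "not representable at n = 10")
  expect_error(explore_designs(10, deltas = 0.15), "supply")
})

test_that("arm counts CSV round-trips through the reader", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(arm = c("S", "E"), events = c(4, 8),
                       total = c(16, 16)), path, row.names = FALSE)
  arms <- read_arm_counts(path)
  expect_length(arms, 2)
  expect_equal(arms[[2]]$label, "E")
  # default beta(0.5, 0.5) prior applied
  expect_equal(arms[[2]]$params$alpha, 8.5)
  expect_equal(arms[[1]]$params$beta, 12.5)
  expect_error(read_arm_counts({
    p2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1), p2, row.names = FALSE)
    p2
  }), "columns")
})

cli_run <- function(cmd, cfg_list = NULL, extra = character(0)) {
  out <- file.path(tempfile(), "out")
  args <- c(cmd, "--out-dir", out, extra)
  if (!is.null(cfg_list)) {
    cfg <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg_list, cfg, auto_unbox = TRUE, digits = NA)
    args <- c(args, "--config", cfg)
  }
  status <- run_design_cli(args)
  list(status = status, out = out)
}

test_that("posterior and compare subcommands write the expected tables", {
  counts <- list(counts = list(
    list(arm = "S", events = 5, total = 9),
    list(arm = "E1", events = 9, total = 10),
    list(arm = "E2", events = 10, total = 11)))
  r <- cli_run("posterior", counts)
  expect_equal(r$status, 0L)
  tab <- read.csv(file.path(r$out, "posterior.csv"))
  expect_equal(tab$arm, c("S", "E1", "E2"))
  expect_equal(tab$alpha, c(5.5, 9.5, 10.5))

  counts$reference <- "S"
  counts$deltas <- 0.15
  r <- cli_run("compare", counts)
  expect_equal(r$status, 0L)
  tab <- read.csv(file.path(r$out, "compare.csv"))
  expect_equal(round(tab$pr_improve_0.15, 2), c(0.82, 0.84))
  expect_true(file.exists(file.path(r$out, "run.log")))
})

test_that("boundary and oc subcommands derive triggers and exact OCs", {
  rule_cfg <- list(rule = list(type = "safety", limit = 0.3,
                               looks = c(4, 8, 12), n_max = 16,
                               cutoff = list(kind = "constant", c = 0.9)))
  r <- cli_run("boundary", rule_cfg)
  expect_equal(r$status, 0L)
  expect_equal(read.csv(file.path(r$out, "boundary.csv"))$trigger, c(3, 5, 6))
  expect_match(readLines(file.path(r$out, "boundary.txt")),
               "stop if >= 3/4, 5/8, 6/12", fixed = TRUE)

  rule_cfg$true_p <- c(0.3, 0.5)
  r <- cli_run("oc", rule_cfg)
  tab <- read.csv(file.path(r$out, "oc.csv"))
  expect_equal(tab$p_stop, c(0.167, 0.658), tolerance = 1e-3)
  expect_equal(tab$q50, c(16, 12))
})

test_that("stochastic subcommands demand a seed and honour it", {
  rand_cfg <- list(arms = c("E", "S"), block_size = 4, n_blocks = 3)
  r <- cli_run("randomize", rand_cfg)
  expect_equal(r$status, 1L)  # no --seed
  expect_false(file.exists(file.path(r$out, "plan.csv")))
  r <- cli_run("randomize", rand_cfg, extra = c("--seed", "4"))
  expect_equal(r$status, 0L)
  lines <- readLines(file.path(r$out, "plan.csv"))
  expect_equal(lines[1], "# seed: 4")
  tab <- read.csv(file.path(r$out, "plan.csv"), comment.char = "#")
  expect_equal(nrow(tab), 12L)

  design_cfg <- list(
    design = list(arms = c("S", "E"), n_per_arm = 8, block_size = 2,
                  safety_rules = list(E = list(
                    type = "safety", limit = 0.3, looks = c(4),
                    n_max = 8, cutoff = list(kind = "constant", c = 0.9)))),
    scenario = list(list(label = "S", p_tox = 0.3, p_res = 0.4),
                    list(label = "E", p_tox = 0.3, p_res = 0.4)))
  r <- cli_run("generate-data", design_cfg, extra = c("--seed", "11"))
  expect_equal(r$status, 0L)
  tab <- read.csv(file.path(r$out, "patients.csv"))
  expect_true(all(c("id", "block", "arm", "tox", "res") %in% names(tab)))

  design_cfg$n_sims <- 40
  r <- cli_run("simulate", design_cfg, extra = c("--seed", "2"))
  expect_equal(r$status, 0L)
  tab <- read.csv(file.path(r$out, "simulate.csv"))
  expect_equal(tab$arm, c("S", "E", "none"))
  expect_equal(sum(tab$pr_selected), 1)
})

test_that("explore and calibrate subcommands run end to end", {
  r <- cli_run("explore", list(n_per_arm = c(10, 20), k_arms = 3,
                               events_e = c(6, 14), events_s = c(3, 7),
                               deltas = 0.15))
  expect_equal(r$status, 0L)
  tab <- read.csv(file.path(r$out, "explore.csv"))
  expect_equal(round(tab$pr_improve_0.15, 2), c(0.74, 0.90))

  cal_cfg <- list(
    rule = list(type = "safety", limit = 0.2, unacceptable = 0.4,
                looks = c(8, 16), n_max = 24,
                comparator = list(alpha = 200, beta = 800)),
    grid = list(list(kind = "constant", c = 0.85),
                list(kind = "constant", c = 0.90)),
    p_stop_max_at_limit = 0.11)
  r <- cli_run("calibrate", cal_cfg)
  expect_equal(r$status, 0L)
  txt <- readLines(file.path(r$out, "calibrate.txt"))
  expect_match(txt[1], "c = 0.9", fixed = TRUE)
})

test_that("configuration errors exit non-zero with no partial output", {
  # unknown subcommand
  expect_equal(run_design_cli("frobnicate"), 1L)
  # empty config file
  cfg <- tempfile(fileext = ".json")
  file.create(cfg)
  out <- tempfile()
  st <- run_design_cli(c("posterior", "--config", cfg, "--out-dir", out))
  expect_equal(st, 1L)
  expect_false(file.exists(file.path(out, "posterior.csv")))
  # config without counts
  writeLines("{}", cfg)
  st <- run_design_cli(c("posterior", "--config", cfg, "--out-dir", out))
  expect_equal(st, 1L)
  expect_false(file.exists(file.path(out, "posterior.csv")))
})

test_that("the report subcommand regenerates the worked-example tables", {
  out <- file.path(tempfile(), "report")
  st <- run_design_cli(c("report", "--out-dir", out))
  expect_equal(st, 0L)
  worked <- read.csv(file.path(out, "worked_posteriors.csv"))
  expect_equal(round(worked$mean, 3), c(0.405, 0.038))
  ocs <- read.csv(file.path(out, "safety_rule_ocs.csv"))
  expect_equal(round(ocs$p_stop, 2), c(0.17, 0.39, 0.66, 0.86))
  cmp <- read.csv(file.path(out, "interim_comparisons.csv"))
  expect_equal(nrow(cmp), 4L)
})
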