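# Independent oracles, deliberately kept apart from the package's own
# computational routes.

# Monte-Carlo oracle for Pr(theta_E > theta_S + delta) by paired beta draws.
mc_improvement <- function(postE, postS, delta, n_draws, seed) {
  set.seed(seed)
  xE <- rbeta(n_draws, postE$alpha, postE$beta)
  xS <- rbeta(n_draws, postS$alpha, postS$beta)
  mean(xE > xS + delta)
}

# Exhaustive brute-force stop-time distribution: enumerate all 2^n binary
# outcome sequences, apply the integer boundary at each look, and weight each
# sequence by its Bernoulli probability.
brute_force_oc <- function(boundary, true_p, n_max) {
  type <- attr(boundary, "type")
  looks <- boundary$look_n
  sizes <- c(looks, n_max)
  dist <- setNames(numeric(length(sizes)), sizes)
  for (code in 0:(2^n_max - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_max)]
    pr <- prod(ifelse(bits == 1L, true_p, 1 - true_p))
    stopped_at <- NA_integer_
    for (j in seq_along(looks)) {
      trig <- boundary$trigger[j]
      if (is.na(trig)) next
      x <- sum(bits[seq_len(looks[j])])
      hit <- if (type == "safety") x >= trig else x <= trig
      if (hit) { stopped_at <- looks[j]; break }
    }
    key <- as.character(if (is.na(stopped_at)) n_max else stopped_at)
    dist[key] <- dist[key] + pr
  }
  dist
}

# Direct tail-probability evaluation of a fixed-threshold posterior
# criterion, bypassing the rule machinery.
fixed_criterion <- function(prior, events, total, limit, direction) {
  post <- beta_params(prior$alpha + events, prior$beta + total - events)
  pbeta(limit, post$alpha, post$beta, lower.tail = (direction == "below"))
}

cell_trial_rule <- function() {
  safety_rule(0.30, monitoring_schedule(c(4, 8, 12), 16),
              unacceptable = 0.40)
}

comparator_rule <- function() {
  safety_rule(0.20, monitoring_schedule(c(8, 16), 24),
              prior = prior_from_mean(0.20, 1),
              comparator = beta_params(200, 800),
              unacceptable = 0.40)
}

jeffreys <- function() beta_params(0.5, 0.5)
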