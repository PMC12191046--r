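# Balanced permuted-block randomization, restricted so per-arm sample sizes
# are equal at every block boundary, with stratified and enrichment variants.

#' Permuted-block randomization plan
#'
#' Generates the full assignment sequence up front: each block is an
#' independent uniform random permutation of the balanced multiset holding
#' every arm exactly `block_size / K` times, so per-arm counts are perfectly
#' balanced at every block boundary — which is what lets interim monitoring
#' be applied at equal per-arm sample sizes.
#'
#' @param arms Character vector of arm labels.
#' @param block_size Block size, a positive multiple of the number of arms.
#' @param n_blocks Number of blocks; total length is
#'   `block_size * n_blocks`.
#' @param seed Integer seed; the plan is reproducible.
#' @return A data frame of class `rand_plan` with columns `position`,
#'   `block`, `arm`; the seed, arms, and block size are kept as attributes.
#' @examples
#' permuted_blocks(c("E", "S"), block_size = 8, n_blocks = 6, seed = 11)
#' @export
permuted_blocks <- function(arms, block_size, n_blocks, seed = 1L) {
  stopifnot(is.character(arms), length(arms) >= 2L, !anyDuplicated(arms),
            is.numeric(block_size), block_size == round(block_size),
            block_size > 0,
            is.numeric(n_blocks), n_blocks == round(n_blocks), n_blocks > 0)
  if (block_size %% length(arms) != 0L)
    stop("block_size must be a multiple of the number of arms",
         call. = FALSE)
  per_block <- block_size %/% length(arms)
  assignments <- with_seed(seed,
    as.vector(replicate(n_blocks, sample(rep(arms, per_block)))))
  out <- data.frame(position = seq_len(block_size * n_blocks),
                    block = rep(seq_len(n_blocks), each = block_size),
                    arm = assignments, stringsAsFactors = FALSE)
  attr(out, "arms") <- arms
  attr(out, "block_size") <- as.integer(block_size)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("rand_plan", "data.frame")
  out
}

#' @export
print.rand_plan <- function(x, max_show = 24L, ...) {
  arms <- attr(x, "arms")
  cat(sprintf("randomization plan: %d arms, blocks of %d, %d positions (seed %d)\n",
              length(arms), attr(x, "block_size"), nrow(x), attr(x, "seed")))
  n <- min(nrow(x), max_show)
  cat("  ", paste(x$arm[seq_len(n)], collapse = " "),
      if (nrow(x) > n) "..." else "", "\n")
  invisible(x)
}

#' Per-arm balance at enrollment checkpoints
#'
#' @param plan A [rand_plan()] (or [permuted_blocks()]) data frame.
#' @param checkpoints Enrollment counts at which to tabulate per-arm sample
#'   sizes; each must be at most the plan length.
#' @return A data frame with one row per checkpoint: `checkpoint`, one
#'   count column per arm, and a `balanced` flag (all counts equal).
#' @examples
#' p <- permuted_blocks(c("S", "E1", "E2"), 6, 8, seed = 3)
#' balance_report(p, c(12, 24, 36))
#' @export
balance_report <- function(plan, checkpoints) {
  stopifnot(inherits(plan, "rand_plan"),
            is.numeric(checkpoints), all(checkpoints >= 1),
            all(checkpoints <= nrow(plan)))
  arms <- attr(plan, "arms")
  rows <- lapply(as.integer(checkpoints), function(k) {
    counts <- vapply(arms, function(a) sum(plan$arm[seq_len(k)] == a),
                     integer(1L))
    out <- data.frame(checkpoint = k, stringsAsFactors = FALSE)
    out[arms] <- as.list(counts)
    out$balanced <- length(unique(counts)) == 1L
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified permuted-block randomization
#'
#' An independent permuted-block plan per stratum, with distinct sub-seeds
#' derived from the root seed, so within-stratum balance holds at each
#' stratum's own block boundaries. Pooled cross-stratum counts need not be
#' balanced at arbitrary checkpoints.
#'
#' @param strata Named list; each element is a list with fields `arms`,
#'   `block_size`, `n_blocks` as for [permuted_blocks()].
#' @param seed Integer root seed; stratum `i` uses `seed + i`.
#' @return A named list of [permuted_blocks()] plans of class
#'   `stratified_plan`.
#' @export
stratified_plan <- function(strata, seed = 1L) {
  stopifnot(is.list(strata), length(strata) >= 1L, !is.null(names(strata)),
            all(nzchar(names(strata))))
  plans <- lapply(seq_along(strata), function(i) {
    s <- strata[[i]]
    permuted_blocks(s$arms, s$block_size, s$n_blocks,
                    seed = as.integer(seed) + i)
  })
  names(plans) <- names(strata)
  structure(plans, class = "stratified_plan")
}

#' @export
print.stratified_plan <- function(x, ...) {
  for (s in names(x)) {
    cat(sprintf("stratum %s:\n", s))
    print(x[[s]])
  }
  invisible(x)
}

#' Re-plan a randomization sequence after dropping an arm
#'
#' Implements enrichment: positions from `from_position` on are re-blocked
#' over the surviving arms, with the block size scaled to the surviving arm
#' count (e.g. blocks of 6 over 3 arms become blocks of 4 over 2), so the
#' total planned sample size is preserved and interim balance is restored
#' among survivors. Assignments before `from_position` are untouched; a
#' final partial block is the truncated prefix of one more permuted block.
#'
#' @param plan A [rand_plan()].
#' @param dropped Label of the arm being dropped.
#' @param from_position First position (1-based) to re-randomize.
#' @param seed Integer seed for the new tail.
#' @return A new [rand_plan()] of the same length.
#' @export
enrichment_replan <- function(plan, dropped, from_position, seed = 1L) {
  stopifnot(inherits(plan, "rand_plan"),
            is.numeric(from_position),
            from_position >= 1, from_position <= nrow(plan) + 1)
  arms <- attr(plan, "arms")
  if (!dropped %in% arms)
    stop(sprintf("arm '%s' is not in the plan", dropped), call. = FALSE)
  survivors <- setdiff(arms, dropped)
  if (length(survivors) == 0L)
    stop("cannot drop the last arm", call. = FALSE)
  from_position <- as.integer(from_position)
  if (from_position > nrow(plan)) return(plan)
  old_bs <- attr(plan, "block_size")
  new_bs <- (old_bs %/% length(arms)) * length(survivors)
  tail_len <- nrow(plan) - from_position + 1L
  n_full <- tail_len %/% new_bs
  rem <- tail_len - n_full * new_bs
  new_tail <- with_seed(seed, {
    blocks <- character(0)
    if (n_full > 0)
      blocks <- as.vector(replicate(n_full,
        sample(rep(survivors, new_bs %/% length(survivors)))))
    if (rem > 0)
      blocks <- c(blocks,
        sample(rep(survivors, new_bs %/% length(survivors)))[seq_len(rem)])
    blocks
  })
  out <- plan
  out$arm[from_position:nrow(plan)] <- new_tail
  n_head_blocks <- if (from_position > 1L)
    max(plan$block[seq_len(from_position - 1L)]) else 0L
  out$block[from_position:nrow(plan)] <- n_head_blocks +
    rep(seq_len(n_full + (rem > 0)),
        times = c(rep(new_bs, n_full), if (rem > 0) rem))
  attr(out, "replanned_from") <- from_position
  # the plan now allocates over the survivors only; successive drops chain
  attr(out, "arms") <- survivors
  attr(out, "block_size") <- as.integer(new_bs)
  out
}
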