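# Independent, loop-based reference implementations and tiny fixtures.
# The oracles deliberately avoid the package's vectorized code paths:
# profiles are extracted row by row and correlated pair by pair with
# stats::cor().

# --- fixtures ---------------------------------------------------------------

tiny_partition <- function(sizes = c(A = 4, B = 4, C = 3)) {
  network_partition(data.frame(
    node_index = seq_len(sum(sizes)),
    module = rep(names(sizes), sizes)))
}

# random valid FC stack (symmetric, unit diagonal, entries in [-1, 1])
random_stack <- function(m, n_win, seed) {
  set.seed(seed)
  mats <- lapply(seq_len(n_win), function(i) {
    x <- matrix(rnorm((m + 2) * m), m + 2, m)
    stats::cor(x)
  })
  arr <- array(unlist(mats), dim = c(m, m, n_win))
  structure(list(subject_id = "rand", window_length = NA_integer_,
                 fisher_z = FALSE, windows = arr),
            class = "fc_stack")
}

tiny_spec <- function(...) {
  args <- list(...)
  merged <- list(n_control = 2, n_patient = 2,
                 partition = tiny_partition(), n_volumes = 60,
                 n_states = 2, mean_dwell = 10,
                 target_modules = "A", seed = 1L)
  for (nm in names(args)) merged[[nm]] <- args[[nm]]
  do.call(cohort_spec, merged)
}

# --- variability oracles ----------------------------------------------------

oracle_nodal <- function(stack, k) {
  n <- dim(stack$windows)[3]
  profiles <- lapply(seq_len(n), function(i) stack$windows[k, -k, i])
  rs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rs <- c(rs, stats::cor(profiles[[i]], profiles[[j]]))
  }
  1 - mean(rs)
}

oracle_block <- function(stack, rows, cols, upper_only) {
  n <- dim(stack$windows)[3]
  profiles <- lapply(seq_len(n), function(i) {
    blk <- stack$windows[rows, cols, i]
    if (upper_only) blk[upper.tri(blk)] else as.vector(blk)
  })
  rs <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rs <- c(rs, stats::cor(profiles[[i]], profiles[[j]]))
  }
  1 - mean(rs)
}

oracle_intra <- function(stack, partition, module) {
  idx <- module_members(partition)[[module]]
  oracle_block(stack, idx, idx, upper_only = TRUE)
}

oracle_inter <- function(stack, partition, a, b) {
  ia <- module_members(partition)[[a]]
  ib <- module_members(partition)[[b]]
  oracle_block(stack, ia, ib, upper_only = FALSE)
}

# --- permutation oracles ----------------------------------------------------

# exhaustive label permutation: proportion of all C(n, np) relabelings with
# a mean difference at least (at most) the observed one
oracle_perm_exhaustive <- function(vc, vp) {
  pooled <- c(vc, vp)
  n <- length(pooled)
  np <- length(vp)
  obs <- mean(vp) - mean(vc)
  sets <- utils::combn(n, np)
  diffs <- apply(sets, 2, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  # count exact ties despite floating-point summation-order noise
  eps <- 1e-10 * max(1, abs(obs))
  list(p_greater = mean(diffs >= obs - eps),
       p_smaller = mean(diffs <= obs + eps))
}

# exhaustive sign-flip null over all 2^n patterns
oracle_signflip_exhaustive <- function(d) {
  n <- length(d)
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  nulls <- as.vector(signs %*% d) / n
  eps <- 1e-10 * max(1, abs(obs))
  list(p_greater = mean(nulls >= obs - eps),
       p_smaller = mean(nulls <= obs + eps))
}

# --- misc helpers -----------------------------------------------------------

write_micro_cohort <- function(dir, spec = tiny_spec()) {
  simulate_cohort(spec, dir = dir)
}
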