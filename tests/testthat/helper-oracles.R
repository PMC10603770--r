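# Independent oracles used against the HMM implementation.

# All 4^M hidden-state paths, brute force: total likelihood and per-locus
# posteriors for one progeny (emission matrix 4 x M).
brute_force_paths <- function(E_ind, rf) {
  M <- ncol(E_ind)
  states <- 1:4
  paths <- as.matrix(expand.grid(rep(list(states), M)))
  si <- c(1L, 1L, 2L, 2L)
  sj <- c(1L, 2L, 1L, 2L)
  probs <- apply(paths, 1, function(p) {
    pr <- 0.25 * E_ind[p[1], 1]
    if (M > 1) for (m in 2:M) {
      r <- rf[m - 1]
      sw <- (si[p[m]] != si[p[m - 1]]) + (sj[p[m]] != sj[p[m - 1]])
      pr <- pr * r^sw * (1 - r)^(2 - sw) * E_ind[p[m], m]
    }
    pr
  })
  lik <- sum(probs)
  post <- matrix(0, 4, M)
  for (m in 1:M) for (s in 1:4)
    post[s, m] <- sum(probs[paths[, m] == s]) / lik
  list(lik = lik, loglik = log(lik), posteriors = post,
       paths = paths, path_probs = probs)
}

# Exact likelihood of a <=3-marker dataset as a function of the interval
# recombination fractions, via per-progeny path-group coefficients.
exact_lik_fun <- function(E, rf_len) {
  N <- dim(E)[2]; M <- dim(E)[3]
  stopifnot(M - 1 == rf_len, M <= 3)
  si <- c(1L, 1L, 2L, 2L); sj <- c(1L, 2L, 1L, 2L)
  paths <- as.matrix(expand.grid(rep(list(1:4), M)))
  sw <- sapply(seq_len(M - 1), function(m)
    (si[paths[, m + 1]] != si[paths[, m]]) +
      (sj[paths[, m + 1]] != sj[paths[, m]]))
  sw <- matrix(sw, nrow(paths), M - 1)
  emis <- sapply(seq_len(N), function(n) {
    e <- 1
    for (m in 1:M) e <- e * E[paths[, m], n, m]
    e
  })
  function(rf) {
    f <- rep(0.25, nrow(paths))
    for (t in seq_len(M - 1))
      f <- f * rf[t]^sw[, t] * (1 - rf[t])^(2 - sw[, t])
    sum(log(colSums(emis * f)))
  }
}

# Grid-search MLE of the exact likelihood (coordinate refinement down to
# step 1e-4), independent of the EM code path.
grid_mle_rf <- function(E) {
  M <- dim(E)[3]
  ll <- exact_lik_fun(E, M - 1)
  rf <- rep(0.25, M - 1)
  for (pass in 1:6) {
    step <- c(0.02, 0.005, 0.002, 5e-4, 2e-4, 1e-4)[pass]
    for (t in seq_len(M - 1)) {
      grid <- seq(max(1e-8, rf[t] - 25 * step),
                  min(0.5 - 1e-8, rf[t] + 25 * step), by = step)
      vals <- vapply(grid, function(r) {
        rr <- rf; rr[t] <- r; ll(rr)
      }, numeric(1))
      rf[t] <- grid[which.max(vals)]
    }
  }
  rf
}

# Exact multinomial goodness-of-fit p-value by enumeration (small n).
exact_multinomial_p <- function(obs, prob) {
  n <- sum(obs)
  k <- length(obs)
  counts <- as.matrix(expand.grid(rep(list(0:n), k - 1)))
  counts <- counts[rowSums(counts) <= n, , drop = FALSE]
  counts <- cbind(counts, n - rowSums(counts))
  probs <- apply(counts, 1, dmultinom, prob = prob)
  p_obs <- dmultinom(obs, prob = prob)
  sum(probs[probs <= p_obs + 1e-12])
}

# random small dataset (informative biallelic markers) with its truth;
# B3.7-only sets keep every interval identifiable (a D1-D2 flank leaves
# a likelihood ridge where the MLE is not unique)
random_small_sim <- function(n_markers, n_progeny, seed,
                             total_cm = 30, b37_only = FALSE) {
  props <- if (b37_only) c(B3.7 = 1)
           else c(B3.7 = 1, D1.10 = 1, D2.15 = 1)
  cfg <- sim_config(n_markers = n_markers, n_progeny = n_progeny,
                    total_cm = total_cm, type_proportions = props)
  simulate_f1(cfg, seed = seed, observe = "true")
}
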