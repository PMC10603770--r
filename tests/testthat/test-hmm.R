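test_that("transition matrices factorize over the two meioses", {
  expect_equal(transition_matrix(0), diag(4))
  expect_equal(transition_matrix(0.5), matrix(0.25, 4, 4))
  Tm <- transition_matrix(0.123)
  expect_equal(rowSums(Tm), rep(1, 4))
  expect_equal(Tm, t(Tm))
  expect_equal(Tm[1, 4], 0.123^2)       # both meioses recombine
  expect_error(transition_matrix(0.6), "0.5")
})

test_that("emission vectors map states through phased parental alleles", {
  # B3.7 coupling x coupling, error-free het call: states (1,2) and (2,1)
  # produce "ab"
  prior <- c(aa = 0, ab = 1, bb = 0)
  e <- emission_vector("ab", "ab", 0L, 0L, prior)
  expect_equal(e, c(0, 1, 1, 0))
  # under a flipped P2 phase the roles swap
  e2 <- emission_vector("ab", "ab", 0L, 1L, prior)
  expect_equal(e2, c(1, 0, 0, 1))
  # missing observation -> all-ones
  expect_equal(emission_vector("ab", "ab", 0L, 0L, rep(1 / 3, 3)),
               rep(1, 4))
  # D1.10: P2 is uninformative, entries collapse over its index
  d <- emission_vector("ab", "aa", 0L, NA, c(aa = 0.9, ab = 0.1))
  expect_equal(d[1], d[2])
  expect_equal(d[3], d[4])
  expect_equal(d, c(0.9, 0.9, 0.1, 0.1))
})

test_that("forward-backward posteriors match brute-force path enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    M <- sample(2:4, 1)
    N <- sample(1:3, 1)
    E <- array(runif(4 * N * M, 0.05, 1), c(4, N, M))
    rf <- runif(M - 1, 0.01, 0.45)
    fb <- forward_backward(E, rf)
    for (n in seq_len(N)) {
      oracle <- brute_force_paths(E[, n, , drop = TRUE], rf)
      expect_equal(fb$loglik_ind[n], oracle$loglik, tolerance = 1e-9)
      expect_equal(fb$posteriors[, n, ], oracle$posteriors,
                   tolerance = 1e-9)
    }
    # posteriors are distributions at every locus
    expect_equal(apply(fb$posteriors, c(2, 3), sum),
                 matrix(1, N, M), tolerance = 1e-9)
  }
})

test_that("uninformative data leave the chain at its stationary point", {
  E <- array(1, c(4, 2, 3))
  fb <- forward_backward(E, c(0.5, 0.5))
  expect_equal(as.vector(fb$posteriors), rep(0.25, 24))
  # EM update from r = 0.5 stays at 0.5
  expect_equal(fb$exp_rec / (2 * 2), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("EM recovers the recombinant-gamete fraction on perfect data", {
  # 10 progeny, 2 markers, fully informative phases; exactly 2 of the 20
  # meioses recombine in the interval -> r = 0.1
  o1 <- rbind(rep(1L, 10), c(2L, rep(1L, 9)))            # 1 switch
  o2row <- rep(c(1L, 2L), 5)
  o2 <- rbind(o2row, replace(o2row, 1, 2L))              # 1 switch
  sw <- sum(o1[1, ] != o1[2, ]) + sum(o2[1, ] != o2[2, ])
  expect_equal(sw, 2L)
  ds <- dataset_from_origins(o1, o2, p1 = "ab", p2 = "cd")  # A.1 markers
  phases <- cbind(p1 = c(0L, 0L), p2 = c(0L, 0L))
  map <- estimate_map(ds, phases, "global_error", 0, rf_init = 0.25)
  expect_equal(map$rf, 0.1, tolerance = 1e-6)
})

test_that("EM matches the exact-likelihood grid search on small instances", {
  set.seed(41)
  for (rep in 1:10) {
    sim <- random_small_sim(3, sample(4:8, 1), seed = 400 + rep,
                            b37_only = TRUE)
    ds <- sim$dataset
    phases <- sim$truth$phases
    map <- estimate_map(ds, phases, "global_error", 0.02, rf_init = 0.2)
    priors <- create_priors(ds, "global_error", 0.02)
    E <- fsmapr:::emission_array(ds, phases, priors)
    rf_oracle <- grid_mle_rf(E)
    expect_equal(map$rf, rf_oracle, tolerance = 1e-3)
  }
})

test_that("the EM log-likelihood never decreases across iterations", {
  sim <- random_small_sim(8, 15, seed = 77)
  priors <- create_priors(sim$dataset, "global_error", 0.05)
  E <- fsmapr:::emission_array(sim$dataset, sim$truth$phases, priors)
  rf <- rep(0.3, 7)
  ll <- -Inf
  for (i in 1:25) {
    fb <- forward_backward(E, rf)
    expect_gte(fb$loglik, ll - 1e-9)
    ll <- fb$loglik
    rf <- pmin(pmax(fb$exp_rec / (2 * 15), 1e-8), 0.5 - 1e-8)
  }
})

test_that("the likelihood is invariant under a global homolog relabeling", {
  sim <- random_small_sim(6, 10, seed = 55)
  ds <- sim$dataset
  ph <- sim$truth$phases
  flip1 <- ph; flip1[, 1] <- 1L - flip1[, 1]
  flip2 <- ph; flip2[, 2] <- 1L - flip2[, 2]
  m0 <- estimate_map(ds, ph, "global_error", 0.01, rf_init = 0.1)
  m1 <- estimate_map(ds, flip1, "global_error", 0.01, rf_init = 0.1)
  m2 <- estimate_map(ds, flip2, "global_error", 0.01, rf_init = 0.1)
  expect_equal(m1$loglik, m0$loglik, tolerance = 1e-6)
  expect_equal(m2$loglik, m0$loglik, tolerance = 1e-6)
  expect_equal(m1$rf, m0$rf, tolerance = 1e-6)
})

test_that("phases are recovered modulo the per-parent gauge flip", {
  cfg <- sim_config(n_markers = 20, n_progeny = 80,
                    type_proportions = c(B3.7 = 1), total_cm = 40)
  sim <- simulate_f1(cfg, seed = 9, observe = "true")
  ph <- infer_phases(sim$dataset)
  for (p in 1:2) {
    agree <- ph[, p] == sim$truth$phases[, p]
    expect_true(all(agree) || all(!agree))
  }
  # a single-marker dataset is trivially phase 0
  one <- subset_markers(sim$dataset, 1L)
  one$geno <- one$geno  # keep >=2 progeny
  ph1 <- infer_phases(one)
  expect_equal(unname(ph1[1, ]), c(0L, 0L))
})

test_that("coupling and repulsion phases differ in likelihood unless unlinked", {
  # two D1.10 markers, strong linkage: the two relative P1 phases give
  # different two-marker likelihoods
  sim <- random_small_sim(2, 40, seed = 12)
  ds <- sim$dataset
  d1 <- which(ds$markers$type == "D1.10")
  if (length(d1) < 2) {
    cfg <- sim_config(n_markers = 2, n_progeny = 40, total_cm = 10,
                      type_proportions = c(D1.10 = 1))
    sim <- simulate_f1(cfg, seed = 12, observe = "true")
    ds <- sim$dataset
  }
  coupling <- cbind(p1 = c(0L, 0L), p2 = c(NA_integer_, NA_integer_))
  repulsion <- cbind(p1 = c(0L, 1L), p2 = c(NA_integer_, NA_integer_))
  mc <- estimate_map(ds, coupling, "global_error", 0.01, rf_init = 0.25)
  mr <- estimate_map(ds, repulsion, "global_error", 0.01, rf_init = 0.25)
  expect_gt(abs(mc$loglik - mr$loglik), 1)
})

test_that("two-point estimation flags pairs without a shared informative parent", {
  cfg <- sim_config(n_markers = 4, n_progeny = 60, total_cm = 20,
                    type_proportions = c(D1.10 = 1, D2.15 = 1))
  sim <- simulate_f1(cfg, seed = 23, observe = "true")
  ds <- sim$dataset
  d1 <- which(ds$markers$type == "D1.10")
  d2 <- which(ds$markers$type == "D2.15")
  skip_if(length(d1) == 0 || length(d2) == 0)
  est <- estimate_rf_pair(d1[1], d2[1], ds)
  expect_identical(est$flag, "unlinked-types")
  expect_equal(est$rf, 0.5)
  expect_equal(est$lod, 0)
})

test_that("two-point estimates behave at the linkage extremes", {
  # duplicated marker: r at the lower clamp with a large LOD
  o1 <- rbind(rep(c(1L, 2L), 5), rep(c(1L, 2L), 5))
  o2 <- rbind(rep(c(1L, 1L, 2L, 2L), length.out = 10),
              rep(c(1L, 1L, 2L, 2L), length.out = 10))
  ds <- dataset_from_origins(o1, o2, p1 = "ab", p2 = "ab")
  est <- estimate_rf_pair(1, 2, ds, global_error = 1e-6)
  expect_lt(est$rf, 1e-4)
  expect_gt(est$lod, 3)
  # independent markers: r near 0.5, LOD near 0 (the best-phase search
  # biases individual estimates slightly below 0.5, so check the mean)
  rfs <- lods <- numeric(5)
  for (i in 1:5) {
    cfg <- sim_config(n_markers = 2, n_progeny = 200, total_cm = 1000,
                      type_proportions = c(B3.7 = 1))
    sim <- simulate_f1(cfg, seed = 60 + i, observe = "true")
    est2 <- estimate_rf_pair(1, 2, sim$dataset, global_error = 1e-4)
    rfs[i] <- est2$rf; lods[i] <- est2$lod
  }
  expect_gt(mean(rfs), 0.4)
  expect_lt(mean(lods), 2)
})

test_that("the pairwise rf matrix is symmetric with flagged D1xD2 cells", {
  cfg <- sim_config(n_markers = 5, n_progeny = 40, total_cm = 25,
                    type_proportions = c(B3.7 = 1, D1.10 = 1, D2.15 = 1))
  sim <- simulate_f1(cfg, seed = 71, observe = "true")
  rfm <- rf_matrix(sim$dataset, global_error = 0.01)
  expect_equal(rfm$rf, t(rfm$rf))
  expect_equal(rfm$lod, t(rfm$lod))
  types <- sim$dataset$markers$type
  for (i in 1:4) for (j in (i + 1):5) {
    if (setequal(types[c(i, j)], c("D1.10", "D2.15")))
      expect_true(rfm$unlinked[i, j])
  }
})

test_that("Viterbi decoding recovers simulated crossovers exactly", {
  # error-free, one P1 crossover between markers 5 and 6 in progeny 1
  M <- 10
  o1 <- matrix(1L, M, 6); o2 <- matrix(1L, M, 6)
  o1[6:M, 1] <- 2L
  o2[, 2] <- 2L
  ds <- dataset_from_origins(o1, o2, p1 = "ab", p2 = "cd")
  phases <- cbind(p1 = rep(0L, M), p2 = rep(0L, M))
  map <- estimate_map(ds, phases, "global_error", 1e-5, rf_init = 0.05)
  dec <- decode_haplotypes(map)
  expect_equal(unname(dec$breakpoints[1, ]), c(1L, 0L))
  expect_equal(unname(dec$breakpoints[2, ]), c(0L, 0L))
  expect_equal(unname(dec$origin_p1[, 1]), o1[, 1])
  expect_equal(sum(dec$breakpoints[3:6, ]), 0L)
})

test_that("the Viterbi path is at least as probable as any enumerated path", {
  set.seed(81)
  sim <- random_small_sim(3, 5, seed = 91)
  ds <- sim$dataset
  map <- estimate_map(ds, sim$truth$phases, "global_error", 0.05,
                      rf_init = 0.2)
  dec <- decode_haplotypes(map)
  priors <- create_priors(ds, "global_error", 0.05)
  E <- fsmapr:::emission_array(ds, sim$truth$phases, priors)
  state_of <- function(i, j) which(fsmapr:::STATE_I == i &
                                     fsmapr:::STATE_J == j)
  for (n in 1:5) {
    oracle <- brute_force_paths(E[, n, , drop = TRUE], map$rf)
    vit <- vapply(1:3, function(m)
      state_of(dec$origin_p1[m, n], dec$origin_p2[m, n]), integer(1))
    vit_prob <- oracle$path_probs[
      which(apply(oracle$paths, 1, function(p) all(p == vit)))]
    expect_equal(vit_prob, max(oracle$path_probs), tolerance = 1e-12)
  }
})

test_that("breakpoint accounting follows the count-only definition", {
  dec <- list(breakpoints = cbind(p1 = c(1L, 0L, 3L), p2 = c(0L, 2L, 1L)),
              marker_ids = NULL)
  truth <- list(breakpoints = cbind(p1 = c(1L, 1L, 1L), p2 = c(0L, 2L, 1L)))
  res <- count_breakpoint_errors(dec, truth)
  # progeny 2: simulated 1, estimated 0 -> 1 underestimated
  # progeny 3: estimated 3, simulated 1 -> 2 overestimated
  expect_equal(res$underestimated, 1L)
  expect_equal(res$overestimated, 2L)
  ident <- count_breakpoint_errors(
    list(breakpoints = truth$breakpoints, marker_ids = NULL), truth)
  expect_equal(ident$overestimated + ident$underestimated, 0L)
})
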