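#' Hidden Markov model over transmitted parental homologs
#'
#' The latent state of a progeny individual at a locus is the ordered
#' pair `(i, j)`: which of P1's two homologs (`i`) and which of P2's
#' (`j`) it inherited. States are ordered `(1,1), (1,2), (2,1), (2,2)`.
#' Transitions between adjacent loci factorize over the two independent
#' meioses with a shared recombination fraction per interval; emissions
#' are the genotype-class priors of [create_priors()] mapped through the
#' parental linkage phases.
#'
#' @name hmm
NULL

STATE_I <- c(1L, 1L, 2L, 2L)
STATE_J <- c(1L, 2L, 1L, 2L)
# recombination events implied by a state change: P1 switch + P2 switch
REC_COUNT <- outer(STATE_I, STATE_I, "!=") + outer(STATE_J, STATE_J, "!=")

#' Transition matrix for one interval
#'
#' Kronecker product of the two per-meiosis 2x2 switch matrices
#' `[[1-r, r], [r, 1-r]]`; no crossover interference is assumed, so the
#' two parental meioses are independent with the same `r`.
#'
#' @param r recombination fraction in `[0, 0.5]`.
#' @return 4 x 4 row-stochastic (and symmetric) matrix.
#' @export
transition_matrix <- function(r) {
  if (r < 0 || r > 0.5) stop("recombination fraction must lie in [0, 0.5]")
  m <- matrix(c(1 - r, r, r, 1 - r), 2, 2)
  kronecker(m, m)
}

#' Emission vector of one marker under a phase assignment
#'
#' Entry `s` is the prior probability of the genotype class produced by
#' combining the allele on P1 homolog `i(s)` with the allele on P2
#' homolog `j(s)`. A missing observation (uniform prior) is encoded as
#' the all-ones vector, which leaves the likelihood unaffected.
#'
#' @param p1_call,p2_call parental genotypes of the marker.
#' @param phase1,phase2 phase codes (`NA` for homozygous parents).
#' @param prior numeric vector over the marker's observable classes
#'   (named), as one column of [create_priors()] output.
#' @return numeric vector of length 4.
#' @export
emission_vector <- function(p1_call, p2_call, phase1, phase2, prior) {
  cls <- state_classes(p1_call, p2_call, phase1, phase2)
  if (all(abs(prior - 1 / length(prior)) < 1e-12))
    return(rep(1, 4))
  unname(prior[cls])
}

# 4 x N x M emission array for the informative markers of a dataset
emission_array <- function(dataset, phases, priors) {
  M <- nrow(dataset$markers)
  N <- n_progeny(dataset)
  E <- array(NA_real_, c(4L, N, M))
  for (m in seq_len(M)) {
    pr <- priors[[m]]
    if (is.null(pr)) stop("non-informative marker in emission construction")
    cls <- state_classes(dataset$markers$p1[m], dataset$markers$p2[m],
                         phases[m, 1], phases[m, 2])
    pm <- pr[cls, , drop = FALSE]          # 4 x N
    k <- nrow(pr)
    uni <- abs(matrixStats_colMaxs(pr) - matrixStats_colMins(pr)) < 1e-12
    pm[, uni] <- 1
    E[, , m] <- pm
  }
  E
}

# small local helpers (avoid a matrixStats dependency)
matrixStats_colMaxs <- function(x) apply(x, 2, max)
matrixStats_colMins <- function(x) apply(x, 2, min)

#' Forward-backward pass over a marker sequence
#'
#' Scaled forward-backward per progeny with a uniform (1/4) initial
#' distribution, run jointly over all progeny (columns). Returns the
#' total log-likelihood, per-locus posterior state probabilities and the
#' expected number of recombination events per interval (each P1 homolog
#' switch counts 1 and each P2 switch counts 1, so the maximum per
#' individual per interval is 2).
#'
#' @param E emission array `4 x N x M` (see [emission_array()]).
#' @param rf numeric vector of `M - 1` recombination fractions.
#' @return list with `loglik` (scalar), `loglik_ind` (per progeny),
#'   `posteriors` (`4 x N x M`, each locus/progeny column sums to 1) and
#'   `exp_rec` (length `M - 1`).
#' @export
forward_backward <- function(E, rf) {
  d <- dim(E)
  N <- d[2]; M <- d[3]
  if (M < 2L) stop("forward-backward needs at least 2 markers")
  stopifnot(length(rf) == M - 1L)
  alpha <- array(NA_real_, c(4L, N, M))
  cs <- matrix(NA_real_, M, N)
  a <- matrix(E[, , 1], 4L, N) * 0.25
  cs[1, ] <- colSums(a)
  if (any(cs[1, ] <= 0))
    stop("zero-probability observation at marker 1 for progeny ",
         paste(which(cs[1, ] <= 0), collapse = ","))
  a <- sweep(a, 2, cs[1, ], "/")
  alpha[, , 1] <- a
  Ts <- lapply(rf, transition_matrix)
  for (m in 2:M) {
    e <- matrix(E[, , m], 4L, N)
    a <- (Ts[[m - 1]] %*% a) * e
    cs[m, ] <- colSums(a)
    if (any(cs[m, ] <= 0))
      stop("zero-probability observation sequence at marker ", m,
           " for progeny ", paste(which(cs[m, ] <= 0), collapse = ","))
    a <- sweep(a, 2, cs[m, ], "/")
    alpha[, , m] <- a
  }
  beta <- array(NA_real_, c(4L, N, M))
  b <- matrix(1, 4L, N)
  beta[, , M] <- b
  exp_rec <- numeric(M - 1L)
  for (m in (M - 1L):1L) {
    e <- matrix(E[, , m + 1], 4L, N)
    eb <- e * b
    ebc <- sweep(eb, 2, cs[m + 1, ], "/")
    TW <- Ts[[m]] * REC_COUNT
    exp_rec[m] <- sum((TW %*% ebc) * matrix(alpha[, , m], 4L, N))
    b <- Ts[[m]] %*% ebc
    beta[, , m] <- b
  }
  post <- alpha * beta
  # normalize defensively (scaled alpha*beta already sums to 1)
  for (m in seq_len(M)) {
    g <- matrix(post[, , m], 4L, N)
    post[, , m] <- sweep(g, 2, colSums(g), "/")
  }
  ll_ind <- colSums(log(cs))
  list(loglik = sum(ll_ind), loglik_ind = ll_ind,
       posteriors = post, exp_rec = exp_rec)
}
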