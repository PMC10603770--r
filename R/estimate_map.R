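#' Estimate a multipoint linkage map by EM
#'
#' Runs the forward-backward / expectation-maximization algorithm over
#' the marker sequence at its current (genomic) order with fixed linkage
#' phases. The M-step for interval `t` is the expected number of
#' recombination events divided by `2 N` (each progeny contributes two
#' meioses). Iteration stops when the largest change in any `r` falls
#' below `tol`, the log-likelihood increase falls below `1e-6`, or
#' `max_iter` is reached; estimates are clamped to
#' `[1e-8, 0.5 - 1e-8]`.
#'
#' @param dataset a [marker_dataset()] containing only informative
#'   markers in map order (non-informative markers are dropped with a
#'   message).
#' @param phases M x 2 matrix of phase codes (see [infer_phases()]).
#' @param mode,global_error error model passed to [create_priors()].
#' @param mapfunc `"haldane"` or `"kosambi"` for the cM scale.
#' @param tol convergence tolerance on `max |delta r|`.
#' @param max_iter maximum EM iterations.
#' @param rf_init optional initial recombination fractions (length
#'   M - 1); by default each interval starts from the two-point estimate
#'   of its flanking pair when defined, else 0.1.
#' @return object of class `linkage_map`: list with `markers`, `phases`,
#'   `rf`, `loglik`, `cumulative_cm`, `mapfunc`, `n_iter`, `converged`,
#'   and the `dataset` used.
#' @export
estimate_map <- function(dataset, phases,
                         mode = "global_error", global_error = 1e-5,
                         mapfunc = c("haldane", "kosambi"),
                         tol = 1e-5, max_iter = 100L, rf_init = NULL) {
  mapfunc <- match.arg(mapfunc)
  keep <- informative_markers(dataset)
  if (length(keep) < nrow(dataset$markers)) {
    message("dropping ", nrow(dataset$markers) - length(keep),
            " non-informative markers before map estimation")
    dataset <- subset_markers(dataset, keep)
    phases <- phases[keep, , drop = FALSE]
  }
  M <- nrow(dataset$markers)
  if (M < 2L) stop("map estimation needs at least 2 informative markers")
  N <- n_progeny(dataset)
  priors <- create_priors(dataset, mode, global_error)
  E <- emission_array(dataset, phases, priors)
  rf <- if (!is.null(rf_init)) rep(rf_init, length.out = M - 1L)
        else init_rf(E, N)
  rf <- clamp_rf(rf)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  fb <- NULL
  repeat {
    iter <- iter + 1L
    fb <- forward_backward(E, rf)
    rf_new <- clamp_rf(fb$exp_rec / (2 * N))
    delta <- max(abs(rf_new - rf))
    dll <- fb$loglik - ll_old
    rf <- rf_new
    ll_old <- fb$loglik
    if (delta < tol || (iter > 1L && dll < 1e-6)) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  cum <- c(0, cumsum(map_function(rf, mapfunc)))
  structure(list(markers = dataset$markers, phases = phases, rf = rf,
                 loglik = ll_old, cumulative_cm = cum, mapfunc = mapfunc,
                 n_iter = iter, converged = converged,
                 flag = if (converged) NULL else "max_iter",
                 mode = mode, global_error = global_error,
                 dataset = dataset),
            class = "linkage_map")
}

clamp_rf <- function(r) pmin(pmax(r, 1e-8), 0.5 - 1e-8)

# per-interval EM on each flanking pair for initial values
init_rf <- function(E, N, n_iter = 10L) {
  M <- dim(E)[3]
  vapply(seq_len(M - 1L), function(m) {
    Epair <- E[, , c(m, m + 1L), drop = FALSE]
    r <- 0.1
    for (i in seq_len(n_iter)) {
      fb <- forward_backward(Epair, r)
      r_new <- clamp_rf(fb$exp_rec / (2 * N))
      if (abs(r_new - r) < 1e-4) { r <- r_new; break }
      r <- r_new
    }
    # pairs with no shared information stay at the neutral default
    if (!is.finite(r)) 0.1 else r
  }, numeric(1))
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("linkage_map:", nrow(x$markers), "markers,",
      sprintf("%.2f cM (%s), loglik %.3f", max(x$cumulative_cm),
              x$mapfunc, x$loglik),
      if (x$converged) "" else "[max_iter reached]", "\n")
  invisible(x)
}

#' Total genetic length of a linkage map
#' @param map a `linkage_map`.
#' @return map length in cM.
#' @export
map_length <- function(map) max(map$cumulative_cm)

#' Infer parental linkage phases along the genomic order
#'
#' Fixes the gauge by assigning phase 0 to the first marker heterozygous
#' in each parent, then proceeds left to right: each subsequent marker's
#' compatible phase codes (at most 4 combinations) are scored by the
#' prefix likelihood, computed from the cached forward variables with
#' the new interval's recombination fraction optimized; the
#' highest-scoring code is kept, ties resolved toward code 0. Earlier
#' intervals keep their running estimates during the scan, and the final
#' map should be refit with [estimate_map()] on the chosen phases.
#'
#' If a parent is heterozygous at no marker its phase column is all
#' `NA`; the map is then driven entirely by the other parent.
#'
#' The greedy scan can occasionally mis-phase a marker whose interval to
#' the previous marker carries little prefix information (typically a
#' D2.15 marker entered from a D1.10 stretch); with `polish = TRUE`
#' (default) the scan is followed by full-likelihood polish rounds: the
#' map is fit by EM and every marker's feasible phase flips are scored
#' by the exact change in total log-likelihood (computed from cached
#' forward/backward quantities), flipping while any improvement remains.
#'
#' @inheritParams estimate_map
#' @param polish run full-likelihood phase polish rounds after the
#'   greedy scan.
#' @return M x 2 integer matrix of phase codes (`NA` where the parent is
#'   homozygous), with attribute `rf` holding the running per-interval
#'   estimates.
#' @export
infer_phases <- function(dataset, mode = "global_error",
                         global_error = 1e-5, polish = TRUE) {
  M <- nrow(dataset$markers)
  N <- n_progeny(dataset)
  phases <- matrix(NA_integer_, M, 2L, dimnames = list(NULL, c("p1", "p2")))
  if (any(dataset$markers$type == "NONINF"))
    stop("remove non-informative markers before phase inference")
  priors <- create_priors(dataset, mode, global_error)
  het1 <- is_het(dataset$markers$p1)
  het2 <- is_het(dataset$markers$p2)
  if (M == 1L) {
    phases[1, 1] <- if (het1[1]) 0L else NA_integer_
    phases[1, 2] <- if (het2[1]) 0L else NA_integer_
    return(phases)
  }
  seen1 <- FALSE; seen2 <- FALSE
  rf <- numeric(M - 1L)
  emis <- function(m, ph1, ph2) {
    cls <- state_classes(dataset$markers$p1[m], dataset$markers$p2[m],
                         ph1, ph2)
    pr <- priors[[m]]
    pm <- pr[cls, , drop = FALSE]
    uni <- abs(apply(pr, 2, max) - apply(pr, 2, min)) < 1e-12
    pm[, uni] <- 1
    pm
  }
  # first marker: gauge 0 for whichever parents are heterozygous here
  phases[1, 1] <- if (het1[1]) { seen1 <- TRUE; 0L } else NA_integer_
  phases[1, 2] <- if (het2[1]) { seen2 <- TRUE; 0L } else NA_integer_
  a <- emis(1, phases[1, 1], phases[1, 2]) * 0.25
  ll <- log(colSums(a))
  a <- sweep(a, 2, colSums(a), "/")
  for (m in 2:M) {
    cand1 <- if (!het1[m]) NA_integer_ else if (!seen1) 0L else c(0L, 1L)
    cand2 <- if (!het2[m]) NA_integer_ else if (!seen2) 0L else c(0L, 1L)
    grid <- expand.grid(p1 = cand1, p2 = cand2, KEEP.OUT.ATTRS = FALSE)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      e <- emis(m, grid$p1[g], grid$p2[g])
      opt <- optimize(function(r) {
        sum(log(colSums((transition_matrix(r) %*% a) * e)))
      }, interval = c(1e-8, 0.5 - 1e-8), maximum = TRUE, tol = 1e-6)
      if (is.null(best) || opt$objective > best$obj + 1e-9)
        best <- list(obj = opt$objective, r = opt$maximum, g = g, e = e)
    }
    phases[m, 1] <- grid$p1[best$g]
    phases[m, 2] <- grid$p2[best$g]
    rf[m - 1L] <- best$r
    if (het1[m]) seen1 <- TRUE
    if (het2[m]) seen2 <- TRUE
    a <- (transition_matrix(best$r) %*% a) * best$e
    cs <- colSums(a)
    if (any(cs <= 0)) stop("zero-probability prefix at marker ", m)
    a <- sweep(a, 2, cs, "/")
  }
  attr(phases, "rf") <- rf
  if (polish)
    phases <- polish_phases(dataset, phases, priors, mode, global_error)
  phases
}

# Full-likelihood phase refinement: iteratively fit the map by EM, score
# every marker's feasible phase flips by the exact log-likelihood change
# (single-site emission swap against cached predicted-forward and
# backward variables), and apply improving flips until stable.
polish_phases <- function(dataset, phases, priors, mode, global_error,
                          max_rounds = 4L) {
  M <- nrow(dataset$markers)
  N <- n_progeny(dataset)
  rf <- attr(phases, "rf")
  for (round in seq_len(max_rounds)) {
    fit <- estimate_map(dataset, phases, mode, global_error,
                        rf_init = rf, max_iter = 40L, tol = 1e-4)
    rf <- fit$rf
    E <- emission_array(dataset, phases, priors)
    Ts <- lapply(rf, transition_matrix)
    # predicted forward (before emission) and scaled backward variables
    pre <- array(NA_real_, c(4L, N, M))
    alpha <- matrix(NA_real_, 4L, N)
    cs <- matrix(NA_real_, M, N)
    for (m in seq_len(M)) {
      p <- if (m == 1L) matrix(0.25, 4L, N) else Ts[[m - 1L]] %*% alpha
      pre[, , m] <- p
      a <- p * matrix(E[, , m], 4L, N)
      cs[m, ] <- colSums(a)
      alpha <- sweep(a, 2, cs[m, ], "/")
    }
    beta <- array(NA_real_, c(4L, N, M))
    b <- matrix(1, 4L, N)
    beta[, , M] <- b
    if (M > 1L) for (m in (M - 1L):1L) {
      eb <- matrix(E[, , m + 1L], 4L, N) * b
      b <- Ts[[m]] %*% sweep(eb, 2, cs[m + 1L, ], "/")
      beta[, , m] <- b
    }
    changed <- FALSE
    het1 <- is_het(dataset$markers$p1)
    het2 <- is_het(dataset$markers$p2)
    for (m in seq_len(M)) {
      flips <- list()
      if (het1[m]) flips <- c(flips, list(c(1L, 0L)))
      if (het2[m]) flips <- c(flips, list(c(0L, 1L)))
      if (het1[m] && het2[m]) flips <- c(flips, list(c(1L, 1L)))
      p0 <- matrix(pre[, , m], 4L, N)
      b0 <- matrix(beta[, , m], 4L, N)
      base <- colSums(p0 * matrix(E[, , m], 4L, N) * b0)
      best_delta <- 0; best_ph <- NULL
      for (f in flips) {
        ph1 <- if (f[1] == 1L) 1L - phases[m, 1] else phases[m, 1]
        ph2 <- if (f[2] == 1L) 1L - phases[m, 2] else phases[m, 2]
        cls <- state_classes(dataset$markers$p1[m], dataset$markers$p2[m],
                             ph1, ph2)
        pr <- priors[[m]]
        e2 <- pr[cls, , drop = FALSE]
        uni <- abs(apply(pr, 2, max) - apply(pr, 2, min)) < 1e-12
        e2[, uni] <- 1
        delta <- sum(log(colSums(p0 * e2 * b0))) - sum(log(base))
        if (delta > best_delta + 1e-6) {
          best_delta <- delta; best_ph <- c(ph1, ph2)
        }
      }
      if (!is.null(best_ph)) {
        phases[m, ] <- best_ph
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(phases, "rf") <- rf
  phases
}

#' Two-point recombination fraction between a pair of markers
#'
#' Estimates `r` for every compatible phase combination of the pair via
#' the two-marker EM and returns the maximum-likelihood combination;
#' `LOD = (loglik(r_hat) - loglik(0.5)) / ln 10`. A D1.10 x D2.15 pair
#' shares no informative parent, carries no linkage information, and is
#' returned flagged with `r = 0.5`, `LOD = 0`.
#'
#' @param i,j marker indices in `dataset`.
#' @inheritParams estimate_map
#' @return list with `rf`, `lod`, `phase` (the second marker's codes),
#'   and `flag` (`NULL` or `"unlinked-types"`).
#' @export
estimate_rf_pair <- function(i, j, dataset, mode = "global_error",
                             global_error = 1e-5) {
  sub <- subset_markers(dataset, c(i, j))
  het1 <- is_het(sub$markers$p1)
  het2 <- is_het(sub$markers$p2)
  if (!any(het1[1] & het1[2], het2[1] & het2[2]))
    return(list(rf = 0.5, lod = 0, phase = c(NA_integer_, NA_integer_),
                flag = "unlinked-types"))
  priors <- create_priors(sub, mode, global_error)
  ph1 <- c(if (het1[1]) 0L else NA_integer_, if (het2[1]) 0L else NA_integer_)
  cand1 <- if (het1[2] && het1[1]) c(0L, 1L) else if (het1[2]) 0L else NA_integer_
  cand2 <- if (het2[2] && het2[1]) c(0L, 1L) else if (het2[2]) 0L else NA_integer_
  grid <- expand.grid(p1 = cand1, p2 = cand2, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    phases <- rbind(ph1, c(grid$p1[g], grid$p2[g]))
    fit <- estimate_map(sub, phases, mode, global_error, rf_init = 0.25)
    if (is.null(best) || fit$loglik > best$fit$loglik + 1e-9)
      best <- list(fit = fit, g = g)
  }
  E <- emission_array(sub, best$fit$phases,
                      create_priors(sub, mode, global_error))
  ll_null <- forward_backward(E, 0.5 - 1e-8)$loglik
  list(rf = best$fit$rf, lod = (best$fit$loglik - ll_null) / log(10),
       phase = c(grid$p1[best$g], grid$p2[best$g]), flag = NULL)
}

#' Pairwise recombination-fraction matrix
#'
#' Runs [estimate_rf_pair()] over all marker pairs. Quadratic in the
#' number of markers; intended for diagnostics on filtered sets.
#'
#' @inheritParams estimate_map
#' @return list of symmetric M x M matrices `rf` and `lod`, plus a
#'   logical matrix `unlinked` flagging pairs without a shared
#'   informative parent.
#' @export
rf_matrix <- function(dataset, mode = "global_error", global_error = 1e-5) {
  M <- nrow(dataset$markers)
  rf <- matrix(NA_real_, M, M, dimnames = list(dataset$markers$id,
                                               dataset$markers$id))
  lod <- rf
  unlinked <- matrix(FALSE, M, M, dimnames = dimnames(rf))
  for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
    est <- estimate_rf_pair(i, j, dataset, mode, global_error)
    rf[i, j] <- rf[j, i] <- est$rf
    lod[i, j] <- lod[j, i] <- est$lod
    unlinked[i, j] <- unlinked[j, i] <- identical(est$flag, "unlinked-types")
  }
  list(rf = rf, lod = lod, unlinked = unlinked)
}
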