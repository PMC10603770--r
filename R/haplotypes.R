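#' Decode progeny haplotypes by the Viterbi algorithm
#'
#' For each progeny the most probable joint path over the four hidden
#' states is computed (Viterbi, log space). Decoding a single consistent
#' path -- rather than taking per-locus posterior argmaxes -- guarantees
#' that adjacent-state changes can be counted as recombination
#' breakpoints.
#'
#' @param map a `linkage_map` from [estimate_map()].
#' @return object of class `progeny_haplotypes`: list with `origin_p1`
#'   and `origin_p2` (M x N matrices of transmitted homolog, 1 or 2) and
#'   `breakpoints` (N x 2 matrix of per-parent breakpoint counts).
#' @export
decode_haplotypes <- function(map) {
  dataset <- map$dataset
  priors <- create_priors(dataset, map$mode, map$global_error)
  E <- emission_array(dataset, map$phases, priors)
  M <- dim(E)[3]; N <- dim(E)[2]
  logT <- lapply(map$rf, function(r) log(transition_matrix(r)))
  logE <- log(pmax(E, 1e-300))
  delta <- matrix(log(0.25), 4L, N) + matrix(logE[, , 1], 4L, N)
  psi <- array(NA_integer_, c(4L, N, M))
  for (m in 2:M) {
    newdelta <- matrix(NA_real_, 4L, N)
    for (s in 1:4) {
      scores <- delta + logT[[m - 1]][, s]       # 4 x N
      idx <- max.col(t(scores), ties.method = "first")
      psi[s, , m] <- idx
      newdelta[s, ] <- scores[cbind(idx, seq_len(N))] + logE[s, , m]
    }
    delta <- newdelta
  }
  path <- matrix(NA_integer_, M, N)
  path[M, ] <- max.col(t(delta), ties.method = "first")
  for (m in (M - 1L):1L)
    path[m, ] <- psi[cbind(path[m + 1L, ], seq_len(N), m + 1L)]
  origin_p1 <- matrix(STATE_I[path], M, N,
                      dimnames = list(dataset$markers$id, colnames(dataset$geno)))
  origin_p2 <- matrix(STATE_J[path], M, N, dimnames = dimnames(origin_p1))
  bp <- cbind(p1 = count_switches(origin_p1), p2 = count_switches(origin_p2))
  rownames(bp) <- colnames(dataset$geno)
  structure(list(origin_p1 = origin_p1, origin_p2 = origin_p2,
                 breakpoints = bp, marker_ids = dataset$markers$id),
            class = "progeny_haplotypes")
}

count_switches <- function(origin) {
  colSums(origin[-1L, , drop = FALSE] != origin[-nrow(origin), , drop = FALSE])
}

#' @export
print.progeny_haplotypes <- function(x, ...) {
  cat("progeny_haplotypes:", nrow(x$origin_p1), "markers x",
      ncol(x$origin_p1), "progeny; mean breakpoints/parent:",
      sprintf("%.2f", mean(x$breakpoints)), "\n")
  invisible(x)
}

#' Compare decoded and true breakpoint counts
#'
#' Per progeny and per parental haplotype, only the *number* of
#' breakpoints is compared, not their positions: with estimated count
#' `b_hat` and true count `b`, `max(b_hat - b, 0)` recombination events
#' are overestimated and `max(b - b_hat, 0)` underestimated. A haplotype
#' simulated with 1 break but decoded with 0 therefore counts as 1
#' underestimated break.
#'
#' @param decoded a `progeny_haplotypes` object.
#' @param truth a `sim_truth` object (see [simulate_progeny()]), or any
#'   list with an N x 2 `breakpoints` matrix.
#' @return list with totals `overestimated` and `underestimated` and the
#'   per-haplotype count matrices `est` and `true`.
#' @export
count_breakpoint_errors <- function(decoded, truth) {
  bt <- true_breakpoints(truth, decoded$marker_ids)
  be <- decoded$breakpoints
  if (!all(dim(be) == dim(bt)))
    stop("decoded and true haplotype sets have mismatched dimensions")
  over <- pmax(be - bt, 0)
  under <- pmax(bt - be, 0)
  list(overestimated = sum(over), underestimated = sum(under),
       est = be, true = bt)
}

# true per-parent breakpoint counts, restricted to a marker subset
true_breakpoints <- function(truth, marker_ids = NULL) {
  if (!is.null(truth$breakpoints) && is.null(marker_ids))
    return(truth$breakpoints)
  o1 <- truth$origin_p1; o2 <- truth$origin_p2
  if (!is.null(marker_ids)) {
    keep <- match(marker_ids, rownames(o1))
    if (anyNA(keep)) stop("marker ids absent from the simulated truth")
    o1 <- o1[keep, , drop = FALSE]
    o2 <- o2[keep, , drop = FALSE]
  }
  cbind(p1 = count_switches(o1), p2 = count_switches(o2))
}
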