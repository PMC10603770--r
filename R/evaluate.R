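#' Summary statistics of a linkage map
#'
#' Reports the marker count and per-type composition, the total genetic
#' length, the largest inter-marker gap, the number of gaps above
#' `gap_threshold` and the outlier markers -- internal markers whose
#' flanking intervals both exceed the threshold, the typical signature
#' of a single misplaced or error-ridden marker.
#'
#' @param map a `linkage_map`.
#' @param gap_threshold gap size in cM considered problematic
#'   (default 10).
#' @return list of class `map_summary`.
#' @export
map_summary <- function(map, gap_threshold = 10) {
  gaps <- diff(map$cumulative_cm)
  M <- nrow(map$markers)
  outlier <- logical(M)
  if (M > 2L)
    outlier[2:(M - 1L)] <- gaps[1:(M - 2L)] > gap_threshold &
      gaps[2:(M - 1L)] > gap_threshold
  structure(list(
    n_markers = M,
    type_counts = table(map$markers$type),
    total_cm = max(map$cumulative_cm),
    max_gap_cm = max(gaps),
    n_gaps_over = sum(gaps > gap_threshold),
    gap_threshold = gap_threshold,
    outlier_markers = map$markers$id[outlier]), class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("map_summary: %d markers, %.2f cM, max gap %.2f cM, %d gaps > %g cM, %d outliers\n",
              x$n_markers, x$total_cm, x$max_gap_cm, x$n_gaps_over,
              x$gap_threshold, length(x$outlier_markers)))
  invisible(x)
}

# cumulative positions (named by marker id) from a linkage_map, a
# sim_truth, or a ready-made named numeric vector
cumulative_positions <- function(x) {
  if (inherits(x, "linkage_map"))
    return(setNames(x$cumulative_cm, x$markers$id))
  if (inherits(x, "sim_truth"))
    return(setNames(x$cum_cm, x$markers$id))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot extract cumulative positions from this object")
}

#' Euclidean distance between two genetic maps
#'
#' Both maps are restricted to their shared markers and re-zeroed at the
#' first shared marker, then
#' `D = sqrt(sum_i (chat_i - c_i)^2)` over the cumulative positions.
#' `D <= 1` is the regime of maps whose size is not inflated; `D = 0`
#' iff the maps agree exactly on the shared markers.
#'
#' @param est,truth `linkage_map`/`sim_truth` objects or named numeric
#'   vectors of cumulative cM positions.
#' @return the distance (cM scale).
#' @export
euclidean_map_distance <- function(est, truth) {
  a <- cumulative_positions(est)
  b <- cumulative_positions(truth)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 2L)
    stop("need at least 2 shared markers to compare maps")
  a <- a[shared]; b <- b[shared]
  a <- a - a[1]; b <- b - b[1]
  sqrt(sum((a - b)^2))
}

#' Breakpoint accounting between decoded and simulated haplotypes
#'
#' Wraps [count_breakpoint_errors()]: `wrong = overestimated +
#' underestimated`, with a per-progeny table to expose outlier
#' individuals (e.g. contaminants, which accumulate spurious breaks).
#'
#' @inheritParams count_breakpoint_errors
#' @return list with `overestimated`, `underestimated`, `wrong` and the
#'   `per_progeny` data.frame.
#' @export
breakpoint_error_summary <- function(decoded, truth) {
  cnt <- count_breakpoint_errors(decoded, truth)
  over_i <- rowSums(pmax(cnt$est - cnt$true, 0))
  under_i <- rowSums(pmax(cnt$true - cnt$est, 0))
  list(overestimated = cnt$overestimated,
       underestimated = cnt$underestimated,
       wrong = cnt$overestimated + cnt$underestimated,
       per_progeny = data.frame(progeny = rownames(cnt$est),
                                est_p1 = cnt$est[, 1], est_p2 = cnt$est[, 2],
                                true_p1 = cnt$true[, 1], true_p2 = cnt$true[, 2],
                                overestimated = over_i,
                                underestimated = under_i,
                                row.names = NULL))
}

#' Absolute Spearman correlation between two marker orders
#'
#' @param order_a,order_b character vectors giving the same marker set
#'   in two orders.
#' @return `|rho|`; 1 for identical or exactly reversed orders.
#' @export
order_correlation <- function(order_a, order_b) {
  if (length(order_a) != length(order_b) ||
      !setequal(order_a, order_b) ||
      anyDuplicated(order_a) || anyDuplicated(order_b))
    stop("orders must be permutations of the same marker set")
  abs(cor(seq_along(order_a), match(order_b, order_a),
          method = "spearman"))
}
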