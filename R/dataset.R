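#' Construct a marker dataset for a full-sib F1 family
#'
#' The container holding everything downstream steps need: marker
#' definitions (position, cross type, parental calls), the progeny
#' genotype-call matrix, and the optional sequencing evidence (allele
#' depths, total depth, GQ-derived error probabilities, PL-derived class
#' probabilities). Markers are kept sorted by `(chrom, pos_bp)`;
#' genotype classes are canonical strings (see [canonical_geno()]).
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos_bp`, `p1`,
#'   `p2` (parental canonical genotypes, `NA` allowed) and optionally
#'   `type` (recomputed when absent).
#' @param geno M x N character matrix of progeny genotype classes
#'   (`NA` = missing), rows matching `markers`.
#' @param ad_ref,ad_alt,dp optional M x N integer matrices of reference /
#'   alternate allele depths and total depth (`NA` = missing).
#' @param gq_error optional M x N numeric matrix of per-genotype error
#'   probabilities (`10^(-GQ/10)`).
#' @param class_probs optional M x N x 3 array of genotype-class
#'   probabilities over `aa`, `ab`, `bb` (reference-coded biallelic).
#' @param parent_ids character vector of length 2.
#' @param parent_ad_ref,parent_ad_alt,parent_dp,parent_gq_error optional
#'   M x 2 matrices with the parental sequencing evidence.
#' @return an object of class `marker_dataset`.
#' @export
marker_dataset <- function(markers, geno,
                           ad_ref = NULL, ad_alt = NULL, dp = NULL,
                           gq_error = NULL, class_probs = NULL,
                           parent_ids = c("P1", "P2"),
                           parent_ad_ref = NULL, parent_ad_alt = NULL,
                           parent_dp = NULL, parent_gq_error = NULL) {
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos_bp", "p1", "p2") %in% names(markers)),
            is.matrix(geno), nrow(geno) == nrow(markers),
            length(parent_ids) == 2L)
  if (ncol(geno) < 2L) stop("a full-sib family needs at least 2 progeny")
  ord <- order(markers$chrom, markers$pos_bp)
  if (is.null(markers$type)) {
    markers$type <- vapply(seq_len(nrow(markers)), function(i)
      classify_marker_type(markers$p1[i], markers$p2[i]), character(1))
  }
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("I", seq_len(ncol(geno)))
  reindex <- function(x) if (is.null(x)) NULL else
    if (length(dim(x)) == 3L) x[ord, , , drop = FALSE] else x[ord, , drop = FALSE]
  obj <- structure(list(
    markers = markers[ord, , drop = FALSE],
    geno = geno[ord, , drop = FALSE],
    ad_ref = reindex(ad_ref), ad_alt = reindex(ad_alt), dp = reindex(dp),
    gq_error = reindex(gq_error), class_probs = reindex(class_probs),
    parent_ids = parent_ids,
    parent_ad_ref = reindex(parent_ad_ref),
    parent_ad_alt = reindex(parent_ad_alt),
    parent_dp = reindex(parent_dp),
    parent_gq_error = reindex(parent_gq_error)
  ), class = "marker_dataset")
  rownames(obj$markers) <- NULL
  dup <- duplicated(obj$markers[, c("chrom", "pos_bp")])
  if (any(dup))
    attr(obj, "duplicated_positions") <- obj$markers$id[dup]
  obj
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat("marker_dataset:", nrow(x$markers), "markers x",
      ncol(x$geno), "progeny (parents:",
      paste(x$parent_ids, collapse = ", "), ")\n")
  print(table(x$markers$type))
  invisible(x)
}

#' @export
dim.marker_dataset <- function(x) c(nrow(x$markers), ncol(x$geno))

#' Subset a marker dataset by marker index
#'
#' @param dataset a [marker_dataset()].
#' @param keep integer or logical index over markers.
#' @return the restricted `marker_dataset`.
#' @export
subset_markers <- function(dataset, keep) {
  sub <- function(x) if (is.null(x)) NULL else
    if (length(dim(x)) == 3L) x[keep, , , drop = FALSE] else x[keep, , drop = FALSE]
  out <- dataset
  out$markers <- dataset$markers[keep, , drop = FALSE]
  rownames(out$markers) <- NULL
  for (f in c("geno", "ad_ref", "ad_alt", "dp", "gq_error", "class_probs",
              "parent_ad_ref", "parent_ad_alt", "parent_dp",
              "parent_gq_error"))
    out[[f]] <- sub(dataset[[f]])
  out
}

#' Subset a marker dataset by progeny index
#'
#' @inheritParams subset_markers
#' @param keep integer or logical index over progeny columns.
#' @return the restricted `marker_dataset`.
#' @export
subset_progeny <- function(dataset, keep) {
  out <- dataset
  for (f in c("geno", "ad_ref", "ad_alt", "dp", "gq_error"))
    if (!is.null(dataset[[f]])) out[[f]] <- dataset[[f]][, keep, drop = FALSE]
  if (!is.null(dataset$class_probs))
    out$class_probs <- dataset$class_probs[, keep, , drop = FALSE]
  out
}

n_progeny <- function(dataset) ncol(dataset$geno)

informative_markers <- function(dataset) which(dataset$markers$type != "NONINF")
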