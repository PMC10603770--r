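#' Genotype-class prior for one observation
#'
#' Converts a genotype observation into a probability vector over the
#' marker's observable genotype classes; these vectors are the HMM
#' emission parameters, so the error model chosen here is how genotyping
#' uncertainty enters distance estimation. Four modes are supported:
#'
#' * `global_error`: the called class receives `1 - e`, the remaining
#'   `k - 1` classes share `e` uniformly;
#' * `genotype_error`: as above with the observation's own error
#'   probability (e.g. `10^(-GQ/10)`) in place of the global value;
#' * `genotype_probs`: caller-reported class probabilities restricted to
#'   the observable classes and renormalized;
#' * `probs_plus_global`: the per-genotype error (1 minus the maximum
#'   renormalized class probability) is first combined with the global
#'   value via [combine_errors()], then distributed as in `global_error`.
#'
#' A missing observation, or a call outside the observable classes,
#' yields the uniform vector `1/k`.
#'
#' @param call canonical genotype string or `NA`.
#' @param classes observable genotype classes (see [marker_classes()]).
#' @param mode one of `"global_error"`, `"genotype_error"`,
#'   `"genotype_probs"`, `"probs_plus_global"`.
#' @param global_error global error probability (default `1e-5`, the
#'   historical default of HMM-based mapping software; raise it for
#'   low-depth sequencing data).
#' @param gq_error per-genotype error probability (for `genotype_error`);
#'   when `NA`, `global_error` is used as fallback.
#' @param class_probs named probabilities over `aa`/`ab`/`bb` (or over
#'   `classes`) for the probability modes; `NA`/`NULL` falls back to the
#'   call with `global_error`.
#' @return numeric vector over `classes`, summing to 1.
#' @examples
#' genotype_prior("ab", c("aa", "ab", "bb"), "global_error",
#'                global_error = 0.05)  # 0.025 0.950 0.025
#' @export
genotype_prior <- function(call, classes,
                           mode = c("global_error", "genotype_error",
                                    "genotype_probs", "probs_plus_global"),
                           global_error = 1e-5, gq_error = NA_real_,
                           class_probs = NULL) {
  mode <- match.arg(mode)
  k <- length(classes)
  if (k < 1L) stop("marker has no observable classes (non-informative?)")
  uniform <- rep(1 / k, k)
  names(uniform) <- classes

  probs <- NULL
  if (mode %in% c("genotype_probs", "probs_plus_global") &&
      !is.null(class_probs) && !all(is.na(class_probs))) {
    p <- class_probs[match(classes, names(class_probs))]
    p[is.na(p)] <- 0
    if (sum(p) > 0) probs <- p / sum(p)
  }

  if (mode == "genotype_probs") {
    if (!is.null(probs)) return(setNames(as.numeric(probs), classes))
    # no caller probabilities: fall back to the call under the global rate
    mode <- "global_error"
  }

  if (mode == "probs_plus_global") {
    if (!is.null(probs)) {
      called <- classes[which.max(probs)]
      e <- combine_errors(global_error, 1 - max(probs))
      return(spread_error(called, classes, e))
    }
    if (!is.na(gq_error))
      return(spread_error_call(call, classes,
                               combine_errors(global_error, gq_error),
                               uniform))
    mode <- "global_error"
  }

  e <- if (mode == "genotype_error" && !is.na(gq_error)) gq_error
       else global_error
  spread_error_call(call, classes, e, uniform)
}

spread_error_call <- function(call, classes, e, uniform) {
  if (is.na(call) || !(call %in% classes)) return(uniform)
  spread_error(call, classes, e)
}

spread_error <- function(called, classes, e) {
  k <- length(classes)
  if (k == 1L) return(setNames(1, classes))
  out <- rep(e / (k - 1), k)
  out[classes == called] <- 1 - e
  setNames(out, classes)
}

#' Build genotype-class priors for every observation in a dataset
#'
#' Applies [genotype_prior()] marker by marker; non-informative markers
#' get a `NULL` entry.
#'
#' @param dataset a [marker_dataset()].
#' @inheritParams genotype_prior
#' @return list of length M; each informative entry is a `k x N` matrix
#'   (classes x progeny) with columns summing to 1.
#' @export
create_priors <- function(dataset,
                          mode = c("global_error", "genotype_error",
                                   "genotype_probs", "probs_plus_global"),
                          global_error = 1e-5) {
  mode <- match.arg(mode)
  M <- nrow(dataset$markers)
  N <- n_progeny(dataset)
  lapply(seq_len(M), function(m) {
    if (dataset$markers$type[m] == "NONINF") return(NULL)
    mc <- marker_classes(dataset$markers$p1[m], dataset$markers$p2[m])
    out <- matrix(NA_real_, length(mc$classes), N,
                  dimnames = list(mc$classes, colnames(dataset$geno)))
    for (n in seq_len(N)) {
      cp <- if (!is.null(dataset$class_probs))
        setNames(dataset$class_probs[m, n, ], dimnames(dataset$class_probs)[[3]])
      else NULL
      ge <- if (!is.null(dataset$gq_error)) dataset$gq_error[m, n] else NA_real_
      out[, n] <- genotype_prior(dataset$geno[m, n], mc$classes, mode,
                                 global_error = global_error,
                                 gq_error = ge, class_probs = cp)
    }
    out
  })
}
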