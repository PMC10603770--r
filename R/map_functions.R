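#' Map functions: recombination fraction to genetic distance
#'
#' Haldane's function assumes crossovers occur without interference
#' (`d = -50 ln(1 - 2r)`); Kosambi's accounts for positive interference
#' (`d = 25 ln((1 + 2r) / (1 - 2r))`). Distances are in centimorgans.
#' For every `r` in (0, 0.5), `kosambi(r) <= haldane(r)`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param method `"haldane"` or `"kosambi"`.
#' @return genetic distance(s) in cM.
#' @examples
#' map_function(0.25, "haldane")  # 34.657
#' map_function(0.25, "kosambi")  # 27.465
#' @export
map_function <- function(r, method = c("haldane", "kosambi")) {
  method <- match.arg(method)
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must lie in [0, 0.5)")
  switch(method,
         haldane = -50 * log(1 - 2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Inverse map functions: genetic distance to recombination fraction
#'
#' Exact closed-form inverses of [map_function()]; the round trip
#' `r -> d -> r` is the identity to numerical precision.
#'
#' @param d genetic distance(s) in cM, `>= 0`.
#' @inheritParams map_function
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
inverse_map_function <- function(d, method = c("haldane", "kosambi")) {
  method <- match.arg(method)
  if (any(d < 0, na.rm = TRUE)) stop("genetic distance must be non-negative")
  switch(method,
         haldane = (1 - exp(-d / 50)) / 2,
         kosambi = tanh(d / 50) / 2)
}

#' Combine a global error rate with a per-genotype error probability
#'
#' Treats the two error sources as independent on the complement scale:
#' the genotype is correct only if neither source corrupted it, so the
#' combined error is `1 - (1 - e_global) * (1 - e_soft)`.
#'
#' @param e_global global error probability in `[0, 1]`.
#' @param e_soft per-genotype (software-reported) error probability.
#' @return combined error probability.
#' @examples
#' combine_errors(0.05, 0.1)  # 0.145
#' @export
combine_errors <- function(e_global, e_soft) {
  if (any(e_global < 0 | e_global > 1 | e_soft < 0 | e_soft > 1, na.rm = TRUE))
    stop("error probabilities must lie in [0, 1]")
  1 - (1 - e_global) * (1 - e_soft)
}
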