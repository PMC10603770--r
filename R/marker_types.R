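#' Marker types for a diploid full-sib F1 cross
#'
#' In an outcrossing F1 family up to four parental haplotypes segregate,
#' and the information a marker carries depends on the parental genotype
#' configuration. The supported codes are the configurations observable
#' from codominant markers without null alleles:
#'
#' * `A.1` -- `ab x cd`, progeny classes `ac, ad, bc, bd`, 1:1:1:1;
#' * `A.2` -- `ab x ac`, progeny classes `aa, ab, ac, bc`, 1:1:1:1;
#' * `B3.7` -- `ab x ab`, progeny classes `aa, ab, bb`, 1:2:1;
#' * `D1.10` -- `ab x aa`, classes `aa, ab`, 1:1 (informative for P1 only);
#' * `D2.15` -- `aa x ab`, classes `aa, ab`, 1:1 (informative for P2 only);
#' * `NONINF` -- both parents homozygous, or a parental call missing:
#'   no segregation information.
#'
#' Configurations that require null alleles or dominance, and the
#' `ab x cc` / `cc x ab` forms (which cannot occur for biallelic SNPs),
#' are outside the supported set and are classified `NONINF`.
#'
#' @name marker_types
NULL

SUPPORTED_TYPES <- c("A.1", "A.2", "B3.7", "D1.10", "D2.15", "NONINF")

#' Canonical genotype string from two alleles
#'
#' Genotypes are unordered allele pairs; the canonical form sorts the two
#' single-character allele codes, so `"ba"` and `"ab"` are the same class.
#'
#' @param a1,a2 single-character allele codes (vectorised).
#' @return character vector of canonical two-letter genotype strings.
#' @keywords internal
canonical_geno <- function(a1, a2) {
  ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
}

geno_alleles <- function(g) strsplit(g, "")

is_het <- function(g) {
  !is.na(g) & substr(g, 1L, 1L) != substr(g, 2L, 2L)
}

#' Classify the cross type of a marker from its parental genotypes
#'
#' @param p1_call,p2_call canonical genotype strings (e.g. `"ab"`, `"aa"`)
#'   or `NA` for a missing parental call.
#' @param n_alleles number of distinct alleles observed at the locus
#'   (default: counted from the parental calls). More than 4 is an error.
#' @return one of `r paste(SUPPORTED_TYPES, collapse = ", ")`.
#' @examples
#' classify_marker_type("ab", "ab")  # B3.7
#' classify_marker_type("ab", "aa")  # D1.10
#' classify_marker_type("aa", "ab")  # D2.15
#' classify_marker_type("aa", "aa")  # NONINF
#' @export
classify_marker_type <- function(p1_call, p2_call, n_alleles = NULL) {
  if (is.na(p1_call) || is.na(p2_call)) return("NONINF")
  a1 <- geno_alleles(p1_call)[[1]]
  a2 <- geno_alleles(p2_call)[[1]]
  all_alleles <- unique(c(a1, a2))
  if (!is.null(n_alleles) && n_alleles > 4L || length(all_alleles) > 4L)
    stop("more than 4 distinct alleles at a locus is not a valid diploid cross")
  h1 <- a1[1] != a1[2]
  h2 <- a2[1] != a2[2]
  if (!h1 && !h2) return("NONINF")
  if (h1 && h2) {
    shared <- length(intersect(a1, a2))
    if (shared == 2L) return("B3.7")
    if (shared == 1L) return("A.2")
    return("A.1")
  }
  if (h1) {
    # ab x cc (D1.9) needs a third allele and is unsupported
    if (a2[1] %in% a1) return("D1.10") else return("NONINF")
  }
  if (a1[1] %in% a2) "D2.15" else "NONINF"
}

#' Parental homolog alleles under a phase code
#'
#' Phase code 0 places the alphabetically first allele of a heterozygous
#' parent on homolog 1; code 1 swaps the homologs. Homozygous parents
#' carry the same allele on both homologs and take a null (`NA`) code.
#'
#' @param call canonical genotype string of the parent.
#' @param phase 0, 1 or `NA`.
#' @return character vector of length 2: allele on homolog 1 and 2.
#' @keywords internal
parent_homologs <- function(call, phase) {
  al <- geno_alleles(call)[[1]]
  if (al[1] == al[2]) return(al)
  if (is.na(phase)) stop("heterozygous parent requires a 0/1 phase code")
  if (phase == 0) al else rev(al)
}

#' Genotype class produced by each hidden state
#'
#' Hidden states are ordered `(1,1), (1,2), (2,1), (2,2)` where the first
#' index is the P1 homolog transmitted and the second the P2 homolog.
#'
#' @param p1_call,p2_call parental genotype strings.
#' @param phase1,phase2 phase codes (see [parent_homologs()]).
#' @return character vector of length 4 with the genotype class each state
#'   emits.
#' @keywords internal
state_classes <- function(p1_call, p2_call, phase1 = 0, phase2 = 0) {
  h1 <- parent_homologs(p1_call, phase1)
  h2 <- parent_homologs(p2_call, phase2)
  i <- c(1L, 1L, 2L, 2L)
  j <- c(1L, 2L, 1L, 2L)
  canonical_geno(h1[i], h2[j])
}

#' Observable genotype classes and expected segregation of a marker
#'
#' The class set and expected Mendelian ratio follow from the four equally
#' likely homolog-transmission combinations, e.g. `ab x ab` yields
#' `aa : ab : bb = 1 : 2 : 1` and `ab x aa` yields `aa : ab = 1 : 1`.
#' The result does not depend on the (unknown) linkage phase.
#'
#' @inheritParams state_classes
#' @return list with `classes` (sorted character vector) and `ratio`
#'   (expected class probabilities, same order).
#' @export
marker_classes <- function(p1_call, p2_call) {
  if (is.na(p1_call) || is.na(p2_call))
    stop("marker_classes undefined for missing parental calls")
  cls <- state_classes(p1_call, p2_call,
                       phase1 = if (is_het(p1_call)) 0 else NA,
                       phase2 = if (is_het(p2_call)) 0 else NA)
  tab <- table(cls) / 4
  list(classes = names(tab), ratio = as.numeric(tab))
}
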