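#' Simulation configuration for a GBS-genotyped F1 family
#'
#' Defaults emulate the reference chromosome segment used throughout the
#' package's validation: 810 SNP markers spanning 38 cM / 8.426 Mb with
#' marker-type proportions 126 B3.7 : 263 D1.10 : 278 D2.15 : 143
#' non-informative, a family of 200 progeny, mean progeny depth 10 with
#' parents sequenced 8x deeper, and meiosis without crossover
#' interference. The optional segregation-distortion block oversamples
#' the family 50-fold, eliminates 50% of the carriers of one allele at
#' the 30th marker and samples 200 survivors.
#'
#' @param n_markers number of markers.
#' @param type_proportions named non-negative weights over marker types
#'   (any of `B3.7`, `D1.10`, `D2.15`, `A.1`, `A.2`, `NONINF`);
#'   normalized internally.
#' @param total_cm total genetic length of the simulated segment (cM).
#' @param chrom_len_bp physical span in bp (markers equally spaced).
#' @param n_progeny family size.
#' @param mean_depth mean sequencing depth per progeny genotype.
#' @param parent_depth_multiplier parents' depth relative to progeny.
#' @param overdispersion depth/allele-ratio overdispersion `rho` in
#'   `[0, 1)`; 0 gives Poisson depths and binomial allele counts.
#' @param allelic_bias expected reference-allele fraction in
#'   heterozygotes (0.5 = unbiased).
#' @param seq_error per-read sequencing/miscall error probability.
#' @param distortion `NULL` or a list with `locus` (marker index),
#'   `intensity` (elimination probability for carriers), `oversample`
#'   (pool multiplier) -- see [apply_selection()].
#' @param anchors optional data.frame with `bp` and `cm` columns mapping
#'   physical to genetic positions via [interpolate_cm()]; by default
#'   the cM positions are uniformly spaced.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 810,
                       type_proportions = c(B3.7 = 126, D1.10 = 263,
                                            D2.15 = 278, NONINF = 143),
                       total_cm = 38, chrom_len_bp = 8426323,
                       n_progeny = 200, mean_depth = 10,
                       parent_depth_multiplier = 8,
                       overdispersion = 0.2, allelic_bias = 0.5,
                       seq_error = 0.001,
                       distortion = NULL, anchors = NULL) {
  stopifnot(n_markers >= 2, all(type_proportions >= 0),
            sum(type_proportions) > 0, total_cm > 0,
            n_progeny >= 2, mean_depth > 0, parent_depth_multiplier > 0,
            overdispersion >= 0, overdispersion < 1,
            allelic_bias > 0, allelic_bias < 1,
            seq_error >= 0, seq_error <= 1)
  bad <- setdiff(names(type_proportions), SUPPORTED_TYPES)
  if (length(bad)) stop("unsupported marker types: ", paste(bad, collapse = ", "))
  if (!is.null(distortion)) {
    distortion <- utils::modifyList(
      list(locus = 30L, intensity = 0.5, oversample = 50L), distortion)
    stopifnot(distortion$intensity >= 0, distortion$intensity <= 1,
              distortion$oversample >= 1)
  }
  structure(list(n_markers = n_markers,
                 type_proportions = type_proportions / sum(type_proportions),
                 total_cm = total_cm, chrom_len_bp = chrom_len_bp,
                 n_progeny = n_progeny, mean_depth = mean_depth,
                 parent_depth_multiplier = parent_depth_multiplier,
                 overdispersion = overdispersion,
                 allelic_bias = allelic_bias, seq_error = seq_error,
                 distortion = distortion, anchors = anchors),
            class = "sim_config")
}

#' Monotone interpolation of genetic positions from physical positions
#'
#' Hyman-filtered monotone cubic spline through `(bp, cM)` anchor pairs;
#' the interpolant is non-decreasing whenever the anchors are. Queries
#' outside the anchor range are extended linearly with the boundary
#' slope.
#'
#' @param query_bp physical positions to interpolate at.
#' @param anchor_bp,anchor_cm anchor coordinates, strictly increasing.
#' @return genetic positions (cM) at `query_bp`.
#' @export
interpolate_cm <- function(query_bp, anchor_bp, anchor_cm) {
  if (length(anchor_bp) < 2L || length(anchor_bp) != length(anchor_cm))
    stop("need at least 2 (bp, cM) anchor pairs")
  if (any(diff(anchor_bp) <= 0) || any(diff(anchor_cm) <= 0))
    stop("anchors must be strictly increasing in both coordinates")
  f <- splinefun(anchor_bp, anchor_cm, method = "hyman")
  lo <- anchor_bp[1]; hi <- anchor_bp[length(anchor_bp)]
  out <- f(pmin(pmax(query_bp, lo), hi))
  below <- query_bp < lo
  above <- query_bp > hi
  if (any(below))
    out[below] <- anchor_cm[1] + f(lo, deriv = 1) * (query_bp[below] - lo)
  if (any(above))
    out[above] <- anchor_cm[length(anchor_cm)] +
      f(hi, deriv = 1) * (query_bp[above] - hi)
  out
}

#' Simulate parental haplotypes and a true genetic map
#'
#' Draws a marker type for each locus from the configured proportions,
#' assigns parental genotypes accordingly (`B3.7` = ab x ab, `D1.10` =
#' ab x aa, `D2.15` = aa x ab, `A.1` = ab x cd, `A.2` = ab x ac;
#' non-informative markers draw from aa x aa, bb x bb, aa x bb), places
#' markers at equally spaced physical positions, and assigns each
#' heterozygous parent's linkage phase uniformly at random.
#'
#' @param config a [sim_config()].
#' @return list with `markers` (data.frame incl. true `cm` positions),
#'   `phases` (true M x 2 phase codes) and `rf` (true per-interval
#'   recombination fractions, Haldane).
#' @export
simulate_parents <- function(config) {
  M <- config$n_markers
  types <- sample(names(config$type_proportions), M, replace = TRUE,
                  prob = config$type_proportions)
  p1 <- character(M); p2 <- character(M)
  for (i in seq_len(M)) {
    g <- switch(types[i],
                B3.7 = c("ab", "ab"), D1.10 = c("ab", "aa"),
                D2.15 = c("aa", "ab"), A.1 = c("ab", "cd"),
                A.2 = c("ab", "ac"),
                NONINF = list(c("aa", "aa"), c("bb", "bb"),
                              c("aa", "bb"))[[sample.int(3L, 1L)]])
    p1[i] <- g[1]; p2[i] <- g[2]
  }
  pos_bp <- round(seq(1, config$chrom_len_bp, length.out = M))
  cm <- if (is.null(config$anchors))
    seq(0, config$total_cm, length.out = M)
  else interpolate_cm(pos_bp, config$anchors$bp, config$anchors$cm)
  phases <- cbind(p1 = ifelse(is_het(p1), rbinom(M, 1L, 0.5), NA_integer_),
                  p2 = ifelse(is_het(p2), rbinom(M, 1L, 0.5), NA_integer_))
  markers <- data.frame(id = sprintf("M%04d", seq_len(M)), chrom = "chr1",
                        pos_bp = pos_bp, type = types, p1 = p1, p2 = p2,
                        cm = cm, stringsAsFactors = FALSE)
  list(markers = markers, phases = phases,
       rf = inverse_map_function(diff(cm), "haldane"))
}

#' Simulate F1 meioses and progeny genotypes
#'
#' Each gamete is a Markov chain over homolog origin: the origin at the
#' first marker is uniform and switches between adjacent markers with
#' the interval's recombination fraction, independently for the two
#' parents (no crossover interference, matching the Haldane map
#' function). Progeny genotypes are the union of the transmitted
#' alleles.
#'
#' @param parents output of [simulate_parents()].
#' @param n number of progeny.
#' @return object of class `sim_truth`: the markers, true phases and
#'   map, `origin_p1`/`origin_p2` (M x n transmitted homolog),
#'   `geno` (M x n true genotype classes) and per-progeny true
#'   `breakpoints`.
#' @export
simulate_progeny <- function(parents, n) {
  M <- nrow(parents$markers)
  rf <- parents$rf
  origin <- function() {
    start <- sample(c(1L, 2L), n, replace = TRUE)
    switches <- matrix(rbinom((M - 1L) * n, 1L, rep(rf, n)), M - 1L, n)
    cum <- apply(switches, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, 1L, n)
    o <- rbind(start, sweep(cum, 2, start, "+"))
    matrix(1L + (o - 1L) %% 2L, M, n)
  }
  o1 <- origin(); o2 <- origin()
  h1 <- vapply(seq_len(M), function(m)
    parent_homologs(parents$markers$p1[m], parents$phases[m, 1]),
    character(2))
  h2 <- vapply(seq_len(M), function(m)
    parent_homologs(parents$markers$p2[m], parents$phases[m, 2]),
    character(2))
  a1 <- matrix(h1[cbind(as.vector(o1), rep(seq_len(M), n))], M, n)
  a2 <- matrix(h2[cbind(as.vector(o2), rep(seq_len(M), n))], M, n)
  geno <- matrix(canonical_geno(a1, a2), M, n)
  ids <- sprintf("F1_%03d", seq_len(n))
  dimnames(geno) <- list(parents$markers$id, ids)
  dimnames(o1) <- dimnames(o2) <- dimnames(geno)
  structure(list(markers = parents$markers, phases = parents$phases,
                 rf = rf, cum_cm = parents$markers$cm - parents$markers$cm[1],
                 origin_p1 = o1, origin_p2 = o2, geno = geno,
                 breakpoints = cbind(p1 = count_switches(o1),
                                     p2 = count_switches(o2)),
                 selection = NULL),
            class = "sim_truth")
}

#' Apply selection-driven segregation distortion to a progeny pool
#'
#' One allele carried by a heterozygous parent at the selected locus is
#' targeted; every individual whose genotype contains that allele is
#' eliminated independently with probability `intensity`, and `target_n`
#' survivors are then sampled without replacement. Bookkeeping on the
#' carriers and eliminations is stored in the `selection` element.
#'
#' @param pool a `sim_truth` whose family is larger than `target_n`
#'   (typically oversampled, e.g. 50 x 200).
#' @param locus marker index at which selection acts.
#' @param intensity elimination probability for carriers.
#' @param target_n final family size.
#' @return the distorted, down-sampled `sim_truth`.
#' @export
apply_selection <- function(pool, locus = 30L, intensity = 0.5,
                            target_n = 200L) {
  stopifnot(ncol(pool$geno) >= target_n)
  het_parent_alleles <- unique(unlist(geno_alleles(
    c(pool$markers$p1[locus], pool$markers$p2[locus])[
      is_het(c(pool$markers$p1[locus], pool$markers$p2[locus]))])))
  if (!length(het_parent_alleles))
    stop("selected locus is not informative (no heterozygous parent)")
  target <- het_parent_alleles[length(het_parent_alleles)]
  carriers <- grepl(target, pool$geno[locus, ], fixed = TRUE)
  eliminated <- carriers & (runif(ncol(pool$geno)) < intensity)
  survivors <- which(!eliminated)
  if (length(survivors) < target_n)
    stop("selection too strong: fewer survivors than the target size")
  keep <- sort(sample(survivors, target_n))
  out <- pool
  for (f in c("origin_p1", "origin_p2", "geno"))
    out[[f]] <- pool[[f]][, keep, drop = FALSE]
  out$breakpoints <- pool$breakpoints[keep, , drop = FALSE]
  out$selection <- list(locus = locus, target_allele = target,
                        intensity = intensity,
                        n_pool = ncol(pool$geno),
                        n_carriers = sum(carriers),
                        n_eliminated = sum(eliminated),
                        kept = keep)
  out
}

#' Simulate GBS allele depths for a family
#'
#' Total depth per genotype is negative binomial with mean `mean_depth`
#' (progeny) or `mean_depth * parent_depth_multiplier` (parents) and
#' overdispersion `rho` (`rho -> 0` recovers Poisson). For
#' heterozygotes the reference-allele count is beta-binomial with mean
#' `allelic_bias` and the same `rho`; homozygotes draw the wrong allele
#' with probability `seq_error` per read. Only biallelic (a/b) markers
#' can be depth-simulated.
#'
#' @param truth a `sim_truth`.
#' @param config the [sim_config()] used to generate it.
#' @return list with progeny matrices `ad_ref`, `ad_alt` and parental
#'   `parent_ad_ref`, `parent_ad_alt` (M x 2).
#' @export
simulate_depths <- function(truth, config) {
  if (any(truth$markers$type %in% c("A.1", "A.2")))
    stop("allele-depth simulation requires biallelic (a/b) markers")
  M <- nrow(truth$geno); N <- ncol(truth$geno)
  rho <- config$overdispersion
  rdepth <- function(n, mu) {
    if (rho == 0) rpois(n, mu) else rnbinom(n, size = 1 / rho, mu = mu)
  }
  rref <- function(geno, depth) {
    n <- length(depth)
    ref <- integer(n)
    het <- geno == "ab"
    if (any(het)) {
      p <- if (rho == 0) rep(config$allelic_bias, sum(het))
      else rbeta(sum(het), config$allelic_bias * (1 - rho) / rho,
                 (1 - config$allelic_bias) * (1 - rho) / rho)
      ref[het] <- rbinom(sum(het), depth[het], p)
    }
    aa <- geno == "aa"
    if (any(aa)) ref[aa] <- depth[aa] - rbinom(sum(aa), depth[aa], config$seq_error)
    bb <- geno == "bb"
    if (any(bb)) ref[bb] <- rbinom(sum(bb), depth[bb], config$seq_error)
    ref
  }
  dp <- matrix(rdepth(M * N, config$mean_depth), M, N)
  ref <- matrix(rref(as.vector(truth$geno), as.vector(dp)), M, N)
  dimnames(dp) <- dimnames(ref) <- dimnames(truth$geno)
  pgeno <- cbind(truth$markers$p1, truth$markers$p2)
  pdp <- matrix(rdepth(M * 2L, config$mean_depth * config$parent_depth_multiplier),
                M, 2L)
  pref <- matrix(rref(as.vector(pgeno), as.vector(pdp)), M, 2L)
  list(ad_ref = ref, ad_alt = dp - ref,
       parent_ad_ref = pref, parent_ad_alt = pdp - pref)
}

#' Naive maximum-likelihood genotype calls from allele counts
#'
#' Per observation, binomial likelihoods for the three biallelic classes
#' with reference-read probability `1 - e` (aa), `0.5` (ab) and `e`
#' (bb), a flat prior, `GT` as the posterior argmax, `PL` as the
#' min-rescaled Phred-scaled likelihoods and `GQ` from the maximum
#' posterior (capped at 99). Zero-depth observations are missing.
#'
#' @param ad_ref,ad_alt matrices of reference/alternate read counts.
#' @param seq_error per-read error probability used in the likelihoods.
#' @return list with `call` (canonical genotype strings, `NA` missing),
#'   `gq_error` (`10^(-GQ/10)`), `class_probs` (posteriors, last dim
#'   `aa`/`ab`/`bb`) and integer `pl` array.
#' @export
call_genotypes <- function(ad_ref, ad_alt, seq_error = 0.001) {
  dims <- dim(ad_ref)
  ref <- as.vector(ad_ref); alt <- as.vector(ad_alt)
  e <- min(max(seq_error, 1e-12), 1 - 1e-12)
  pref <- c(1 - e, 0.5, e)
  ll <- matrix(vapply(pref, function(p) ref * log(p) + alt * log(1 - p),
                      numeric(length(ref))), length(ref), 3L)
  ll <- ll - apply(ll, 1, max)
  lik <- exp(ll)
  post <- lik / rowSums(lik)
  call_idx <- max.col(post, ties.method = "first")
  call <- c("aa", "ab", "bb")[call_idx]
  missing <- (ref + alt) == 0
  call[missing] <- NA_character_
  pmax_post <- post[cbind(seq_along(call_idx), call_idx)]
  gq <- pmin(round(-10 * log10(pmax(1 - pmax_post, 1e-10))), 99)
  pl <- round(-10 * (ll / log(10)))
  pl[missing, ] <- NA_integer_
  post[missing, ] <- NA_real_
  gq[missing] <- NA_integer_
  shape <- function(x) { dim(x) <- dims; dimnames(x) <- dimnames(ad_ref); x }
  dn <- dimnames(ad_ref)
  if (is.null(dn)) dn <- list(NULL, NULL)
  cp <- array(post, c(dims, 3L), dimnames = c(dn, list(c("aa", "ab", "bb"))))
  plarr <- array(pl, c(dims, 3L), dimnames = dimnames(cp))
  list(call = shape(call), gq_error = shape(10^(-gq / 10)),
       class_probs = cp, pl = plarr)
}

#' Simulate a complete GBS-genotyped F1 dataset with ground truth
#'
#' End-to-end generator: parents and true map, meioses (with optional
#' selection-driven segregation distortion), GBS allele depths and naive
#' genotype calls, assembled into a [marker_dataset()]. With
#' `observe = "true"` the dataset carries the error-free true genotypes
#' and no sequencing evidence.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; all randomness flows from it.
#' @param observe `"depths"` (default, realistic) or `"true"`
#'   (error-free genotypes).
#' @return list with `dataset` (a `marker_dataset`) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_f1 <- function(config = sim_config(), seed = 1L,
                        observe = c("depths", "true")) {
  observe <- match.arg(observe)
  set.seed(seed)
  parents <- simulate_parents(config)
  if (!is.null(config$distortion)) {
    pool <- simulate_progeny(parents,
                             config$distortion$oversample * config$n_progeny)
    truth <- apply_selection(pool, config$distortion$locus,
                             config$distortion$intensity, config$n_progeny)
  } else {
    truth <- simulate_progeny(parents, config$n_progeny)
  }
  markers <- truth$markers[, c("id", "chrom", "pos_bp", "p1", "p2")]
  if (observe == "true") {
    dataset <- marker_dataset(markers, truth$geno)
    return(list(dataset = dataset, truth = truth))
  }
  depths <- simulate_depths(truth, config)
  calls <- call_genotypes(depths$ad_ref, depths$ad_alt, config$seq_error)
  pcalls <- call_genotypes(depths$parent_ad_ref, depths$parent_ad_alt,
                           config$seq_error)
  markers$p1 <- pcalls$call[, 1]
  markers$p2 <- pcalls$call[, 2]
  dataset <- marker_dataset(
    markers, calls$call,
    ad_ref = depths$ad_ref, ad_alt = depths$ad_alt,
    dp = depths$ad_ref + depths$ad_alt,
    gq_error = calls$gq_error, class_probs = calls$class_probs,
    parent_ad_ref = depths$parent_ad_ref,
    parent_ad_alt = depths$parent_ad_alt,
    parent_dp = depths$parent_ad_ref + depths$parent_ad_alt,
    parent_gq_error = pcalls$gq_error)
  list(dataset = dataset, truth = truth)
}

#' Inject random genotype errors into a dataset
#'
#' Flips a fraction of the non-missing progeny calls to another
#' observable class of the marker, chosen uniformly. Used to study how
#' the error model of [estimate_map()] absorbs miscalls.
#'
#' @param dataset a [marker_dataset()].
#' @param rate per-genotype error rate.
#' @return the corrupted dataset (calls only; depth fields untouched).
#' @export
inject_genotype_errors <- function(dataset, rate = 0.1) {
  out <- dataset
  for (m in seq_len(nrow(dataset$markers))) {
    if (dataset$markers$type[m] == "NONINF") next
    cls <- marker_classes(dataset$markers$p1[m], dataset$markers$p2[m])$classes
    obs <- which(!is.na(dataset$geno[m, ]))
    flip <- obs[runif(length(obs)) < rate]
    for (n in flip) {
      alt <- setdiff(cls, dataset$geno[m, n])
      if (length(alt))
        out$geno[m, n] <- alt[sample.int(length(alt), 1L)]
    }
  }
  out
}
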