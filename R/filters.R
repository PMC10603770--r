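#' Marker and genotype filters between variant calling and map building
#'
#' The filters are applied in a fixed order -- missing-data/MAF,
#' non-informative removal, impossible-genotype masking, genotype
#' probability threshold, segregation test, redundancy -- each returning
#' the reduced dataset plus a `filter_report` with in/out counts. Later
#' filters therefore see fewer markers; in particular the Bonferroni
#' denominator of the segregation test is the number of markers that
#' actually reach it.
#'
#' @name filters
NULL

filter_report <- function(name, n_in, n_removed, extra = list()) {
  stopifnot(n_removed >= 0, n_removed <= n_in)
  structure(c(list(filter = name, markers_in = n_in,
                   markers_removed = n_removed,
                   markers_out = n_in - n_removed), extra),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter %-18s %d -> %d markers (-%d)", x$filter,
              x$markers_in, x$markers_out, x$markers_removed))
  if (!is.null(x$genotypes_masked))
    cat(";", x$genotypes_masked, "genotypes masked")
  cat("\n")
  invisible(x)
}

#' Filter markers by missing data and minor allele frequency
#'
#' Drops markers whose fraction of missing progeny calls exceeds
#' `max_missing` or whose minor-allele frequency -- computed by counting
#' alleles in the non-missing progeny calls (parents excluded) -- is
#' below `min_maf`.
#'
#' @param dataset a [marker_dataset()].
#' @param max_missing maximum tolerated missing fraction (default 0.25).
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @return list with `dataset` and `report`.
#' @export
filter_missing_maf <- function(dataset, max_missing = 0.25, min_maf = 0.05) {
  M <- nrow(dataset$markers)
  miss_frac <- rowMeans(is.na(dataset$geno))
  maf <- apply(dataset$geno, 1, function(g) {
    al <- unlist(geno_alleles(g[!is.na(g)]))
    if (!length(al)) return(0)
    min(table(al)) / length(al)
  })
  # monomorphic rows have a single allele "frequency" of 1; their MAF is 0
  mono <- apply(dataset$geno, 1, function(g) {
    al <- unique(unlist(geno_alleles(g[!is.na(g)])))
    length(al) < 2L
  })
  maf[mono] <- 0
  keep <- miss_frac <= max_missing & maf >= min_maf
  list(dataset = subset_markers(dataset, keep),
       report = filter_report("missing_maf", M, sum(!keep),
                              list(missing_fraction = unname(miss_frac),
                                   maf = unname(maf))))
}

#' Remove non-informative markers
#'
#' A marker is non-informative for an outcrossing F1 family when both
#' parents are homozygous or when at least one parental genotype is
#' missing: its progeny carry no segregation information.
#'
#' @inheritParams filter_missing_maf
#' @return list with `dataset` and `report`.
#' @export
remove_noninformative <- function(dataset) {
  M <- nrow(dataset$markers)
  keep <- dataset$markers$type != "NONINF"
  list(dataset = subset_markers(dataset, keep),
       report = filter_report("noninformative", M, sum(!keep)))
}

#' Mask genotype calls impossible under the cross type
#'
#' In a cross `aa x ab` the genotype `bb` cannot exist; such calls are
#' artefacts and are made missing (their priors become uniform).
#' Idempotent.
#'
#' @inheritParams filter_missing_maf
#' @return list with `dataset` and `report` (markers are never removed;
#'   `genotypes_masked` counts the masked calls).
#' @export
mask_unexpected <- function(dataset) {
  M <- nrow(dataset$markers)
  masked <- 0L
  for (m in seq_len(M)) {
    if (dataset$markers$type[m] == "NONINF") next
    cls <- marker_classes(dataset$markers$p1[m], dataset$markers$p2[m])$classes
    bad <- !is.na(dataset$geno[m, ]) & !(dataset$geno[m, ] %in% cls)
    if (any(bad)) {
      dataset$geno[m, bad] <- NA_character_
      if (!is.null(dataset$class_probs))
        dataset$class_probs[m, bad, ] <- NA_real_
      if (!is.null(dataset$gq_error)) dataset$gq_error[m, bad] <- NA_real_
      masked <- masked + sum(bad)
    }
  }
  list(dataset = dataset,
       report = filter_report("mask_unexpected", M, 0L,
                              list(genotypes_masked = masked)))
}

#' Mask genotypes below a probability threshold
#'
#' A genotype whose maximum class probability (or `1 - gq_error` when
#' only GQ evidence is present) falls below `threshold` becomes missing.
#' Observations carrying no probability evidence are left untouched and
#' counted.
#'
#' @inheritParams filter_missing_maf
#' @param threshold minimum acceptable genotype probability (default 0.8).
#' @return list with `dataset` and `report`.
#' @export
filter_genotype_prob <- function(dataset, threshold = 0.8) {
  M <- nrow(dataset$markers)
  masked <- 0L
  no_info <- 0L
  for (m in seq_len(M)) {
    for (n in seq_len(ncol(dataset$geno))) {
      if (is.na(dataset$geno[m, n])) next
      p <- NA_real_
      if (!is.null(dataset$class_probs) &&
          !all(is.na(dataset$class_probs[m, n, ])))
        p <- max(dataset$class_probs[m, n, ], na.rm = TRUE)
      else if (!is.null(dataset$gq_error) && !is.na(dataset$gq_error[m, n]))
        p <- 1 - dataset$gq_error[m, n]
      if (is.na(p)) { no_info <- no_info + 1L; next }
      if (p < threshold) {
        dataset$geno[m, n] <- NA_character_
        masked <- masked + 1L
      }
    }
  }
  list(dataset = dataset,
       report = filter_report("genotype_prob", M, 0L,
                              list(genotypes_masked = masked,
                                   genotypes_no_info = no_info)))
}

#' Chi-square segregation test with Bonferroni correction
#'
#' Tests each marker's non-missing progeny class counts against its
#' expected Mendelian ratio (1:2:1 for `B3.7`, 1:1 for `D1.10`/`D2.15`,
#' 1:1:1:1 for `A` types) with a plain chi-square goodness-of-fit
#' statistic (no continuity correction). Markers with
#' `p < alpha / m_tested` are removed, where `m_tested` is the number of
#' markers entering this filter. Markers with fewer than 2 non-missing
#' observations are removed with reason `insufficient data`.
#'
#' @inheritParams filter_missing_maf
#' @param alpha global significance level (default 0.05).
#' @return list with `dataset` and `report` (carrying `p_values`,
#'   `chisq` and the Bonferroni `threshold`).
#' @export
segregation_filter <- function(dataset, alpha = 0.05) {
  M <- nrow(dataset$markers)
  testable <- dataset$markers$type != "NONINF"
  m_tested <- sum(testable)
  thr <- alpha / max(m_tested, 1L)
  pv <- rep(NA_real_, M)
  stat <- rep(NA_real_, M)
  insufficient <- rep(FALSE, M)
  for (m in which(testable)) {
    mc <- marker_classes(dataset$markers$p1[m], dataset$markers$p2[m])
    g <- dataset$geno[m, ]
    g <- g[!is.na(g)]
    if (length(g) < 2L) { insufficient[m] <- TRUE; next }
    obs <- as.numeric(table(factor(g, levels = mc$classes)))
    expd <- mc$ratio * length(g)
    stat[m] <- sum((obs - expd)^2 / expd)
    pv[m] <- pchisq(stat[m], df = length(mc$classes) - 1L,
                    lower.tail = FALSE)
  }
  distorted <- !is.na(pv) & pv < thr
  keep <- !(distorted | insufficient)
  list(dataset = subset_markers(dataset, keep),
       report = filter_report("segregation", M, sum(!keep),
                              list(p_values = pv, chisq = stat,
                                   threshold = thr,
                                   n_tested = m_tested,
                                   n_insufficient = sum(insufficient))))
}

#' Collapse redundant markers into bins
#'
#' Markers whose full progeny call vector (including the missing-data
#' pattern) is identical to an earlier marker's carry no additional
#' mapping information; the first occurrence (lowest genomic position)
#' represents the bin and the rest are dropped.
#'
#' @inheritParams filter_missing_maf
#' @return list with `dataset` and `report` (carrying `bin`, the bin
#'   representative index for every input marker).
#' @export
remove_redundant <- function(dataset) {
  M <- nrow(dataset$markers)
  key <- apply(dataset$geno, 1, function(g)
    paste(ifelse(is.na(g), ".", g), collapse = "|"))
  bin <- match(key, key)
  keep <- !duplicated(key)
  list(dataset = subset_markers(dataset, keep),
       report = filter_report("redundant", M, sum(!keep),
                              list(bin = bin)))
}

#' Run the full filter cascade in the standard order
#'
#' Order: missing/MAF, non-informative, impossible-genotype masking,
#' genotype-probability threshold, segregation test, redundancy. Each
#' step can be switched off.
#'
#' @inheritParams filter_missing_maf
#' @inheritParams filter_genotype_prob
#' @inheritParams segregation_filter
#' @param steps character vector naming the steps to run.
#' @param verbose print one log line per filter.
#' @return list with `dataset` and `reports` (list of `filter_report`).
#' @export
apply_filters <- function(dataset, max_missing = 0.25, min_maf = 0.05,
                          threshold = 0.8, alpha = 0.05,
                          steps = c("missing_maf", "noninformative",
                                    "mask_unexpected", "genotype_prob",
                                    "segregation", "redundant"),
                          verbose = TRUE) {
  reports <- list()
  run <- function(name, res) {
    if (verbose) print(res$report)
    reports[[name]] <<- res$report
    res$dataset
  }
  if ("missing_maf" %in% steps)
    dataset <- run("missing_maf", filter_missing_maf(dataset, max_missing, min_maf))
  if ("noninformative" %in% steps)
    dataset <- run("noninformative", remove_noninformative(dataset))
  if ("mask_unexpected" %in% steps)
    dataset <- run("mask_unexpected", mask_unexpected(dataset))
  if ("genotype_prob" %in% steps)
    dataset <- run("genotype_prob", filter_genotype_prob(dataset, threshold))
  if ("segregation" %in% steps)
    dataset <- run("segregation", segregation_filter(dataset, alpha))
  if ("redundant" %in% steps)
    dataset <- run("redundant", remove_redundant(dataset))
  list(dataset = dataset, reports = reports)
}

#' Serialize filter reports to JSON
#'
#' @param reports list of `filter_report` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(reports, path) {
  slim <- lapply(reports, function(r)
    r[intersect(names(r), c("filter", "markers_in", "markers_removed",
                            "markers_out", "genotypes_masked",
                            "genotypes_no_info", "threshold", "n_tested",
                            "n_insufficient"))])
  jsonlite::write_json(slim, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
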