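#' Read a VCF into a marker dataset
#'
#' Parses a VCF (via the vcfR package), keeps only biallelic SNP
#' records, and converts the FORMAT fields of the two parents and the
#' progeny into genotype observations: `GT` (phased or unphased
#' separators; phase is ignored and re-estimated), `AD` reference/
#' alternate depths, `DP`, `GQ` converted to an error probability
#' `10^(-GQ/10)`, and `PL` converted to class probabilities
#' (`p_i` proportional to `10^(-PL_i/10)`, normalized). Each marker's
#' cross type is classified from the parental calls. Input is assumed
#' already left-aligned/normalized (e.g. by `bcftools norm`).
#'
#' @param path VCF file (plain or gzipped).
#' @param parent1_id,parent2_id sample names of the two parents.
#' @return a [marker_dataset()]; excluded records are tallied in the
#'   `excluded` attribute (`multiallelic`, `non_snp`).
#' @export
read_vcf <- function(path, parent1_id, parent2_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!all(c(parent1_id, parent2_id) %in% samples))
    stop("parent sample ids not found in VCF: ",
         paste(setdiff(c(parent1_id, parent2_id), samples), collapse = ", "))
  progeny_ids <- setdiff(samples, c(parent1_id, parent2_id))
  if (length(progeny_ids) < 2L) stop("need at least 2 progeny samples")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  nonsnp <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
                        is.na(fix$ALT))
  keep <- !multi & !nonsnp
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  excluded <- c(multiallelic = sum(multi), non_snp = sum(nonsnp))
  sub <- function(x) x[keep, , drop = FALSE]

  gt_raw <- sub(vcfR::extract.gt(vcf, "GT", convertNA = TRUE))
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if (!"GT" %in% fmt) stop("VCF has no GT FORMAT field")
  has <- function(f) f %in% fmt
  parse_calls <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_character_, length(g))
    out[g %in% c("0/0")] <- "aa"
    out[g %in% c("0/1", "1/0")] <- "ab"
    out[g %in% c("1/1")] <- "bb"
    out
  }
  calls <- matrix(parse_calls(gt_raw), nrow(gt_raw), ncol(gt_raw),
                  dimnames = dimnames(gt_raw))
  ad_raw <- if (has("AD")) sub(vcfR::extract.gt(vcf, "AD")) else NULL
  dp_raw <- if (has("DP")) sub(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)) else NULL
  gq_raw <- if (has("GQ")) sub(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)) else NULL
  pl_raw <- if (has("PL")) sub(vcfR::extract.gt(vcf, "PL")) else NULL
  if (is.null(ad_raw) && is.null(dp_raw) && is.null(gq_raw) && is.null(pl_raw))
    message("VCF carries GT only; no depth or quality evidence ingested")

  parse_ad <- function(x, idx) {
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(x), ",", x), ","),
                        function(p) if (length(p) >= idx) p[idx] else NA_character_,
                        character(1))))
    matrix(v, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  ad_ref <- parse_ad(ad_raw, 1L)
  ad_alt <- parse_ad(ad_raw, 2L)
  # "0,0" and "." both mean no usable depth
  if (!is.null(ad_ref)) {
    none <- !is.na(ad_ref) & !is.na(ad_alt) & ad_ref == 0L & ad_alt == 0L
    ad_ref[none] <- NA_integer_; ad_alt[none] <- NA_integer_
  }
  parse_pl <- function(x) {
    if (is.null(x)) return(NULL)
    out <- array(NA_real_, c(nrow(x), ncol(x), 3L),
                 dimnames = c(dimnames(x), list(c("aa", "ab", "bb"))))
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      if (is.na(x[i, j])) next
      pl <- suppressWarnings(as.numeric(strsplit(x[i, j], ",")[[1]]))
      if (length(pl) != 3L || anyNA(pl)) next
      p <- 10^(-pl / 10)
      out[i, j, ] <- p / sum(p)
    }
    out
  }
  class_probs <- parse_pl(pl_raw)
  gq_err <- if (!is.null(gq_raw)) 10^(-gq_raw / 10) else NULL

  fixk <- sub(as.matrix(fix[, c("CHROM", "POS", "ID")]))
  ids <- fixk[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fixk[, "CHROM"], "_",
                                         fixk[, "POS"])[is.na(ids) | ids == "."]
  p1c <- calls[, parent1_id]; p2c <- calls[, parent2_id]
  markers <- data.frame(id = ids, chrom = fixk[, "CHROM"],
                        pos_bp = as.integer(fixk[, "POS"]),
                        p1 = p1c, p2 = p2c, stringsAsFactors = FALSE)
  pick <- function(x, cols) if (is.null(x)) NULL else
    if (length(dim(x)) == 3L) x[, cols, , drop = FALSE] else x[, cols, drop = FALSE]
  ds <- marker_dataset(
    markers, calls[, progeny_ids, drop = FALSE],
    ad_ref = pick(ad_ref, progeny_ids), ad_alt = pick(ad_alt, progeny_ids),
    dp = pick(dp_raw, progeny_ids), gq_error = pick(gq_err, progeny_ids),
    class_probs = pick(class_probs, progeny_ids),
    parent_ids = c(parent1_id, parent2_id),
    parent_ad_ref = pick(ad_ref, c(parent1_id, parent2_id)),
    parent_ad_alt = pick(ad_alt, c(parent1_id, parent2_id)),
    parent_dp = pick(dp_raw, c(parent1_id, parent2_id)),
    parent_gq_error = pick(gq_err, c(parent1_id, parent2_id)))
  attr(ds, "excluded") <- excluded
  ds
}

#' Write a marker dataset to a VCF file
#'
#' Emits a VCF 4.2 file with GT, AD, DP, GQ and PL reconstructed from
#' the stored observations (reference-coded: `aa` = 0/0, `ab` = 0/1,
#' `bb` = 1/1). Missing calls are written `./.` with AD/DP omitted.
#' Only biallelic (a/b) markers can be represented.
#'
#' @param dataset a [marker_dataset()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  if (any(dataset$markers$type %in% c("A.1", "A.2")))
    stop("VCF export supports biallelic markers only")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fsmapr",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled likelihoods">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$parent_ids, colnames(dataset$geno)),
          collapse = "\t"))
  M <- nrow(dataset$markers)
  gt_code <- c(aa = "0/0", ab = "0/1", bb = "1/1")
  fmt_one <- function(call, adr, ada, dp, gqe, probs) {
    gt <- if (is.na(call)) "./." else gt_code[[call]]
    ad <- if (is.na(call) || is.na(adr) || is.na(ada)) "."
          else paste0(adr, ",", ada)
    dpf <- if (is.na(call) || is.na(dp)) "." else as.character(dp)
    gq <- if (is.na(gqe)) "." else as.character(round(-10 * log10(max(gqe, 1e-10))))
    pl <- if (any(is.na(probs))) "." else {
      p <- pmax(probs, 1e-30)
      v <- round(-10 * log10(p / max(p)))
      paste(pmin(v, 999), collapse = ",")
    }
    paste(gt, ad, dpf, gq, pl, sep = ":")
  }
  get2 <- function(x, m, j, default = NA) {
    if (is.null(x)) default else x[m, j]
  }
  lines <- vapply(seq_len(M), function(m) {
    psamp <- vapply(1:2, function(j) fmt_one(
      dataset$markers[[c("p1", "p2")[j]]][m],
      get2(dataset$parent_ad_ref, m, j), get2(dataset$parent_ad_alt, m, j),
      get2(dataset$parent_dp, m, j), get2(dataset$parent_gq_error, m, j),
      rep(NA_real_, 3)), character(1))
    osamp <- vapply(seq_len(ncol(dataset$geno)), function(j) fmt_one(
      dataset$geno[m, j],
      get2(dataset$ad_ref, m, j), get2(dataset$ad_alt, m, j),
      get2(dataset$dp, m, j), get2(dataset$gq_error, m, j),
      if (is.null(dataset$class_probs)) rep(NA_real_, 3)
      else dataset$class_probs[m, j, ]), character(1))
    paste(c(dataset$markers$chrom[m], dataset$markers$pos_bp[m],
            dataset$markers$id[m], "A", "T", ".", "PASS", ".",
            "GT:AD:DP:GQ:PL", psamp, osamp), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Zero out allele depths of missing genotype calls
#'
#' Variant callers sometimes report read counts in the AD/DP fields of
#' records whose genotype they refused to call (e.g. `GT:AD ./.;149,0`),
#' and depth-based genotype re-callers will happily use those phantom
#' counts. This sanitization sets AD and DP to zero wherever the call is
#' missing, for progeny and parents alike; everything else is untouched.
#'
#' @param dataset a [marker_dataset()].
#' @return the sanitized dataset, with attribute `n_sanitized`.
#' @export
sanitize_allele_depths <- function(dataset) {
  out <- dataset
  n <- 0L
  if (!is.null(out$ad_ref)) {
    miss <- is.na(out$geno)
    n <- n + sum(miss & (!is.na(out$ad_ref) & out$ad_ref != 0L |
                           !is.na(out$ad_alt) & out$ad_alt != 0L))
    out$ad_ref[miss] <- 0L
    out$ad_alt[miss] <- 0L
    if (!is.null(out$dp)) out$dp[miss] <- 0L
  }
  if (!is.null(out$parent_ad_ref)) {
    pmiss <- cbind(is.na(out$markers$p1), is.na(out$markers$p2))
    n <- n + sum(pmiss & (!is.na(out$parent_ad_ref) & out$parent_ad_ref != 0L |
                            !is.na(out$parent_ad_alt) & out$parent_ad_alt != 0L))
    out$parent_ad_ref[pmiss] <- 0L
    out$parent_ad_alt[pmiss] <- 0L
    if (!is.null(out$parent_dp)) out$parent_dp[pmiss] <- 0L
  }
  attr(out, "n_sanitized") <- n
  out
}

#' Export a linkage map as a tab-separated table
#'
#' One row per marker: id, chromosome, physical position, cross type,
#' parental phase codes, recombination fraction and cM of the interval
#' to the previous marker, and cumulative cM.
#'
#' @param map a `linkage_map`.
#' @param path output file.
#' @return the exported data.frame, invisibly.
#' @export
export_map_tsv <- function(map, path) {
  df <- data.frame(
    id = map$markers$id, chrom = map$markers$chrom,
    pos_bp = map$markers$pos_bp, type = map$markers$type,
    phase_p1 = map$phases[, 1], phase_p2 = map$phases[, 2],
    interval_rf = c(NA, map$rf),
    interval_cm = c(NA, map_function(map$rf, map$mapfunc)),
    cumulative_cm = map$cumulative_cm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export decoded progeny haplotypes as a long-format table
#'
#' @param haplotypes a `progeny_haplotypes` object.
#' @param path output file.
#' @return the exported data.frame, invisibly.
#' @export
export_haplotypes_tsv <- function(haplotypes, path) {
  M <- nrow(haplotypes$origin_p1); N <- ncol(haplotypes$origin_p1)
  df <- data.frame(
    progeny = rep(colnames(haplotypes$origin_p1), each = M),
    marker = rep(haplotypes$marker_ids, N),
    p1_homolog = as.vector(haplotypes$origin_p1),
    p2_homolog = as.vector(haplotypes$origin_p2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
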