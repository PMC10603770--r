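# Hand-built fixtures shared across test files.

# A 10-marker, 8-progeny dataset with hand-enumerated per-filter
# outcomes (defaults: missing 0.25, MAF 0.05, prob 0.8, alpha 0.05):
#  T01 B3.7   clean 2:4:2 segregation                      -> survives all
#  T02 B3.7   duplicate call vector of T01                 -> redundancy
#  T03 D1.10  3/8 missing (0.375 > 0.25)                   -> missing rule
#  T04 D2.15  clean 4:4                                    -> survives all
#  T05 NONINF aa x aa (2 miscalls keep its MAF above 5%)   -> noninformative
#  T06 D1.10  parent call missing => NONINF                -> noninformative
#  T07 B3.7   one genotype with max class prob 0.5 (masked by
#             the 0.8 filter), otherwise clean             -> survives all
#  T08 B3.7   distorted 6:0:2, chisq = 12, p = 2.5e-3
#             < 0.05/6 Bonferroni                          -> segregation
#  T09 D1.10  monomorphic progeny, MAF 0 < 0.05            -> MAF rule
#  T10 D1.10  one call "bb" impossible under ab x aa (masked),
#             then clean                                   -> survives all
# Step-by-step marker counts: 10 -> 8 (T03, T09) -> 6 (T05, T06)
# -> 6 (+1 mask) -> 6 (+1 mask) -> 5 (T08) -> 4 (T02).
toy_filter_dataset <- function() {
  geno <- rbind(
    T01 = c("aa", "ab", "ab", "bb", "ab", "aa", "bb", "ab"),
    T02 = c("aa", "ab", "ab", "bb", "ab", "aa", "bb", "ab"),
    T03 = c("aa", NA, NA, "ab", NA, "aa", "ab", "aa"),
    T04 = c("aa", "ab", "aa", "ab", "aa", "ab", "aa", "ab"),
    T05 = c("aa", "aa", "ab", "aa", "aa", "ab", "aa", "aa"),
    T06 = c("aa", "ab", "aa", "ab", "aa", "ab", "aa", "ab"),
    T07 = c("aa", "ab", "ab", "bb", "ab", "bb", "aa", "ab"),
    T08 = c("aa", "aa", "aa", "aa", "aa", "aa", "bb", "bb"),
    T09 = c("aa", "aa", "aa", "aa", "aa", "aa", "aa", "aa"),
    T10 = c("aa", "ab", "bb", "ab", "aa", "ab", "aa", "ab"))
  colnames(geno) <- paste0("I", 1:8)
  markers <- data.frame(
    id = rownames(geno), chrom = "chr1", pos_bp = seq(1000, 10000, 1000),
    p1 = c("ab", "ab", "ab", "aa", "aa", "ab", "ab", "ab", "ab", "ab"),
    p2 = c("ab", "ab", "aa", "ab", "aa", NA, "ab", "ab", "aa", "aa"),
    stringsAsFactors = FALSE)
  cp <- array(NA_real_, c(10, 8, 3),
              dimnames = list(rownames(geno), colnames(geno),
                              c("aa", "ab", "bb")))
  for (m in 1:10) for (n in 1:8) {
    g <- geno[m, n]
    if (is.na(g)) next
    p <- c(aa = 0.02, ab = 0.02, bb = 0.02)
    p[g] <- 0.96
    cp[m, n, ] <- p
  }
  cp["T07", 3, ] <- c(0.40, 0.50, 0.10)  # low-confidence genotype
  marker_dataset(markers, geno, class_probs = cp)
}

# Minimal hand-written VCF used by the I/O tests.
toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Quality">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Likelihoods">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "I1", "I2", sep = "\t"),
    paste("chr1", "100", "S1", "A", "T", ".", "PASS", ".", "GT:AD:DP:GQ:PL",
          "0/1:5,6:11:60:80,0,90", "0/0:9,0:9:45:0,27,200",
          "0/1:3,4:7:20:30,0,40", "0/0:6,0:6:20:0,18,150", sep = "\t"),
    paste("chr1", "200", "S2", "G", "C", ".", "PASS", ".", "GT:AD:DP:GQ:PL",
          "0/1:7,7:14:70:90,0,95", "0/1:8,6:14:66:85,0,80",
          "1/1:0,9:9:33:120,27,0", "./.:149,0:149:.:.", sep = "\t"),
    # multiallelic record: must be excluded
    paste("chr1", "300", "S3", "A", "T,G", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/2", "0/0", sep = "\t"),
    # indel record: must be excluded
    paste("chr1", "400", "S4", "AT", "A", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/1", "0/0", sep = "\t"))
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toy_vcf_lines(), path)
  path
}

# Deterministic error-free dataset built directly from chosen gamete
# origins (marker types all fully informative for the relevant parent).
dataset_from_origins <- function(o1, o2, p1 = "ab", p2 = "ab",
                                 phase1 = 0L, phase2 = 0L) {
  M <- nrow(o1); n <- ncol(o1)
  types <- rep(p1, M); types2 <- rep(p2, M)
  h1 <- fsmapr:::parent_homologs(p1, if (fsmapr:::is_het(p1)) phase1 else NA)
  h2 <- fsmapr:::parent_homologs(p2, if (fsmapr:::is_het(p2)) phase2 else NA)
  geno <- matrix(fsmapr:::canonical_geno(h1[o1], h2[o2]), M, n)
  colnames(geno) <- paste0("I", seq_len(n))
  markers <- data.frame(id = sprintf("M%02d", 1:M), chrom = "chr1",
                        pos_bp = seq_len(M) * 1000,
                        p1 = types, p2 = types2, stringsAsFactors = FALSE)
  marker_dataset(markers, geno)
}
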