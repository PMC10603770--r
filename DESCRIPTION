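Package: fsmapr
Title: Error-Aware Linkage Maps for Full-Sib F1 Families from
    Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds multipoint linkage maps for diploid outcrossing F1
    (full-sib) populations genotyped with reduced-representation
    sequencing (GBS/RADseq). Genotype calls are converted into per-class
    probability priors (a global error rate, per-genotype errors, caller
    probabilities, or their combination) that feed the emissions of a
    four-state hidden Markov model over the transmitted parental
    homologs; recombination fractions are estimated by
    expectation-maximization with the forward-backward algorithm and
    converted to centimorgans with the Haldane or Kosambi map function.
    Includes the marker and genotype filters used between variant
    calling and map building (missing data, minor allele frequency,
    non-informative markers, impossible-genotype masking, genotype
    probability threshold, chi-square segregation test with Bonferroni
    correction, redundancy bins), a count-level GBS simulator (meiosis
    without interference, selection-driven segregation distortion,
    negative-binomial depths with beta-binomial allelic bias) and map
    quality statistics (map length, Euclidean distance to a reference
    map, recombination breakpoint accounting, order correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
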