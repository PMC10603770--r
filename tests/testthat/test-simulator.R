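test_that("monotone interpolation honours anchors and stays non-decreasing", {
  # two anchors: the monotone cubic reduces to a straight line
  expect_equal(interpolate_cm(5e5, c(0, 1e6), c(0, 10)), 5)
  # anchor positions are reproduced exactly
  bp <- c(0, 2e5, 9e5, 3e6); cm <- c(0, 3, 10, 38)
  expect_equal(interpolate_cm(bp, bp, cm), cm)
  # linear extension outside the anchor range
  lo <- interpolate_cm(c(-1e5, 3.1e6), bp, cm)
  expect_true(lo[1] < 0 && lo[2] > 38)
  set.seed(101)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    abp <- sort(sample(1:1e6, n))
    acm <- cumsum(runif(n, 0.1, 5))
    q <- seq(min(abp) - 1e4, max(abp) + 1e4, length.out = 400)
    out <- interpolate_cm(q, abp, acm)
    expect_true(all(diff(out) >= -1e-9))
  }
  expect_error(interpolate_cm(1, c(1, 2), c(5, 4)), "increasing")
})

test_that("simulated parents follow the configured type proportions", {
  cfg <- sim_config(n_markers = 50, type_proportions = c(B3.7 = 1))
  set.seed(3); par <- simulate_parents(cfg)
  expect_true(all(par$markers$type == "B3.7"))
  expect_true(all(par$markers$p1 == "ab" & par$markers$p2 == "ab"))
  # default proportions 126:263:278:143 within multinomial error
  cfg2 <- sim_config(n_markers = 810)
  set.seed(4); par2 <- simulate_parents(cfg2)
  counts <- table(factor(par2$markers$type,
                         levels = c("B3.7", "D1.10", "D2.15", "NONINF")))
  p <- c(126, 263, 278, 143) / 810
  gof <- sum((counts - 810 * p)^2 / (810 * p))
  expect_lt(gof, qchisq(0.999, df = 3))
  # phases are fair coin flips per heterozygous parent
  het <- fsmapr:::is_het(par2$markers$p1)
  expect_equal(mean(par2$phases[het, 1]), 0.5, tolerance = 0.1)
})

test_that("meiosis switch frequencies match the interval recombination fractions", {
  cfg <- sim_config(n_markers = 3, n_progeny = 1000, total_cm = 20,
                    type_proportions = c(B3.7 = 1))
  set.seed(5)
  par <- simulate_parents(cfg)
  # all r = 0: every gamete is an intact parental homolog
  par0 <- par; par0$rf <- c(0, 0)
  tr0 <- simulate_progeny(par0, 500)
  expect_equal(sum(tr0$breakpoints), 0L)
  # r = 0.5: adjacent origins are independent
  par5 <- par; par5$rf <- c(0.5, 0.5)
  tr5 <- simulate_progeny(par5, 1000)
  sw5 <- mean(tr5$origin_p1[1, ] != tr5$origin_p1[2, ])
  expect_equal(sw5, 0.5, tolerance = 3 * sqrt(0.25 / 1000) / 0.5)
  # r = 0.1: switch fraction over 2000 meioses within 3 SE
  par1 <- par; par1$rf <- c(0.1, 0.1)
  tr1 <- simulate_progeny(par1, 1000)
  sw1 <- mean(c(tr1$origin_p1[1, ] != tr1$origin_p1[2, ],
                tr1$origin_p2[1, ] != tr1$origin_p2[2, ]))
  expect_lt(abs(sw1 - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("progeny class frequencies are Mendelian without distortion", {
  cfg <- sim_config(n_markers = 12, n_progeny = 2000, total_cm = 30,
                    type_proportions = c(B3.7 = 1, D1.10 = 1, D2.15 = 1))
  sim <- simulate_f1(cfg, seed = 6, observe = "true")
  for (m in seq_len(12)) {
    mc <- marker_classes(sim$dataset$markers$p1[m], sim$dataset$markers$p2[m])
    obs <- as.numeric(table(factor(sim$truth$geno[m, ], mc$classes)))
    expd <- mc$ratio * 2000
    stat <- sum((obs - expd)^2 / expd)
    expect_lt(stat, qchisq(0.99, df = length(mc$classes) - 1))
  }
})

test_that("true breakpoints per gamete match the Haldane expectation", {
  cfg <- sim_config()  # default 38 cM map
  set.seed(7)
  par <- simulate_parents(cfg)
  truth <- simulate_progeny(par, 1000)
  expected <- sum(par$rf)        # ~ 0.38 minus high-order crossover loss
  mean_bp <- mean(truth$breakpoints)
  se <- sd(truth$breakpoints) / sqrt(length(truth$breakpoints))
  expect_lt(abs(mean_bp - expected), 3 * se)
  expect_equal(expected, 0.38, tolerance = 0.01)
})

test_that("selection eliminates carriers at the stated intensity", {
  cfg <- sim_config(n_markers = 40, n_progeny = 200, total_cm = 38,
                    type_proportions = c(B3.7 = 1, D1.10 = 2, D2.15 = 2),
                    distortion = list(locus = 30L, intensity = 0.5,
                                      oversample = 50L))
  set.seed(8)
  par <- simulate_parents(cfg)
  pool <- simulate_progeny(par, 50 * 200)
  sel <- apply_selection(pool, 30L, 0.5, 200L)
  expect_equal(ncol(sel$geno), 200L)
  frac <- sel$selection$n_eliminated / sel$selection$n_carriers
  se <- sqrt(0.25 / sel$selection$n_carriers)
  expect_lt(abs(frac - 0.5), 3 * se)
  # intensity 0 is a pure subsample
  sel0 <- apply_selection(pool, 30L, 0, 150L)
  expect_equal(sel0$selection$n_eliminated, 0L)
  expect_equal(ncol(sel0$geno), 150L)
  # D1.10 locus at intensity 0.5: post-selection het fraction near 1/3
  if (pool$markers$type[30] %in% c("D1.10", "D2.15")) {
    het_frac <- mean(sel$geno[30, ] == "ab")
    expect_lt(abs(het_frac - 1 / 3), 0.1)
  }
  expect_error(apply_selection(pool, 30L, 1, ncol(pool$geno)),
               "selection too strong")
})

test_that("depth simulation respects the parental depth multiplier", {
  cfg <- sim_config(n_markers = 150, n_progeny = 150)
  sim <- simulate_f1(cfg, seed = 10)
  ds <- sim$dataset
  mean_prog <- mean(ds$ad_ref + ds$ad_alt)
  mean_par <- mean(ds$parent_ad_ref + ds$parent_ad_alt)
  expect_equal(mean_par / mean_prog, 8, tolerance = 0.05 * 8)
  expect_equal(mean_prog, 10, tolerance = 0.05 * 10)
  # unbiased, non-overdispersed heterozygote reads are symmetric
  cfg2 <- sim_config(n_markers = 80, n_progeny = 100, overdispersion = 0,
                     seq_error = 0, mean_depth = 20,
                     type_proportions = c(B3.7 = 1))
  set.seed(11)
  par <- simulate_parents(cfg2)
  truth <- simulate_progeny(par, 100)
  dep <- simulate_depths(truth, cfg2)
  het <- truth$geno == "ab"
  tot <- dep$ad_ref + dep$ad_alt
  expect_equal(sum(dep$ad_ref[het]) / sum(tot[het]), 0.5, tolerance = 0.01)
  # zero-depth observations come out as missing calls
  calls <- call_genotypes(dep$ad_ref, dep$ad_alt, 0.001)
  expect_true(all(is.na(calls$call[tot == 0])))
})

test_that("naive genotype likelihood calls behave at depth extremes", {
  # 22 reference reads: likelihood ratio (0.999/0.5)^22, GQ ~ 66
  c1 <- call_genotypes(matrix(22L), matrix(0L), 0.001)
  expect_identical(c1$call[1, 1], "aa")
  expect_lt(c1$gq_error[1, 1], 1e-6)
  # deep coverage saturates GQ at the 99 cap
  c1b <- call_genotypes(matrix(60L), matrix(0L), 0.001)
  expect_equal(c1b$gq_error[1, 1], 10^(-99 / 10))
  c2 <- call_genotypes(matrix(5L), matrix(5L), 0.001)
  expect_identical(c2$call[1, 1], "ab")
  expect_gt(c2$class_probs[1, 1, "ab"], 0.99)
  # a single read cannot separate het from hom: below the 0.8 threshold
  c3 <- call_genotypes(matrix(1L), matrix(0L), 0.001)
  expect_lt(max(c3$class_probs[1, 1, ]), 0.8)
  # PL are min-rescaled
  expect_equal(min(c2$pl[1, 1, ]), 0)
})

test_that("identical seeds reproduce identical datasets end to end", {
  cfg <- sim_config(n_markers = 25, n_progeny = 30)
  a <- simulate_f1(cfg, seed = 123)
  b <- simulate_f1(cfg, seed = 123)
  expect_identical(a$truth$geno, b$truth$geno)
  expect_identical(a$dataset$ad_ref, b$dataset$ad_ref)
  expect_identical(a$dataset$geno, b$dataset$geno)
  c <- simulate_f1(cfg, seed = 124)
  expect_false(identical(a$dataset$ad_ref, c$dataset$ad_ref))
})
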