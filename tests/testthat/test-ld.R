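test_that("EM recovers perfect association and unambiguous counts", {
  # 50 individuals (2,2) + 50 (0,0): two complementary haplotypes only
  cc <- matrix(0, 3, 3); cc[3, 3] <- 50; cc[1, 1] <- 50
  est <- em_haplotype_freqs(cc)
  expect_equal(unname(est$hap), c(0.5, 0, 0, 0.5))
  expect_equal(est$D, 0.25)
  expect_equal(est$r2, 1.0)
  expect_true(est$converged)

  # no double heterozygotes: haplotype frequencies equal direct counts
  set.seed(21)
  for (rep in 1:20) {
    cc <- matrix(rpois(9, 10), 3, 3)
    cc[2, 2] <- 0
    n <- sum(cc)
    direct <- c(2 * cc[3, 3] + cc[3, 2] + cc[2, 3],
                2 * cc[3, 1] + cc[3, 2] + cc[2, 1],
                2 * cc[1, 3] + cc[1, 2] + cc[2, 3],
                2 * cc[1, 1] + cc[1, 2] + cc[2, 1]) / (2 * n)
    expect_equal(unname(em_haplotype_freqs(cc)$hap), direct,
                 tolerance = 1e-12)
  }
})

test_that("a single double heterozygote stays at the D = 0 saddle", {
  cc <- matrix(0, 3, 3); cc[2, 2] <- 1
  est <- em_haplotype_freqs(cc)
  expect_equal(est$D, 0)
  expect_equal(est$r2, 0)
  expect_equal(unname(est$hap), rep(0.25, 4))
})

test_that("EM log-likelihood attains the grid-search maximum", {
  set.seed(31)
  for (rep in 1:25) {
    hap <- as.vector(stats::rmultinom(1, 40, runif(4) + 0.05)) / 40
    g <- draw_two_locus(sample(20:150, 1), hap)
    cc <- two_locus_counts(g$da, g$db)
    est <- em_haplotype_freqs(cc, debug = TRUE)  # also asserts monotone EM
    expect_gte(est$loglik, oracle_grid_loglik(cc) - 1e-6)
  }
})

test_that("r2 is invariant to allele relabelling and locus exchange", {
  set.seed(41)
  for (rep in 1:30) {
    cc <- matrix(rpois(9, 6), 3, 3)
    if (sum(cc) == 0) next
    base <- em_haplotype_freqs(cc)$r2
    swapA <- em_haplotype_freqs(cc[3:1, ])$r2       # relabel locus A alleles
    swapB <- em_haplotype_freqs(cc[, 3:1])$r2       # relabel locus B alleles
    flip <- em_haplotype_freqs(t(cc))$r2            # exchange loci
    if (is.na(base)) {
      expect_true(is.na(swapA) && is.na(swapB) && is.na(flip))
    } else {
      expect_equal(swapA, base, tolerance = 1e-8)
      expect_equal(swapB, base, tolerance = 1e-8)
      expect_equal(flip, base, tolerance = 1e-8)
      expect_gte(base, 0); expect_lte(base, 1 + 1e-12)
    }
  }
})

test_that("EM r2 tracks the phased sample and sharpens with n", {
  set.seed(51)
  hap <- c(0.35, 0.15, 0.1, 0.4)
  rmse <- function(n, reps = 120) {
    err <- replicate(reps, {
      g <- draw_two_locus(n, hap)
      em <- em_haplotype_freqs(two_locus_counts(g$da, g$db))
      phased <- tabulate(c(g$h1, g$h2), 4) / (2 * n)
      sqrt(mean((em$hap - phased)^2))
    })
    sqrt(mean(err^2))
  }
  expect_lt(rmse(200), 0.02)            # phase ambiguity is a small error
  r100 <- rmse(100); r400 <- rmse(400)  # roughly halves as n quadruples
  expect_lt(r400 / r100, 0.8)
  expect_gt(r400 / r100, 0.3)
})

test_that("monomorphic loci yield undefined r2 and n = 0 errors", {
  cc <- matrix(0, 3, 3); cc[1, 1] <- 5; cc[1, 3] <- 5  # locus A fixed
  expect_true(is.na(em_haplotype_freqs(cc)$r2))
  expect_error(em_haplotype_freqs(matrix(0, 3, 3)), "no individuals")
})

test_that("population retention follows the core-frequency filter", {
  p <- toy_panel()
  mk_pop <- function(core_freq, pop, n = 50) {
    dos <- cbind(L1 = rbinom(n, 2, 0.2), CORE = rbinom(n, 2, core_freq),
                 R1 = rbinom(n, 2, 0.2))
    rownames(dos) <- sprintf("%s_%03d", pop, 1:n)
    dos
  }
  set.seed(61)
  dos <- rbind(mk_pop(0.3, "hi"), mk_pop(0.01, "lo"))
  gm <- gm_from_dosage(dos, p,
                       population = rep(c("hi", "lo"), each = 50))
  ld <- ld_matrices(gm)
  expect_setequal(unique(ld$population_id), "hi")
  # boundary: frequency must strictly exceed the threshold
  dos_b <- mk_pop(0.3, "b")
  gm_b <- gm_from_dosage(dos_b, p, population = "b")
  f <- sum(dos_b[, "CORE"]) / (2 * nrow(dos_b))
  ld_b <- suppressWarnings(ld_matrices(gm_b, min_core_freq = f))
  expect_equal(nrow(ld_b), 0)
  expect_warning(ld_matrices(gm_b, min_core_freq = 1), "no population")
})

test_that("temporal LD comparison counts decreases per pair class", {
  p <- ciona_panel()
  pairs <- island_pairs(p)
  mk_ld <- function(period, r2) {
    data.frame(population_id = "popA", period = period,
               marker_a = pairs$marker_a, marker_b = pairs$marker_b,
               pair_class = pairs$pair_class, n = 100, D = 0.1, r2 = r2,
               converged = TRUE, stringsAsFactors = FALSE)
  }
  set.seed(71)
  r12 <- runif(45, 0.2, 0.6)
  # strict decrease everywhere
  cmp <- ld_temporal_compare(rbind(mk_ld("2012", r12),
                                   mk_ld("2021", r12 - 0.05)),
                             c("2012", "2021"))
  ct <- cmp$class_tests
  expect_equal(ct$n_decrease, ct$n_pairs)
  expect_equal(cmp$n_pairs_decreased, 45)
  expect_equal(ct$n_pairs[ct$pair_class == "core_shoulder"], 9)
  expect_equal(ct$n_pairs[ct$pair_class == "right_shoulder"], 10)
  # identical matrices: degenerate, p = 1
  cmp0 <- ld_temporal_compare(rbind(mk_ld("2012", r12), mk_ld("2021", r12)),
                              c("2012", "2021"))
  expect_true(all(cmp0$class_tests$degenerate))
  expect_true(all(cmp0$class_tests$sign_p == 1))
  expect_equal(cmp0$n_pairs_decreased, 0)
})

test_that("mean_r2 aggregations agree on complete balanced input", {
  ld <- data.frame(population_id = rep(c("a", "b"), each = 3),
                   period = "2012",
                   marker_a = rep(c("m1", "m1", "m2"), 2),
                   marker_b = rep(c("m2", "m3", "m3"), 2),
                   pair_class = "cross_shoulder", n = 10, D = 0,
                   r2 = c(0.2, 0.1, 0.3, 0.4, 0.3, 0.5),
                   converged = TRUE, stringsAsFactors = FALSE)
  expect_equal(mean_r2(ld, "2012"), 0.3)
  expect_equal(mean_r2(ld, "2012", "pair_means"), 0.3)
  # with disjoint defined pairs the mean runs over the union
  ld$r2[c(2, 6)] <- NA
  expect_equal(mean_r2(ld, "2012"), mean(c(0.2, 0.3, 0.4, 0.3)))
})
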