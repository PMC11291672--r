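test_that("2x2 exact test: closed-form cases", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 7, 7), 2))$p_value, 1.0)
  # complete separation of 5 vs 5: 2 / choose(10, 5)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("2x2 and 2x3 exact tests match enumeration oracle and fisher.test", {
  set.seed(101)
  for (rep in 1:60) {
    tab22 <- matrix(rpois(4, sample(2:12, 1)), 2)
    if (any(rowSums(tab22) == 0) || any(colSums(tab22) == 0)) next
    mine <- fisher_exact_2x2(tab22)$p_value
    expect_equal(mine, oracle_exact_2xc(tab22), tolerance = 1e-12)
    expect_equal(mine, fisher.test(tab22)$p.value, tolerance = 1e-7)

    tab23 <- matrix(rpois(6, sample(2:10, 1)), 2)
    if (any(rowSums(tab23) == 0) || any(colSums(tab23) == 0)) next
    mine3 <- exact_test_rxc(tab23)$p_value
    expect_equal(mine3, oracle_exact_2xc(tab23), tolerance = 1e-12)
    expect_equal(mine3, fisher.test(tab23)$p.value, tolerance = 1e-7)
  }
})

test_that("rxc test reduces to the 2x2 test and handles flat tables", {
  set.seed(7)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(exact_test_rxc(tab)$p_value,
                 fisher_exact_2x2(tab)$p_value, tolerance = 1e-12)
  }
  expect_equal(exact_test_rxc(matrix(c(4, 4, 6, 6, 2, 2), 2))$p_value, 1.0)
  # 3-row recursion path agrees with fisher.test
  tab33 <- matrix(c(3, 1, 2, 2, 4, 1, 1, 2, 3), 3)
  expect_equal(exact_test_rxc(tab33)$p_value, fisher.test(tab33)$p.value,
               tolerance = 1e-7)
})

test_that("large tables refuse enumeration and fall back to seeded MC", {
  big <- matrix(c(4000, 3900, 2000, 2100, 1000, 1000), 2)
  expect_error(exact_test_rxc(big, max_tables = 1e4), "monte_carlo")
  mc1 <- exact_test_rxc(big, max_tables = 1e4,
                        monte_carlo = list(B = 2000, seed = 5))
  mc2 <- exact_test_rxc(big, max_tables = 1e4,
                        monte_carlo = list(B = 2000, seed = 5))
  expect_equal(mc1$p_value, mc2$p_value)  # seeded, reproducible
  expect_equal(mc1$method, "monte_carlo")
})

test_that("BH adjustment: closed form, monotonicity, edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(3)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("sign test: exact binomial doubling", {
  expect_equal(sign_test(8, 9)$p_value, 20 / 512)
  expect_equal(sign_test(9, 10)$p_value, 22 / 1024)
  expect_equal(sign_test(5, 10)$p_value, 1.0)
  expect_equal(sign_test(5, 5)$p_value, 2 / 32)
  expect_error(sign_test(0, 0), "n >= 1")
})

test_that("signed-rank test: extreme case, symmetry, zero handling", {
  # 5 decreases out of 5: one-sided p = 1/32
  w <- wilcoxon_signed_rank(c(-1, -2, -3, -4, -5), "less")
  expect_equal(w$p_value, 1 / 32)
  expect_true(w$exact)
  # mirrored differences: two-sided p well away from significance
  w2 <- wilcoxon_signed_rank(c(-3, 3, -2, 2, -1, 1, -4, 4), "two.sided")
  expect_gt(w2$p_value, 0.5)
  # zeros are discarded and counted
  w3 <- wilcoxon_signed_rank(c(0, 0, -1, -2, 3), "less")
  expect_equal(w3$n_zero, 2)
  expect_equal(w3$n, 3)
  expect_true(wilcoxon_signed_rank(c(0, 0, 0))$degenerate)
})

test_that("signed-rank exact p matches brute-force 2^n enumeration", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    d <- round(runif(n, -5, 5), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    for (alt in c("less", "greater", "two.sided"))
      expect_equal(wilcoxon_signed_rank(d, alt)$p_value,
                   oracle_signed_rank(d, alt), tolerance = 1e-12)
    # cross-check one-sided p against the base R implementation
    expect_equal(wilcoxon_signed_rank(d, "less")$p_value,
                 suppressWarnings(wilcox.test(d, alternative = "less",
                                              exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("type-I error of the exact tests sits near the nominal level", {
  set.seed(404)
  B <- 2000
  # allele 2x2 under a binomial null, 100 individuals per period
  p22 <- replicate(B, {
    x <- rbinom(2, 200, 0.3)
    fisher_exact_2x2(rbind(c(x[1], 200 - x[1]), c(x[2], 200 - x[2])))$p_value
  })
  expect_gte(mean(p22 < 0.05), 0.03)
  expect_lte(mean(p22 < 0.05), 0.07)
  # genotype 2x3 under a Hardy-Weinberg null, 60 individuals per period
  p23 <- replicate(B, {
    g <- replicate(2, table(factor(rbinom(60, 2, 0.3), levels = 0:2)))
    exact_test_rxc(t(g))$p_value
  })
  expect_gte(mean(p23 < 0.05), 0.03)
  expect_lte(mean(p23 < 0.05), 0.07)
  # signed-rank with 14 population replicates of no change
  pw <- replicate(B, wilcoxon_signed_rank(rnorm(14), "less")$p_value)
  expect_gte(mean(pw < 0.05), 0.03)
  expect_lte(mean(pw < 0.05), 0.07)
})

test_that("BH-adjusted per-population null results stay controlled", {
  set.seed(505)
  rej <- replicate(1000, {
    p <- vapply(1:14, function(i) {
      x <- rbinom(2, 80, 0.25)
      fisher_exact_2x2(rbind(c(x[1], 80 - x[1]), c(x[2], 80 - x[2])))$p_value
    }, numeric(1))
    mean(bh_adjust(p) < 0.05)
  })
  expect_lte(mean(rej), 0.07)
})

test_that("pooled test has power against a 0.10 frequency decline", {
  set.seed(606)
  hit <- replicate(300, {
    x1 <- rbinom(1, 900, 0.25); x2 <- rbinom(1, 900, 0.15)
    fisher_exact_2x2(rbind(c(x1, 900 - x1), c(x2, 900 - x2)))$p_value < 0.05
  })
  expect_gt(mean(hit), 0.8)
})
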