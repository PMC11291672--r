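# independent oracles, kept deliberately separate from the implementation's
# code paths (different formulas, brute-force enumeration)

# exact p for a 2-row table by enumeration with the product-of-binomials
# hypergeometric formula P(x) = prod_j choose(c_j, x_j) / choose(n, r1)
oracle_exact_2xc <- function(tab) {
  r1 <- sum(tab[1, ]); cmarg <- colSums(tab); n <- sum(tab)
  k <- length(cmarg)
  grid <- expand.grid(lapply(cmarg, function(cj) 0:cj))
  grid <- as.matrix(grid[rowSums(grid) == r1, , drop = FALSE])
  lp <- rowSums(sapply(seq_len(k), function(j)
    lchoose(cmarg[j], grid[, j]))) - lchoose(n, r1)
  lp_obs <- sum(lchoose(cmarg, tab[1, ])) - lchoose(n, r1)
  sum(exp(lp[lp <= lp_obs + 1e-7]))
}

# signed-rank tail probabilities by brute force over all 2^n sign vectors
oracle_signed_rank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(mask) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[bits == 1])
  }, numeric(1))
  less <- mean(sums <= W); greater <- mean(sums >= W)
  switch(alternative, less = less, greater = greater,
         two.sided = min(1, 2 * min(less, greater)))
}

# maximum over the haplotype-frequency simplex of the observed-data
# log-likelihood, by grid search: a coarse full-simplex sweep plus a fine
# one-dimensional profile in pAB with allele frequencies fixed at their
# sample values (the likelihood is constant in the margins at the optimum)
oracle_grid_loglik <- local({
  coarse_grid <- NULL
  function(counts, coarse_step = 0.01, fine_step = 1e-5) {
    counts <- as.matrix(counts)
    n <- sum(counts)
    ll <- function(H) {  # H: matrix of rows (pAB, pAb, paB, pab)
      p11 <- H[, 1]; p10 <- H[, 2]; p01 <- H[, 3]; p00 <- H[, 4]
      G <- cbind(p00^2, 2 * p00 * p01, p01^2,
                 2 * p00 * p10, 2 * (p00 * p11 + p01 * p10), 2 * p01 * p11,
                 p10^2, 2 * p10 * p11, p11^2)
      # counts laid out to match: rows dosage A 0,1,2 x cols dosage B 0,1,2
      cnt <- c(counts[1, 1], counts[1, 2], counts[1, 3],
               counts[2, 1], counts[2, 2], counts[2, 3],
               counts[3, 1], counts[3, 2], counts[3, 3])
      lg <- log(G)
      lg[, cnt == 0] <- 0
      as.vector(lg %*% cnt)
    }
    if (is.null(coarse_grid)) {
      s <- round(1 / coarse_step)
      g <- expand.grid(i = 0:s, j = 0:s, k = 0:s)
      g <- g[g$i + g$j + g$k <= s, ]
      coarse_grid <<- cbind(g$i, g$j, g$k, s - g$i - g$j - g$k) / s
    }
    best <- max(ll(coarse_grid))
    pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * n)
    pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    pAB <- seq(lo, hi, by = fine_step)
    H <- cbind(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    H[H < 0] <- 0
    max(best, max(ll(H)))
  }
})
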