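REL_TIE_TOL <- 1e-7  # relative tolerance when comparing table probabilities

#' Two-sided Fisher exact test for a 2x2 table by complete enumeration
#'
#' Enumerates the hypergeometric distribution of the top-left cell given the
#' table margins and sums the probabilities of all tables at most as
#' probable as the observed one (point-probability rule, the common Fisher
#' convention). Tables with a zero margin are degenerate: no evidence either
#' way, p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return list with \code{p_value}, \code{degenerate}, and the observed
#'   table probability \code{prob_obs}.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab); r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    return(list(p_value = 1, degenerate = TRUE, prob_obs = 1))
  x <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- stats::dhyper(x, c1, n - c1, r1, log = TRUE)
  lp_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1, log = TRUE)
  p <- sum(exp(lp[lp <= lp_obs + REL_TIE_TOL]))
  list(p_value = min(1, p), degenerate = FALSE, prob_obs = exp(lp_obs))
}

# log multivariate-hypergeometric probability of a table given its margins
log_prob_table <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# all first-row vectors x (sum r1, 0 <= x_j <= c_j) for a 2-row table,
# as a matrix with one row per candidate table
first_row_candidates <- function(r1, cmarg) {
  k <- length(cmarg)
  grids <- lapply(cmarg[-k], function(cj) 0:min(r1, cj))
  g <- as.matrix(expand.grid(grids))
  last <- r1 - rowSums(g)
  keep <- last >= 0 & last <= cmarg[k]
  cbind(g[keep, , drop = FALSE], last[keep])
}

#' Exact test for a small r x c contingency table (Freeman-Halton)
#'
#' Generalises the Fisher exact test by complete enumeration of all tables
#' with the observed margins, summing the multivariate hypergeometric
#' probabilities of tables at most as probable as the observed one
#' (two-sided point-probability rule). Used for genotype (2 periods x 3
#' dosage classes) tables of temporal differentiation.
#'
#' @param tab matrix of non-negative integer counts (2 x c fully vectorised;
#'   other shapes enumerated recursively)
#' @param max_tables refuse complete enumeration beyond this many candidate
#'   tables unless a Monte Carlo fallback is supplied
#' @param monte_carlo optional list(B = replicates, seed = integer); when
#'   enumeration would exceed \code{max_tables}, estimate p by sampling
#'   tables with fixed margins (stats::r2dtable), with the add-one rule.
#' @return list with \code{p_value}, \code{method} ("enumeration" or
#'   "monte_carlo"), \code{degenerate}, \code{n_tables}.
#' @export
exact_test_rxc <- function(tab, max_tables = 2e6, monte_carlo = NULL) {
  stopifnot(is.matrix(tab), all(tab >= 0))
  rmarg <- rowSums(tab); cmarg <- colSums(tab)
  tab <- tab[rmarg > 0, cmarg > 0, drop = FALSE]
  rmarg <- rowSums(tab); cmarg <- colSums(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p_value = 1, method = "enumeration", degenerate = TRUE,
                n_tables = 1L))
  lp_obs <- log_prob_table(tab)

  est <- prod(pmin(rmarg[1], cmarg[-length(cmarg)]) + 1)
  if (nrow(tab) == 2 && est <= max_tables) {
    xs <- first_row_candidates(rmarg[1], cmarg)
    # log-prob of each candidate table from its first row
    lp <- sum(lgamma(rmarg + 1)) + sum(lgamma(cmarg + 1)) -
      lgamma(sum(tab) + 1) -
      rowSums(lgamma(xs + 1) + lgamma(sweep(-xs, 2, cmarg, "+") + 1))
    p <- sum(exp(lp[lp <= lp_obs + REL_TIE_TOL]))
    return(list(p_value = min(1, p), method = "enumeration",
                degenerate = FALSE, n_tables = nrow(xs)))
  }
  if (nrow(tab) > 2) {
    acc <- new.env(); acc$p <- 0; acc$n <- 0L
    enumerate_rec(rmarg, cmarg, numeric(0), acc, lp_obs, max_tables)
    return(list(p_value = min(1, acc$p), method = "enumeration",
                degenerate = FALSE, n_tables = acc$n))
  }
  if (is.null(monte_carlo))
    stop("table too large for complete enumeration (~", format(est),
         " tables); supply monte_carlo = list(B, seed) for a seeded ",
         "permutation fallback")
  set.seed(monte_carlo$seed)
  sims <- stats::r2dtable(monte_carlo$B, rmarg, cmarg)
  lp <- vapply(sims, log_prob_table, numeric(1))
  p <- (1 + sum(lp <= lp_obs + REL_TIE_TOL)) / (monte_carlo$B + 1)
  list(p_value = p, method = "monte_carlo", degenerate = FALSE,
       n_tables = monte_carlo$B)
}

# depth-first enumeration over rows for tables with > 2 rows (toy sizes)
enumerate_rec <- function(rmarg, cmarg, rows_so_far, acc, lp_obs, max_tables) {
  if (length(rmarg) == 1) {
    tab <- matrix(c(rows_so_far, cmarg), nrow = length(rows_so_far) /
                    length(cmarg) + 1, byrow = TRUE)
    lp <- log_prob_table(tab)
    acc$n <- acc$n + 1L
    if (acc$n > max_tables) stop("enumeration exceeded max_tables")
    if (lp <= lp_obs + REL_TIE_TOL) acc$p <- acc$p + exp(lp)
    return(invisible())
  }
  xs <- first_row_candidates(rmarg[1], cmarg)
  for (i in seq_len(nrow(xs)))
    enumerate_rec(rmarg[-1], cmarg - xs[i, ], c(rows_so_far, xs[i, ]),
                  acc, lp_obs, max_tables)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via \code{stats::p.adjust}.
#'
#' @param p numeric vector of p values in [0, 1]
#' @return adjusted p values (empty input gives empty output)
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Exact two-sided sign test
#'
#' Binomial(n, 1/2) test of whether paired differences are equally likely to
#' go either way: p = 2 * min(P(X <= k), P(X >= k)), capped at 1.
#'
#' @param k number of decreases (successes)
#' @param n number of non-zero pairs
#' @return list with \code{p_value}, \code{k}, \code{n}
#' @export
sign_test <- function(k, n) {
  if (n < 1) stop("sign test requires n >= 1")
  stopifnot(k >= 0, k <= n)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(p_value = min(1, 2 * min(lower, upper)), k = k, n = n)
}

#' Wilcoxon signed-rank test with exact small-sample p
#'
#' Zero differences are discarded (their count is reported). With at most 15
#' non-zero differences and no ties among their absolute values the p value
#' is exact, from complete enumeration of the 2^n equally likely sign
#' assignments of the ranks; otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param d paired differences (for temporal use, frequency in the later
#'   period minus the earlier one, so \code{alternative = "less"} tests for
#'   a decrease)
#' @param alternative "less", "greater" or "two.sided"
#' @return list with \code{p_value}, \code{statistic} (W, rank sum of
#'   positive differences), \code{n}, \code{n_zero}, \code{exact},
#'   \code{degenerate}
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("less", "greater",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(d))
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p_value = 1, statistic = NA_real_, n = 0L, n_zero = n_zero,
                exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 15 && !ties) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)  # all 2^n possible W values
    less <- mean(sums <= W); greater <- mean(sums >= W)
    p <- switch(alternative, less = less, greater = greater,
                two.sided = min(1, 2 * min(less, greater)))
    return(list(p_value = p, statistic = W, n = n, n_zero = n_zero,
                exact = TRUE, degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tie_tab^3 - tie_tab) / 48)
  if (sigma == 0)
    return(list(p_value = 1, statistic = W, n = n, n_zero = n_zero,
                exact = FALSE, degenerate = TRUE))
  less <- stats::pnorm((W - mu + 0.5) / sigma)
  greater <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  p <- switch(alternative, less = less, greater = greater,
              two.sided = min(1, 2 * min(less, greater)))
  list(p_value = p, statistic = W, n = n, n_zero = n_zero,
       exact = FALSE, degenerate = FALSE)
}
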