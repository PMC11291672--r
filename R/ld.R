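#' Cross-tabulate dosages at two loci
#'
#' @param da,db integer dosage vectors (0, 1, 2, NA) for the same individuals
#' @return 3x3 matrix of joint dosage counts (rows: locus A dosage 0/1/2,
#'   columns: locus B), over individuals called at both loci.
#' @export
two_locus_counts <- function(da, db) {
  ok <- !is.na(da) & !is.na(db)
  table(factor(da[ok], levels = 0:2), factor(db[ok], levels = 0:2))
}

# P(genotype dosage pair | haplotype frequencies) under random union of
# gametes; h = (pAB, pAb, paB, pab), A/B = robusta allele at each locus
genotype_probs <- function(h) {
  a <- c(1, 1, 0, 0)  # robusta dose at locus A per haplotype
  b <- c(1, 0, 1, 0)
  G <- matrix(0, 3, 3)
  for (k in 1:4) for (l in 1:4)
    G[a[k] + a[l] + 1, b[k] + b[l] + 1] <-
      G[a[k] + a[l] + 1, b[k] + b[l] + 1] + h[k] * h[l]
  G
}

loglik_counts <- function(counts, h) {
  G <- genotype_probs(h)
  sum(counts[counts > 0] * log(G[counts > 0]))
}

#' EM estimation of two-locus haplotype frequencies and r2
#'
#' Maximum-likelihood haplotype frequencies from unphased diploid genotype
#' counts (Hill-type EM). All genotype classes except the double
#' heterozygote resolve into known gametes; the double heterozygotes are
#' split between the two phase resolutions in proportion to the current
#' haplotype-frequency products, iterating from the linkage-equilibrium
#' start until the largest haplotype-frequency change drops below
#' \code{tol}. Exactly tied products split 50/50, the deterministic
#' resolution of the EM saddle, which leaves D = 0.
#'
#' @param counts 3x3 joint dosage table (see \code{\link{two_locus_counts}})
#' @param tol convergence tolerance on haplotype frequencies
#' @param max_iter iteration cap
#' @param debug if TRUE, assert that the observed-data log-likelihood never
#'   decreases across iterations
#' @return object of class \code{ld_estimate}: haplotype frequencies
#'   \code{hap} (pAB, pAb, paB, pab), \code{D}, \code{r2} (NA when either
#'   locus is monomorphic), \code{n}, \code{loglik}, \code{iterations},
#'   \code{converged}.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-8, max_iter = 1000,
                               debug = FALSE) {
  counts <- unclass(as.matrix(counts))
  stopifnot(all(dim(counts) == 3), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no individuals called at both loci")
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * n)          # row dosage
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))

  # fixed gamete contributions from unambiguous cells (per 2n gametes):
  # indices: 1 = AB, 2 = Ab, 3 = aB, 4 = ab
  fixed <- c(
    AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
    Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    aB = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  dh <- counts[2, 2]  # double heterozygotes
  ll <- loglik_counts(counts, h)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    num <- h[1] * h[4]
    den <- num + h[2] * h[3]
    q <- if (den > 0) num / den else 0.5  # P(phase AB/ab | double het)
    exp_counts <- fixed + dh * c(q, 1 - q, 1 - q, q)
    h_new <- exp_counts / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (debug) {
      ll_new <- loglik_counts(counts, h)
      stopifnot(ll_new >= ll - 1e-9)
      ll <- ll_new
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  h <- unname(h)
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  structure(list(hap = stats::setNames(h, c("pAB", "pAb", "paB", "pab")),
                 D = D, r2 = r2, n = n,
                 loglik = loglik_counts(counts, h),
                 iterations = iter, converged = converged),
            class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat("Two-locus LD estimate (EM, n =", x$n, "individuals)\n")
  cat("  haplotype freqs:",
      paste(names(x$hap), sprintf("%.4f", x$hap), sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  D = %.4f   r2 = %s   (%d iterations%s)\n", x$D,
              ifelse(is.na(x$r2), "undefined (monomorphic locus)",
                     sprintf("%.4f", x$r2)),
              x$iterations, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Pairwise r2 over island markers, per population and period
#'
#' Computes EM-based r2 for every island marker pair, for each (population,
#' period) whose robusta allele frequency at the core marker exceeds
#' \code{min_core_freq} (diversity is too low elsewhere for LD to be
#' informative; retention is decided per period on that period's core
#' frequency). Optionally adds rows for all retained populations of a period
#' pooled together, under population id \code{"(pooled)"}.
#'
#' @param gm a \code{genotype_matrix}; restricted to pure C. intestinalis
#'   individuals when a species_class column is present
#' @param min_core_freq inclusion threshold on the core robusta frequency
#' @param pooled also compute pooled-individual estimates per period
#' @return long data.frame: population_id, period, marker_a, marker_b,
#'   pair_class, n, D, r2, converged; attribute \code{retained} lists the
#'   (population, period) combinations kept.
#' @export
ld_matrices <- function(gm, min_core_freq = 0.05, pooled = FALSE) {
  gm <- native_subset(gm)
  panel <- gm$panel
  d <- effective_dosage(gm)
  s <- gm$samples
  core <- attr(panel, "core_marker_id")
  pairs <- island_pairs(panel)

  retained <- list()
  for (per in unique(s$period)) {
    for (pop in unique(s$population_id[s$period == per])) {
      rows <- s$period == per & s$population_id == pop
      dc <- d[rows, core]
      called <- sum(!is.na(dc))
      f <- if (called > 0) sum(dc, na.rm = TRUE) / (2 * called) else NA_real_
      if (!is.na(f) && f > min_core_freq)
        retained[[length(retained) + 1L]] <- list(pop = pop, per = per,
                                                  rows = which(rows))
    }
  }
  if (!length(retained)) {
    warning("no population passes the core-frequency filter")
    out <- data.frame(population_id = character(), period = character(),
                      marker_a = character(), marker_b = character(),
                      pair_class = character(), n = integer(), D = numeric(),
                      r2 = numeric(), converged = logical())
    attr(out, "retained") <- data.frame(population_id = character(),
                                        period = character())
    return(out)
  }
  if (pooled)
    for (per in unique(vapply(retained, `[[`, character(1), "per")))
      retained[[length(retained) + 1L]] <- list(
        pop = "(pooled)", per = per,
        rows = unlist(lapply(retained, function(g)
          if (g$per == per && g$pop != "(pooled)") g$rows)))

  out <- lapply(retained, function(g) {
    est <- lapply(seq_len(nrow(pairs)), function(i) {
      cc <- two_locus_counts(d[g$rows, pairs$marker_a[i]],
                             d[g$rows, pairs$marker_b[i]])
      if (sum(cc) == 0)
        return(list(n = 0L, D = NA_real_, r2 = NA_real_, converged = NA))
      em_haplotype_freqs(cc)
    })
    data.frame(population_id = g$pop, period = g$per,
               marker_a = pairs$marker_a, marker_b = pairs$marker_b,
               pair_class = pairs$pair_class,
               n = vapply(est, function(e) as.integer(e$n), integer(1)),
               D = vapply(est, function(e) as.numeric(e$D), numeric(1)),
               r2 = vapply(est, function(e) as.numeric(e$r2), numeric(1)),
               converged = vapply(est, function(e) as.logical(e$converged),
                                  logical(1)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "retained") <- unique(res[, c("population_id", "period")])
  res
}

#' Mean r2 for a period under a declared aggregation
#'
#' The primary aggregation ("population_pair") is the unweighted mean over
#' all defined (population, pair) r2 values for the period. Alternatives:
#' "pair_means" first averages each pair across populations, then averages
#' pairs; "pooled" uses the pooled-individuals estimates (requires
#' \code{ld_matrices(..., pooled = TRUE)}).
#'
#' @param ld long data.frame from \code{\link{ld_matrices}}
#' @param period period label
#' @param method aggregation
#' @return mean r2 (NA if no defined value)
#' @export
mean_r2 <- function(ld, period,
                    method = c("population_pair", "pair_means", "pooled")) {
  method <- match.arg(method)
  x <- ld[ld$period == period, , drop = FALSE]
  if (method == "pooled") {
    x <- x[x$population_id == "(pooled)", , drop = FALSE]
    return(mean(x$r2, na.rm = TRUE))
  }
  x <- x[x$population_id != "(pooled)", , drop = FALSE]
  if (method == "population_pair") return(mean(x$r2, na.rm = TRUE))
  per_pair <- tapply(x$r2, paste(x$marker_a, x$marker_b),
                     mean, na.rm = TRUE)
  mean(per_pair, na.rm = TRUE)
}

#' Temporal comparison of r2 matrices between two periods
#'
#' For each island pair, averages r2 across retained populations within each
#' period, takes the difference (later minus earlier), and summarises the
#' direction of change within each pair class (core-shoulder, left-shoulder,
#' right-shoulder, cross-shoulder) with a two-sided exact sign test and a
#' one-sided Wilcoxon signed-rank test for a decrease. Per-pair counts of
#' populations decreasing/increasing (over populations retained in both
#' periods) are also reported.
#'
#' @param ld long data.frame from \code{\link{ld_matrices}}
#' @param periods length-2 character vector, earlier then later
#' @return list with \code{deltas} (per pair), \code{class_tests} (per pair
#'   class plus "all"), and \code{n_pairs_decreased} /
#'   \code{n_pairs_compared} overall.
#' @export
ld_temporal_compare <- function(ld, periods) {
  stopifnot(length(periods) == 2)
  x <- ld[ld$population_id != "(pooled)", , drop = FALSE]
  pair_key <- paste(x$marker_a, x$marker_b, sep = "|")
  pairs <- unique(data.frame(pair = pair_key, marker_a = x$marker_a,
                             marker_b = x$marker_b,
                             pair_class = x$pair_class,
                             stringsAsFactors = FALSE))
  deltas <- lapply(seq_len(nrow(pairs)), function(i) {
    xi <- x[pair_key == pairs$pair[i], , drop = FALSE]
    m1 <- mean(xi$r2[xi$period == periods[1]], na.rm = TRUE)
    m2 <- mean(xi$r2[xi$period == periods[2]], na.rm = TRUE)
    # populations retained and defined in both periods, for the cell counts
    w <- merge(xi[xi$period == periods[1] & !is.na(xi$r2),
                  c("population_id", "r2")],
               xi[xi$period == periods[2] & !is.na(xi$r2),
                  c("population_id", "r2")], by = "population_id")
    data.frame(marker_a = pairs$marker_a[i], marker_b = pairs$marker_b[i],
               pair_class = pairs$pair_class[i],
               r2_mean_1 = m1, r2_mean_2 = m2, delta = m2 - m1,
               n_pop_decrease = sum(w$r2.y < w$r2.x),
               n_pop_increase = sum(w$r2.y > w$r2.x),
               stringsAsFactors = FALSE)
  })
  deltas <- do.call(rbind, deltas)
  defined <- !is.na(deltas$delta)
  dropped <- sum(!defined)
  if (dropped) message(dropped, " pair(s) missing in one period excluded")
  dd <- deltas[defined, , drop = FALSE]

  summarise_class <- function(sub, label) {
    nz <- sub$delta != 0
    k <- sum(sub$delta < 0)
    st <- if (any(nz)) sign_test(sum(sub$delta[nz] < 0), sum(nz)) else
      list(p_value = 1)
    wt <- wilcoxon_signed_rank(sub$delta, alternative = "less")
    data.frame(pair_class = label, n_pairs = nrow(sub), n_decrease = k,
               sign_p = st$p_value, wilcoxon_p = wt$p_value,
               degenerate = !any(nz), stringsAsFactors = FALSE)
  }
  classes <- intersect(c("core_shoulder", "left_shoulder", "right_shoulder",
                         "cross_shoulder"), unique(dd$pair_class))
  class_tests <- do.call(rbind, c(
    lapply(classes, function(cl)
      summarise_class(dd[dd$pair_class == cl, , drop = FALSE], cl)),
    list(summarise_class(dd, "all"))))
  list(deltas = deltas, class_tests = class_tests,
       n_pairs_decreased = sum(dd$delta < 0), n_pairs_compared = nrow(dd))
}
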