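#' Configuration of the introgression-island forward simulator
#'
#' Encodes the generative model behind the temporal analysis: a single
#' recipient-species deme of N diploids carrying an introgressed island. The
#' alien core allele is favoured (selection coefficient \code{s_core}) but
#' opposed by immigration of non-introgressed natives at rate \code{m}
#' (migration-selection balance); alien shoulder alleles are mildly
#' deleterious hitchhikers (\code{s_del} per locus) that recombination
#' progressively uncouples from the core, so their frequency erodes while
#' the core stays near equilibrium. Two cohorts are sampled \code{gap}
#' generations apart, mirroring a resampling design ~20 generations apart.
#'
#' The default selection, migration and recombination coefficients are
#' illustrative, chosen once so that the default scenario reproduces the
#' qualitative erosion signature (stable core, declining shoulders, falling
#' core-shoulder LD): \code{m} balances \code{s_core} so that \code{p0} is
#' close to the migration-selection equilibrium of the core allele (per-
#' generation gamete-frequency gain about s*q, offset by immigration loss
#' about m/(1-m)), the per-locus hitchhiker burden is light enough that the
#' core is not dragged far from equilibrium while shoulders remain attached,
#' and the crossover rate (about 8 cM/Mb) leaves the shoulders mid-erosion
#' at the first sampling. See the methods vignette for the reasoning.
#'
#' @param panel a \code{kasp_panel}; the island marker map (positions in bp)
#'   defines the recombination distances
#' @param N diploid population size
#' @param s_core selection coefficient favouring the alien core allele
#' @param s_del per-locus selection against alien shoulder alleles
#' @param m fraction of haplotypes replaced by all-native immigrants per
#'   generation
#' @param p0 initial frequency of full-length alien island haplotypes
#' @param rec_per_bp per-base-pair crossover probability per meiosis
#' @param burn_in generations before the first sample
#' @param gap generations between the two samples
#' @param n_sample individuals sampled per period
#' @param channel_high,channel_low fluorescence means of the strong and weak
#'   channel of a homozygote cluster (heterozygotes sit at their midpoint on
#'   both channels)
#' @param noise_sd Gaussian fluorescence noise, truncated at 0
#' @param seed integer RNG seed
#' @return a \code{sim_config} list
#' @export
sim_config <- function(panel, N = 2000, s_core = 0.2, s_del = 0.005, m = 0.13,
                       p0 = 0.3, rec_per_bp = 8e-8, burn_in = 30, gap = 20,
                       n_sample = 400, channel_high = 1000, channel_low = 50,
                       noise_sd = 40, seed = 1) {
  stopifnot(inherits(panel, "kasp_panel"), N >= 2, n_sample <= N,
            s_core >= 0, s_core <= 1, s_del >= 0, s_del <= 1,
            m >= 0, m <= 1, p0 >= 0, p0 <= 1, rec_per_bp >= 0,
            burn_in >= 0, gap >= 0, noise_sd >= 0,
            channel_high > channel_low, channel_low >= 0)
  im <- island_markers(panel)
  rec <- diff(im$position_bp) * rec_per_bp
  if (any(rec > 0.5)) rec <- pmin(rec, 0.5)
  cfg <- list(panel = panel, N = as.integer(N), s_core = s_core,
              s_del = s_del, m = m, p0 = p0, rec_per_bp = rec_per_bp,
              rec = rec, markers = im$marker_id,
              core_idx = which(im$region == "core"),
              shoulder_idx = which(im$region %in%
                                     c("left_shoulder", "right_shoulder")),
              burn_in = as.integer(burn_in), gap = as.integer(gap),
              n_sample = as.integer(n_sample),
              channel_high = channel_high, channel_low = channel_low,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Initial haplotype pool
#'
#' The starting state is post-introgression, pre-erosion: round(p0 * 2N)
#' haplotypes are alien along the whole island (full-length introgressed
#' tracts), the rest fully native, so the initial alien frequency is p0 at
#' every marker.
#'
#' @param config a \code{sim_config}
#' @return 2N x L binary matrix (1 = alien allele), columns named by marker
#' @export
initialize_population <- function(config) {
  L <- length(config$markers)
  n_alien <- round(config$p0 * 2 * config$N)
  if (n_alien < 1)
    stop("p0 * 2N < 1: no introgressed haplotype to track")
  pool <- matrix(0L, nrow = 2 * config$N, ncol = L,
                 dimnames = list(NULL, config$markers))
  pool[seq_len(n_alien), ] <- 1L
  pool
}

# one gamete per parent: parent = (hap1, hap2) rows; vectorised over parents
meiose <- function(h1, h2, rec) {
  np <- nrow(h1); L <- ncol(h1)
  # which parental haplotype contributes at each marker: start uniform,
  # switch between adjacent markers with the interval's crossover probability
  cur <- stats::runif(np) < 0.5
  use1 <- matrix(NA, np, L)
  use1[, 1] <- cur
  for (j in seq_len(L - 1)) {
    cross <- stats::runif(np) < rec[j]
    cur <- xor(cur, cross)
    use1[, j + 1] <- cur
  }
  out <- h2
  out[use1] <- h1[use1]
  out
}

#' Advance the population one Wright-Fisher generation
#'
#' Immigration (a Binomial(2N, m) draw of haplotypes replaced by all-native
#' immigrants), random pairing into diploids, multiplicative fitness
#' w = (1 + s_core)^(core dosage) * (1 - s_del)^(total alien shoulder
#' dosage), parent sampling proportional to w, and meiosis with independent
#' per-interval crossovers (probability = inter-marker distance x per-bp
#' rate, no interference).
#'
#' @param pool 2N x L haplotype matrix
#' @param config a \code{sim_config}
#' @return the next generation's 2N x L haplotype matrix
#' @export
step_generation <- function(pool, config) {
  n_hap <- nrow(pool)
  n_imm <- stats::rbinom(1, n_hap, config$m)
  if (n_imm > 0)
    pool[sample.int(n_hap, n_imm), ] <- 0L
  # random pairing into N diploids
  ord <- sample.int(n_hap)
  h1 <- pool[ord[seq(1, n_hap, by = 2)], , drop = FALSE]
  h2 <- pool[ord[seq(2, n_hap, by = 2)], , drop = FALSE]
  core_dos <- h1[, config$core_idx] + h2[, config$core_idx]
  sh_dos <- if (length(config$shoulder_idx))
    rowSums(h1[, config$shoulder_idx, drop = FALSE]) +
      rowSums(h2[, config$shoulder_idx, drop = FALSE]) else 0
  w <- (1 + config$s_core)^core_dos * (1 - config$s_del)^sh_dos
  mothers <- sample.int(config$N, config$N, replace = TRUE, prob = w)
  fathers <- sample.int(config$N, config$N, replace = TRUE, prob = w)
  g1 <- meiose(h1[mothers, , drop = FALSE], h2[mothers, , drop = FALSE],
               config$rec)
  g2 <- meiose(h1[fathers, , drop = FALSE], h2[fathers, , drop = FALSE],
               config$rec)
  out <- rbind(g1, g2)
  colnames(out) <- colnames(pool)
  out
}

# r2 between phased haplotype columns (gametic truth)
gametic_r2 <- function(pool) {
  p <- colMeans(pool)
  poly <- p > 0 & p < 1
  L <- ncol(pool)
  r2 <- matrix(NA_real_, L, L, dimnames = list(colnames(pool),
                                               colnames(pool)))
  if (sum(poly) >= 2) {
    cc <- suppressWarnings(stats::cor(pool[, poly, drop = FALSE]))
    r2[poly, poly] <- cc^2
  }
  r2
}

#' Run a full sweep-erosion scenario
#'
#' Initialises the pool, records the truth every generation (per-marker
#' alien frequency and per-pair gametic r2), samples \code{n_sample}
#' individuals after \code{burn_in} generations (first period) and again
#' \code{gap} generations later (second period). A scenario in which the
#' alien core allele is lost is flagged, not discarded: extinction is a
#' biologically meaningful outcome.
#'
#' @param config a \code{sim_config}
#' @param period_labels labels for the two sampling periods
#' @return object of class \code{sweep_scenario}: \code{truth} (frequency
#'   trajectory, list of gametic r2 matrices at the two sampling
#'   generations), \code{cohorts} (list of true-dosage matrices per period),
#'   \code{core_extinct} flag, and the config.
#' @export
run_scenario <- function(config, period_labels = c("2012", "2021")) {
  set.seed(config$seed)
  pool <- initialize_population(config)
  n_gen <- config$burn_in + config$gap
  freq <- matrix(NA_real_, n_gen + 1, ncol(pool),
                 dimnames = list(NULL, colnames(pool)))
  freq[1, ] <- colMeans(pool)
  pool_a <- pool  # first-period state when burn_in == 0
  for (g in seq_len(n_gen)) {
    pool <- step_generation(pool, config)
    freq[g + 1, ] <- colMeans(pool)
    if (g == config$burn_in) pool_a <- pool
  }
  pool_b <- pool

  sample_cohort <- function(p) {
    ind <- sample.int(config$N, config$n_sample)
    h1 <- p[2 * ind - 1, , drop = FALSE]
    h2 <- p[2 * ind, , drop = FALSE]
    dos <- h1 + h2
    rownames(dos) <- NULL
    dos
  }
  # diploids are consecutive haplotype rows (2i-1, 2i)
  cohort_a <- sample_cohort(pool_a)
  cohort_b <- sample_cohort(pool_b)
  cohorts <- stats::setNames(list(cohort_a, cohort_b), period_labels)
  structure(list(
    truth = list(freq = freq,
                 r2 = stats::setNames(list(gametic_r2(pool_a),
                                           gametic_r2(pool_b)),
                                      period_labels)),
    cohorts = cohorts,
    core_extinct = freq[n_gen + 1, config$core_idx] == 0,
    config = config), class = "sweep_scenario")
}

#' @export
print.sweep_scenario <- function(x, ...) {
  cfg <- x$config
  cat("Sweep-erosion scenario: N =", cfg$N, ",", cfg$burn_in, "+", cfg$gap,
      "generations,", cfg$n_sample, "individuals/period\n")
  f <- x$truth$freq
  cat(sprintf("  core alien frequency: %.3f -> %.3f -> %.3f (start, sample 1, sample 2)%s\n",
              f[1, cfg$core_idx], f[cfg$burn_in + 1, cfg$core_idx],
              f[nrow(f), cfg$core_idx],
              if (x$core_extinct) "  [core allele EXTINCT]" else ""))
  invisible(x)
}

#' Run replicate scenarios with a reproducible seed manifest
#'
#' Replicate streams are derived from the config seed by fixed increments,
#' so any single replicate can be re-run independently.
#'
#' @param config a \code{sim_config} (its seed is the base seed)
#' @param n_rep number of replicates
#' @return list with \code{scenarios} (list of \code{sweep_scenario}) and
#'   \code{manifest} (data.frame replicate, seed, core_extinct)
#' @export
run_replicates <- function(config, n_rep) {
  seeds <- config$seed + seq_len(n_rep)
  scenarios <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    run_scenario(cfg)
  })
  list(scenarios = scenarios,
       manifest = data.frame(replicate = seq_len(n_rep), seed = seeds,
                             core_extinct = vapply(scenarios, `[[`,
                                                   logical(1),
                                                   "core_extinct")))
}

# channel means for a robusta-allele dosage
dosage_channels <- function(dosage, high, low) {
  mid <- (high + low) / 2
  f_rob <- ifelse(dosage == 2, high, ifelse(dosage == 1, mid, low))
  f_int <- ifelse(dosage == 0, high, ifelse(dosage == 1, mid, low))
  cbind(f_rob, f_int)
}

#' Emit pipeline-ready fluorescence records for simulated cohorts
#'
#' The measurement forward model: each sampled individual gets one simplex
#' record per chromosome-5 marker and the mitochondrial marker (channel
#' means set by true dosage, Gaussian noise truncated at zero), plus one
#' multiplex record whose robusta channel is proportional to the total
#' alien dosage over the 11 multiplex loci (zero here: simulated
#' individuals are natives outside the island). Four control wells per run
#' mirror the plate design: one robusta, one non-introgressed intestinalis
#' and two introgressed intestinalis (heterozygous across the island), so
#' per-run cutoffs can be calibrated exactly as for real plates.
#'
#' @param scenario a \code{sweep_scenario}
#' @param population_id population label for the emitted records
#' @return data.frame in the \code{\link{read_fluorescence}} layout
#' @export
emit_fluorescence <- function(scenario, population_id = "simdeme") {
  cfg <- scenario$config
  panel <- cfg$panel
  hi <- cfg$channel_high; lo <- cfg$channel_low; sd <- cfg$noise_sd
  set.seed(cfg$seed + 7919L)  # measurement noise stream, distinct from WF

  simplex_markers <- panel$marker_id[!(panel$region %in% "multiplex_member")]
  island <- cfg$markers
  rows <- list()
  emit <- function(ind, popid, per, run, assay, dosage, is_control, cclass,
                   mux_frac = NULL) {
    if (is.null(mux_frac)) {
      ch <- dosage_channels(dosage, hi, lo)
      noise <- sd
    } else {
      # pooled reaction: the 11 assays sum their fluorescence, so the total
      # signal scales with the pool size while noise grows only as sqrt(11)
      n_mux <- length(attr(panel, "multiplex_marker_ids"))
      ch <- n_mux * cbind(lo + (hi - lo) * mux_frac,
                          lo + (hi - lo) * (1 - mux_frac))
      noise <- sd * sqrt(n_mux)
    }
    ch <- ch + matrix(stats::rnorm(length(ch), 0, noise), ncol = 2)
    ch[ch < 0] <- 0
    ch <- unname(ch)
    data.frame(individual_id = ind, population_id = popid, period = per,
               run_id = run, assay_id = assay, f1 = ch[, 1], f2 = ch[, 2],
               is_control = is_control, control_class = cclass,
               stringsAsFactors = FALSE)
  }
  for (per in names(scenario$cohorts)) {
    dos <- scenario$cohorts[[per]]
    n <- nrow(dos)
    ids <- sprintf("%s_%s_%04d", population_id, per, seq_len(n))
    run <- paste0("run_", per)
    for (mk in simplex_markers) {
      d <- if (mk %in% island) dos[, mk] else 0L  # SB / mito: native
      rows[[length(rows) + 1L]] <-
        emit(ids, population_id, per, run, mk, d, FALSE, NA_character_)
    }
    rows[[length(rows) + 1L]] <-
      emit(ids, population_id, per, run, "multiplex", NULL, FALSE,
           NA_character_, mux_frac = rep(0, n))
    # control wells: robusta / plain intestinalis / 2x introgressed
    ctrl <- data.frame(
      id = paste0("CTRL_", run, "_", c("rob", "int", "intro1", "intro2")),
      class = c("robusta", "intestinalis_plain",
                "intestinalis_introgressed", "intestinalis_introgressed"),
      stringsAsFactors = FALSE)
    for (mk in simplex_markers) {
      d <- if (mk %in% island) c(2L, 0L, 1L, 1L) else c(2L, 0L, 0L, 0L)
      rows[[length(rows) + 1L]] <-
        emit(ctrl$id, population_id, per, run, mk, d, TRUE, ctrl$class)
    }
    rows[[length(rows) + 1L]] <-
      emit(ctrl$id, population_id, per, run, "multiplex", NULL, TRUE,
           ctrl$class, mux_frac = c(1, 0, 0, 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$failed <- (out$f1 + out$f2) == 0
  out
}
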