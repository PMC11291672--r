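#' Call genotypes and classify individuals from a fluorescence table
#'
#' The full calling stage: per (run, assay) cutoffs are calibrated from the
#' positive-control wells, every simplex record is converted to an oriented
#' VAFF and called to a robusta-allele dosage, the multiplex records give
#' each individual a hybrid index and nuclear species category, and the
#' mitochondrial call completes the species classification. Control wells
#' are used for calibration only and excluded from the genotype matrix.
#'
#' @param fluor validated fluorescence data.frame
#'   (\code{\link{read_fluorescence}})
#' @param panel a \code{kasp_panel}
#' @param default_cutoffs fallback cutoffs when a run lacks homozygote
#'   controls
#' @param margin near-cutoff band half-width (VAFF scale)
#' @param t_low,t_high hybrid-index category thresholds
#' @param cutoff_overrides optional data.frame (run_id, assay_id, lower,
#'   upper) of manually curated cutoffs that replace the control-derived
#'   ones for matching (run, assay) combinations, so hand curation can be
#'   reproduced exactly
#' @return list: \code{matrix} (a \code{genotype_matrix} whose samples carry
#'   \code{species_class} and \code{hybrid_index}), \code{classifications}
#'   (per individual), \code{cutoffs} (per run x assay, with the cutoffs
#'   actually used and their source), \code{calls} (long per-record call
#'   table for QC).
#' @export
call_pipeline <- function(fluor, panel, default_cutoffs = c(1 / 3, 2 / 3),
                          margin = 0.05, t_low = 0.125, t_high = 0.875,
                          cutoff_overrides = NULL) {
  fluor$robusta_channel <-
    panel$robusta_channel[match(fluor$assay_id, panel$marker_id)]
  fluor$robusta_channel[is.na(fluor$robusta_channel)] <- 1L  # multiplex
  fluor$vaff <- oriented_vaff(fluor$f1, fluor$f2, fluor$robusta_channel)

  # per (run, assay) cutoffs from that run's control wells
  keys <- unique(fluor[, c("run_id", "assay_id")])
  cutoffs <- lapply(seq_len(nrow(keys)), function(i) {
    ctl <- fluor[fluor$is_control & fluor$run_id == keys$run_id[i] &
                   fluor$assay_id == keys$assay_id[i], , drop = FALSE]
    cs <- calibrate_cutoffs(ctl, defaults = default_cutoffs, margin = margin)
    data.frame(run_id = keys$run_id[i], assay_id = keys$assay_id[i],
               lower = cs$lower, upper = cs$upper, margin = cs$margin,
               source = cs$source, stringsAsFactors = FALSE)
  })
  cutoffs <- do.call(rbind, cutoffs)
  if (!is.null(cutoff_overrides)) {
    ov <- match(paste(cutoffs$run_id, cutoffs$assay_id),
                paste(cutoff_overrides$run_id, cutoff_overrides$assay_id))
    hit <- !is.na(ov)
    cutoffs$lower[hit] <- cutoff_overrides$lower[ov[hit]]
    cutoffs$upper[hit] <- cutoff_overrides$upper[ov[hit]]
    cutoffs$source[hit] <- "override"
  }

  samples_f <- fluor[!fluor$is_control, , drop = FALSE]
  ck <- match(paste(samples_f$run_id, samples_f$assay_id),
              paste(cutoffs$run_id, cutoffs$assay_id))
  simplex <- samples_f$assay_id != "multiplex"
  calls <- call_genotype(samples_f$vaff[simplex],
                         list(lower = cutoffs$lower[ck][simplex],
                              upper = cutoffs$upper[ck][simplex],
                              margin = cutoffs$margin[ck][simplex]))
  calls <- cbind(samples_f[simplex, c("individual_id", "population_id",
                                      "period", "run_id", "assay_id")],
                 calls)

  inds <- unique(samples_f[, c("individual_id", "population_id", "period")])
  mk <- unique(calls$assay_id)
  idx <- cbind(match(calls$individual_id, inds$individual_id),
               match(calls$assay_id, mk))
  shape <- function(v, init) {
    m <- matrix(init, nrow(inds), length(mk),
                dimnames = list(inds$individual_id, mk))
    m[idx] <- v
    m
  }
  dosage <- shape(calls$dosage, NA_integer_)
  vaff <- shape(calls$vaff, NA_real_)
  flag <- shape(calls$flag, "failed")

  mux <- samples_f[samples_f$assay_id == "multiplex", , drop = FALSE]
  hyb <- compute_hybrid_index(mux$vaff[match(inds$individual_id,
                                             mux$individual_id)],
                              t_low = t_low, t_high = t_high)
  n_failed_mux <- sum(is.na(hyb$category))
  if (n_failed_mux)
    message(n_failed_mux, " individual(s) without a usable multiplex ",
            "reaction; species category missing")
  mito_id <- attr(panel, "mito_marker_id")
  mito_dos <- if (length(mito_id) && mito_id %in% colnames(dosage))
    dosage[, mito_id] else rep(NA_integer_, nrow(inds))
  cls <- classify_individual(hyb$category, mito_dos)
  classifications <- cbind(inds, hyb, cls)
  rownames(classifications) <- NULL

  inds$species_class <- hyb$category
  inds$hybrid_index <- hyb$hybrid_index
  gm <- genotype_matrix(dosage, inds, panel, vaff = vaff, flag = flag)
  list(matrix = gm, classifications = classifications, cutoffs = cutoffs,
       calls = calls)
}

#' Push one simulated scenario through the whole analysis
#'
#' Convenience wrapper used for validation: emits fluorescence from a
#' scenario, calls and classifies, computes per-period allele frequencies,
#' temporal shoulder changes, and the temporal LD comparison, and returns
#' the qualitative summary quantities the erosion model predicts.
#'
#' @param scenario a \code{sweep_scenario}
#' @param min_core_freq LD population-inclusion threshold
#' @return list with the fitted objects and summary scalars:
#'   \code{core_change} (signed change in core robusta frequency),
#'   \code{mean_shoulder_decline} (mean over shoulder markers of first-period
#'   frequency minus second), \code{n_shoulder_down} / \code{n_shoulder},
#'   \code{n_core_shoulder_r2_down} / \code{n_core_shoulder_pairs},
#'   \code{concordance} (called vs true dosages over island markers).
#' @export
analyze_scenario <- function(scenario, min_core_freq = 0.05) {
  cfg <- scenario$config
  panel <- cfg$panel
  periods <- names(scenario$cohorts)
  fl <- emit_fluorescence(scenario)
  piped <- call_pipeline(fl, panel)
  gm <- piped$matrix

  # concordance of called vs true dosage at island markers
  truth <- do.call(rbind, lapply(periods, function(p) scenario$cohorts[[p]]))
  ord <- order(match(gm$samples$period, periods),
               gm$samples$individual_id)
  called <- gm$dosage[ord, cfg$markers, drop = FALSE]
  concordance <- mean(called == truth, na.rm = TRUE)

  fr <- allele_frequencies(gm, markers = cfg$markers, by = "period")
  core_mk <- attr(panel, "core_marker_id")
  sh_mk <- cfg$markers[cfg$shoulder_idx]
  f1 <- fr[fr$period == periods[1], ]
  f2 <- fr[fr$period == periods[2], ]
  core_change <- f2$robusta_freq[f2$marker_id == core_mk] -
    f1$robusta_freq[f1$marker_id == core_mk]
  sh_delta <- f2$robusta_freq[match(sh_mk, f2$marker_id)] -
    f1$robusta_freq[match(sh_mk, f1$marker_id)]

  ld <- ld_matrices(gm, min_core_freq = min_core_freq)
  cmp <- if (nrow(ld)) ld_temporal_compare(ld, periods) else NULL
  cs <- if (!is.null(cmp))
    cmp$deltas[cmp$deltas$pair_class == "core_shoulder", , drop = FALSE]

  list(matrix = gm, freqs = fr, ld = ld, ld_compare = cmp,
       concordance = concordance,
       core_change = core_change,
       mean_shoulder_decline = mean(-sh_delta, na.rm = TRUE),
       n_shoulder_down = sum(sh_delta < 0, na.rm = TRUE),
       n_shoulder = sum(!is.na(sh_delta)),
       n_core_shoulder_r2_down = if (is.null(cs)) NA_integer_ else
         sum(cs$delta < 0, na.rm = TRUE),
       n_core_shoulder_pairs = if (is.null(cs)) NA_integer_ else
         sum(!is.na(cs$delta)))
}
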