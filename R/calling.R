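#' Variant allele fluorescent fraction (VAFF)
#'
#' The fraction of total two-channel fluorescence carried by the
#' robusta-diagnostic channel, \code{f_rob / (f_rob + f_int)}. Near 1 for
#' robusta homozygotes, near 0 for intestinalis homozygotes, intermediate
#' for heterozygotes; for the pooled multiplex reaction it estimates the
#' genome-wide hybrid index. Scale-invariant in the two channels.
#'
#' @param f1,f2 non-negative fluorescence values (vectorised);
#'   \code{f1} is the robusta-specific channel.
#' @return numeric vector in [0, 1]; NA where f1 + f2 == 0 (failed record).
#' @export
compute_vaff <- function(f1, f2) {
  if (any(f1 < 0, na.rm = TRUE) || any(f2 < 0, na.rm = TRUE))
    stop("fluorescence must be non-negative")
  tot <- f1 + f2
  ifelse(tot > 0, f1 / tot, NA_real_)
}

# VAFF on the robusta-fraction scale regardless of dye orientation
oriented_vaff <- function(f1, f2, robusta_channel) {
  v <- compute_vaff(f1, f2)
  swap <- rep_len(robusta_channel == 2L, length(v))
  v[swap] <- 1 - v[swap]
  v
}

#' Calibrate per-run genotype cutoffs from positive controls
#'
#' Reproduces the geometry of manual cluster calling: the lower cutoff is the
#' midpoint between the intestinalis-homozygote and heterozygote cluster
#' means on the VAFF scale, the upper cutoff the midpoint between
#' heterozygote and robusta-homozygote means. The heterozygote cluster is
#' anchored by introgressed-control wells when these are heterozygous at the
#' assay (VAFF in the middle half between the homozygote means); otherwise it
#' is synthesised as the homozygote-mean midpoint. With either homozygote
#' control missing the configured default cutoffs are used, with a warning.
#'
#' @param controls data.frame of control fluorescence records for one
#'   (run, assay): columns \code{f1}, \code{f2}, \code{control_class},
#'   optionally \code{robusta_channel} (default 1).
#' @param defaults fallback c(lower, upper)
#' @param margin half-width of the near-cutoff uncertainty band on the VAFF
#'   scale; calls closer than this to a cutoff are flagged.
#' @return list with \code{lower}, \code{upper}, \code{margin},
#'   \code{source} ("controls" or "defaults").
#' @export
calibrate_cutoffs <- function(controls, defaults = c(1 / 3, 2 / 3),
                              margin = 0.05) {
  stopifnot(length(defaults) == 2, defaults[1] > 0, defaults[1] < defaults[2],
            defaults[2] < 1, margin >= 0)
  rc <- if (is.null(controls$robusta_channel)) 1L else controls$robusta_channel
  v <- oriented_vaff(controls$f1, controls$f2, rc)
  ok <- !is.na(v)
  cls <- controls$control_class[ok]; v <- v[ok]
  hom_r <- mean(v[cls == "robusta"])
  hom_i <- mean(v[cls == "intestinalis_plain"])
  if (!is.finite(hom_r) || !is.finite(hom_i)) {
    warning("homozygote control(s) missing; using default cutoffs")
    return(list(lower = defaults[1], upper = defaults[2], margin = margin,
                source = "defaults"))
  }
  intro <- v[cls == "intestinalis_introgressed"]
  lo_band <- hom_i + 0.25 * (hom_r - hom_i)
  hi_band <- hom_r - 0.25 * (hom_r - hom_i)
  het_anchor <- intro[intro > lo_band & intro < hi_band]
  het <- if (length(het_anchor)) mean(het_anchor) else (hom_i + hom_r) / 2
  list(lower = (hom_i + het) / 2, upper = (het + hom_r) / 2,
       margin = margin, source = "controls")
}

#' Call a robusta-allele dosage from a VAFF value
#'
#' Dosage 0 below the lower cutoff, 1 between the cutoffs (inclusive), 2
#' above the upper cutoff. Calls within \code{margin} of either cutoff are
#' flagged \code{near_cutoff}; by convention downstream frequency
#' computations treat those as missing while QC output retains them.
#'
#' @param vaff numeric vector in [0, 1] (NA allowed)
#' @param cutoffs list as returned by \code{\link{calibrate_cutoffs}}
#' @return data.frame with columns \code{vaff}, \code{dosage} (integer or
#'   NA) and \code{flag} ("clear", "near_cutoff", "failed").
#' @export
call_genotype <- function(vaff, cutoffs) {
  lo <- cutoffs$lower; hi <- cutoffs$upper; m <- cutoffs$margin
  dosage <- ifelse(is.na(vaff), NA_integer_,
            ifelse(vaff < lo, 0L, ifelse(vaff > hi, 2L, 1L)))
  near <- !is.na(vaff) & (abs(vaff - lo) < m | abs(vaff - hi) < m)
  flag <- ifelse(is.na(vaff), "failed", ifelse(near, "near_cutoff", "clear"))
  data.frame(vaff = vaff, dosage = dosage, flag = flag,
             stringsAsFactors = FALSE)
}

#' Hybrid index from the pooled multiplex reaction
#'
#' The VAFF of the 11-SNP multiplex estimates the fraction of robusta
#' ancestry over the rest of the genome. Under balanced pooling an
#' individual heterozygous at k of the 11 loci has expected VAFF k/22, so
#' the default thresholds 0.125 and 0.875 classify anything heterozygous at
#' three or more multiplex loci as admixed, which captures F1s, F2s and
#' first/second-generation backcrosses.
#'
#' @param vaff multiplex VAFF (vectorised; NA = failed reaction)
#' @param t_low,t_high category thresholds on the hybrid-index scale
#' @return data.frame with \code{hybrid_index} and \code{category}
#'   ("pure_intestinalis", "admixed", "pure_robusta" or NA).
#' @export
compute_hybrid_index <- function(vaff, t_low = 0.125, t_high = 0.875) {
  stopifnot(t_low > 0, t_low < t_high, t_high < 1)
  category <- ifelse(is.na(vaff), NA_character_,
              ifelse(vaff < t_low, "pure_intestinalis",
              ifelse(vaff > t_high, "pure_robusta", "admixed")))
  data.frame(hybrid_index = vaff, category = category,
             stringsAsFactors = FALSE)
}

#' Combine nuclear hybrid index and mitochondrial call into a species class
#'
#' @param category nuclear category from \code{\link{compute_hybrid_index}}
#' @param mito_dosage robusta-allele dosage at the mitochondrial SNP
#'   (haploid in effect: 2 = robusta mitotype, 0 = intestinalis; 1 or NA =
#'   unresolved)
#' @return data.frame with \code{nuclear_category}, \code{mito_allele},
#'   \code{concordant} (NA for admixed or unresolved individuals) and
#'   \code{usable} (FALSE when both sources are missing).
#' @export
classify_individual <- function(category, mito_dosage) {
  mito <- ifelse(is.na(mito_dosage), "missing",
          ifelse(mito_dosage == 2L, "robusta",
          ifelse(mito_dosage == 0L, "intestinalis", "missing")))
  concordant <- ifelse(is.na(category) | category == "admixed" |
                         mito == "missing", NA,
                ifelse(category == "pure_robusta", mito == "robusta",
                       mito == "intestinalis"))
  usable <- !(is.na(category) & mito == "missing")
  data.frame(nuclear_category = category, mito_allele = mito,
             concordant = concordant, usable = usable,
             stringsAsFactors = FALSE)
}
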