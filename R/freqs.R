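# dosages usable for frequency computations: near-cutoff and failed calls
# count as missing (they remain visible in QC output)
effective_dosage <- function(gm) {
  d <- gm$dosage
  if (!is.null(gm$flag)) d[gm$flag != "clear"] <- NA_integer_
  d
}

# restrict a genotype matrix to classified C. intestinalis individuals
native_subset <- function(gm) {
  if (is.null(gm$samples$species_class)) return(gm)
  keep <- !is.na(gm$samples$species_class) &
    gm$samples$species_class == "pure_intestinalis"
  subset_gm(gm, keep)
}

subset_gm <- function(gm, keep) {
  genotype_matrix(gm$dosage[keep, , drop = FALSE],
                  gm$samples[keep, , drop = FALSE], gm$panel,
                  vaff = if (!is.null(gm$vaff)) gm$vaff[keep, , drop = FALSE],
                  flag = if (!is.null(gm$flag)) gm$flag[keep, , drop = FALSE])
}

#' Robusta allele frequencies per population and sampling period
#'
#' One record per (population, period, marker): the number of individuals in
#' the sample, the number of successfully called alleles (twice the called
#' individuals; near-cutoff and failed calls are excluded) and the robusta
#' allele frequency. Groups with zero called alleles are reported with an
#' undefined (NA) frequency so downstream tests can exclude them explicitly.
#'
#' @param gm a \code{genotype_matrix}; when its samples carry a
#'   \code{species_class} column, only pure C. intestinalis individuals are
#'   used (the dataset the temporal analyses are defined on).
#' @param markers marker ids to tabulate (default: all matrix columns)
#' @param by "population_period" (default) or "period" for frequencies
#'   pooled over populations
#' @return data.frame of frequency records
#' @export
allele_frequencies <- function(gm, markers = colnames(gm$dosage),
                               by = c("population_period", "period")) {
  by <- match.arg(by)
  gm <- native_subset(gm)
  d <- effective_dosage(gm)[, markers, drop = FALSE]
  s <- gm$samples
  key <- if (by == "period") s$period else paste(s$population_id, s$period,
                                                 sep = "\r")
  out <- list()
  for (g in unique(key)) {
    rows <- key == g
    dg <- d[rows, , drop = FALSE]
    called <- colSums(!is.na(dg))
    rob <- colSums(dg, na.rm = TRUE)
    out[[g]] <- data.frame(
      population_id = if (by == "period") "(all)" else
        sub("\r.*", "", g),
      period = if (by == "period") g else sub(".*\r", "", g),
      marker_id = markers,
      n_individuals = sum(rows),
      n_called_alleles = 2L * called,
      robusta_count = rob,
      robusta_freq = ifelse(called > 0, rob / (2 * called), NA_real_),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$population_id, res$period, match(res$marker_id, markers)), ,
      drop = FALSE]
}

# allele (2x2) and genotype (2x3) period-contrast tables for one marker
temporal_tables <- function(d, periods, marker) {
  geno <- sapply(periods, function(p)
    c(sum(d[[p]] == 0, na.rm = TRUE), sum(d[[p]] == 1, na.rm = TRUE),
      sum(d[[p]] == 2, na.rm = TRUE)))
  geno <- t(geno)  # rows = periods, cols = dosage 0/1/2
  allele <- cbind(robusta = geno[, 2] + 2 * geno[, 3],
                  intestinalis = 2 * geno[, 1] + geno[, 2])
  list(allele = allele, genotype = geno)
}

#' Exact tests of temporal change in allele and genotype counts
#'
#' Per-population scope: for the core marker, each population sampled in
#' both periods is tested for a change in robusta allele counts (2x2
#' complete-enumeration exact test) and in genotype counts (2x3
#' Freeman-Halton test); p values are Benjamini-Hochberg adjusted across
#' populations within each table type. Pooled scope: each island marker is
#' tested over the whole dataset, both as allele and as genotype tables,
#' adjusted across markers. Populations present in only one period are
#' skipped with a message.
#'
#' @param gm a \code{genotype_matrix} (filtered to C. intestinalis when a
#'   species_class column is present)
#' @param periods length-2 character vector, earlier then later period label
#' @param scope "per_population" or "pooled"
#' @param markers marker ids for the pooled scope (default: island markers)
#' @return data.frame with columns scope, group, marker_id, table_type,
#'   p_value, p_adjusted, degenerate
#' @export
temporal_exact_tests <- function(gm, periods,
                                 scope = c("per_population", "pooled"),
                                 markers = NULL) {
  scope <- match.arg(scope)
  stopifnot(length(periods) == 2)
  gm <- native_subset(gm)
  d <- effective_dosage(gm)
  s <- gm$samples
  panel <- gm$panel
  core <- attr(panel, "core_marker_id")

  rows <- list()
  if (scope == "per_population") {
    for (pop in unique(s$population_id)) {
      have <- vapply(periods, function(p)
        any(s$population_id == pop & s$period == p), logical(1))
      if (!all(have)) {
        message("population ", pop, " present in only one period; skipped")
        next
      }
      dl <- lapply(periods, function(p)
        d[s$population_id == pop & s$period == p, core])
      names(dl) <- periods
      tt <- temporal_tables(dl, periods, core)
      r1 <- fisher_exact_2x2(tt$allele)
      r2 <- exact_test_rxc(tt$genotype)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, group = pop, marker_id = core,
        table_type = c("allele", "genotype"),
        p_value = c(r1$p_value, r2$p_value),
        degenerate = c(r1$degenerate, r2$degenerate),
        stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(markers)) markers <- island_markers(panel)$marker_id
    for (mk in markers) {
      dl <- lapply(periods, function(p) d[s$period == p, mk])
      names(dl) <- periods
      tt <- temporal_tables(dl, periods, mk)
      r1 <- fisher_exact_2x2(tt$allele)
      r2 <- exact_test_rxc(tt$genotype)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, group = "(all)", marker_id = mk,
        table_type = c("allele", "genotype"),
        p_value = c(r1$p_value, r2$p_value),
        degenerate = c(r1$degenerate, r2$degenerate),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$p_adjusted <- NA_real_
  for (ty in unique(res$table_type)) {
    i <- res$table_type == ty
    res$p_adjusted[i] <- bh_adjust(res$p_value[i])
  }
  rownames(res) <- NULL
  res
}
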