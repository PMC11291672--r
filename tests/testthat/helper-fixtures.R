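# in-code fixtures shared across test files

toy_panel <- function() {
  kasp_panel(data.frame(
    marker_id = c("L1", "CORE", "R1"),
    chromosome = "chr5",
    position_bp = c(100L, 200L, 300L),
    allele_robusta = c("A", "G", "T"),
    allele_intestinalis = c("G", "A", "C"),
    region = c("left_shoulder", "core", "right_shoulder"),
    stringsAsFactors = FALSE))
}

# genotype matrix built directly from a dosage matrix
gm_from_dosage <- function(dosage, panel, population = "popA",
                           period = "2012", species = "pure_intestinalis") {
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind%03d", seq_len(nrow(dosage)))
  samples <- data.frame(individual_id = rownames(dosage),
                        population_id = rep_len(population, nrow(dosage)),
                        period = rep_len(period, nrow(dosage)),
                        species_class = species,
                        stringsAsFactors = FALSE)
  genotype_matrix(dosage, samples, panel)
}

# draw n diploid genotypes at two loci from known haplotype frequencies;
# returns phased haplotype matrices and the dosage cross-table
draw_two_locus <- function(n, hap) {
  stopifnot(length(hap) == 4, abs(sum(hap) - 1) < 1e-12)
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  h1 <- sample.int(4, n, replace = TRUE, prob = hap)
  h2 <- sample.int(4, n, replace = TRUE, prob = hap)
  list(da = a[h1] + a[h2], db = b[h1] + b[h2], h1 = h1, h2 = h2)
}

# a small fast simulator configuration for pipeline tests
small_config <- function(panel = ciona_panel(), ...) {
  sim_config(panel, N = 150, n_sample = 80, burn_in = 5, gap = 5, ...)
}
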