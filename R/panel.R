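#' @importFrom stats rnorm rbinom runif setNames aggregate complete.cases
#' @importFrom utils read.delim write.table head
NULL

REGIONS <- c("core", "left_shoulder", "right_shoulder", "island_other",
             "background", "mitochondrial", "multiplex_member")
ISLAND_REGIONS <- c("core", "left_shoulder", "right_shoulder", "island_other")
IUPAC <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Construct a validated SNP panel
#'
#' A panel is the marker map that drives every downstream partition of the
#' analysis: which marker is the selected core of the introgression island,
#' which markers sit in its left and right shoulders, which lie outside the
#' island, and which are pooled in the multiplex hybrid-index assay.
#'
#' @param markers data.frame with columns \code{marker_id}, \code{chromosome},
#'   \code{position_bp}, \code{allele_robusta}, \code{allele_intestinalis},
#'   \code{region} and optionally \code{robusta_channel} (1 or 2; which
#'   fluorescence channel reports the robusta-diagnostic allele, default 1).
#' @return An object of class \code{kasp_panel}: the marker data.frame with
#'   island markers sorted by position, plus attributes \code{core_marker_id},
#'   \code{mito_marker_id} and \code{multiplex_marker_ids}.
#' @export
kasp_panel <- function(markers) {
  req <- c("marker_id", "chromosome", "position_bp",
           "allele_robusta", "allele_intestinalis", "region")
  missing_cols <- setdiff(req, names(markers))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position_bp <- as.integer(markers$position_bp)
  markers$allele_robusta <- toupper(as.character(markers$allele_robusta))
  markers$allele_intestinalis <- toupper(as.character(markers$allele_intestinalis))
  markers$region <- as.character(markers$region)
  if (is.null(markers$robusta_channel)) markers$robusta_channel <- 1L
  markers$robusta_channel <- as.integer(markers$robusta_channel)

  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker_id: ",
         paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
               collapse = ", "))
  bad_region <- setdiff(unique(markers$region), REGIONS)
  if (length(bad_region))
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "))
  if (any(markers$position_bp < 0, na.rm = TRUE))
    stop("position_bp must be >= 0")
  if (!all(markers$allele_robusta %in% IUPAC) ||
      !all(markers$allele_intestinalis %in% IUPAC))
    stop("diagnostic alleles must be single IUPAC bases")
  same <- markers$allele_robusta == markers$allele_intestinalis
  if (any(same))
    stop("allele_robusta equals allele_intestinalis for: ",
         paste(markers$marker_id[same], collapse = ", "))
  if (!all(markers$robusta_channel %in% c(1L, 2L)))
    stop("robusta_channel must be 1 or 2")
  dup_pos <- stats::aggregate(position_bp ~ chromosome, markers,
                              function(x) anyDuplicated(x) > 0)
  if (any(dup_pos$position_bp))
    stop("duplicated position_bp within chromosome(s): ",
         paste(dup_pos$chromosome[dup_pos$position_bp], collapse = ", "))

  n_core <- sum(markers$region == "core")
  if (n_core != 1L)
    stop("panel must contain exactly one core marker, found ", n_core)

  # island markers sorted by position; other markers keep file order after them
  isl <- markers$region %in% ISLAND_REGIONS
  markers <- rbind(markers[isl, ][order(markers$position_bp[isl]), ],
                   markers[!isl, ])
  rownames(markers) <- NULL

  structure(markers,
            core_marker_id = markers$marker_id[markers$region == "core"],
            mito_marker_id = markers$marker_id[markers$region == "mitochondrial"],
            multiplex_marker_ids = markers$marker_id[markers$region == "multiplex_member"],
            class = c("kasp_panel", "data.frame"))
}

#' Read a SNP panel from a TSV file
#'
#' @param path path to a tab-separated file, one row per marker, with a header
#'   naming the \code{\link{kasp_panel}} columns.
#' @return a \code{kasp_panel}
#' @export
read_panel <- function(path) {
  kasp_panel(utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character"))
}

#' The 23-marker Ciona ancestry-informative panel
#'
#' The routine genotyping panel for the Ciona robusta / C. intestinalis
#' contact zone: 11 SNPs on chromosome 5 (10 inside the introgression island
#' plus marker SB outside it), one mitochondrial SNP, and 11 SNPs on the
#' remaining chromosomes pooled in a single multiplex reaction for the
#' hybrid index. The shoulder assignment (4 markers left of the core, 5
#' right) is carried by the panel file, which is the single source of truth
#' for the pair partition used in the LD analysis.
#'
#' @return a \code{kasp_panel}
#' @export
ciona_panel <- function() {
  read_panel(system.file("extdata", "ciona_panel.tsv", package = "kaspop",
                         mustWork = TRUE))
}

#' @export
print.kasp_panel <- function(x, ...) {
  cat("KASP panel:", nrow(x), "markers\n")
  cat("  core marker:    ", attr(x, "core_marker_id"), "\n")
  tab <- table(x$region)
  cat("  regions:        ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  np <- nrow(island_pairs(x))
  cat("  island pairs:   ", np, "\n")
  invisible(x)
}

#' Island markers of a panel
#'
#' @param panel a \code{kasp_panel}
#' @return the subset of markers whose region is core, left_shoulder,
#'   right_shoulder or island_other, sorted by position.
#' @export
island_markers <- function(panel) {
  panel[panel$region %in% ISLAND_REGIONS, , drop = FALSE]
}

#' All unordered pairs of island markers, classified by region
#'
#' Pairs are partitioned into the four disjoint classes used by the temporal
#' LD analysis: \code{core_shoulder} (one member is the core),
#' \code{left_shoulder} (both in the left shoulder), \code{right_shoulder}
#' (both in the right shoulder) and \code{cross_shoulder} (one on each side,
#' or involving an \code{island_other} marker). With 10 island markers this
#' yields choose(10, 2) = 45 pairs.
#'
#' @param panel a \code{kasp_panel}
#' @return data.frame with columns \code{marker_a}, \code{marker_b} (a before
#'   b in map order) and \code{pair_class}.
#' @export
island_pairs <- function(panel) {
  im <- island_markers(panel)
  n <- nrow(im)
  if (n < 2)
    return(data.frame(marker_a = character(), marker_b = character(),
                      pair_class = character(), stringsAsFactors = FALSE))
  idx <- utils::combn(n, 2)
  a <- im$marker_id[idx[1, ]]
  b <- im$marker_id[idx[2, ]]
  ra <- im$region[idx[1, ]]
  rb <- im$region[idx[2, ]]
  cls <- ifelse(ra == "core" | rb == "core", "core_shoulder",
         ifelse(ra == "left_shoulder" & rb == "left_shoulder", "left_shoulder",
         ifelse(ra == "right_shoulder" & rb == "right_shoulder", "right_shoulder",
                "cross_shoulder")))
  data.frame(marker_a = a, marker_b = b, pair_class = cls,
             stringsAsFactors = FALSE)
}
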