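#' Construct a genotype matrix
#'
#' The pipeline's central table: robusta-allele dosages (0, 1, 2 or NA) for
#' individuals (rows) by panel markers (columns), with sample metadata and
#' optional per-cell VAFF values and confidence flags.
#'
#' @param dosage integer matrix, rownames = individual ids, colnames = marker
#'   ids (a subset of the panel); values 0, 1, 2 or NA.
#' @param samples data.frame with one row per individual: \code{individual_id},
#'   \code{population_id}, \code{period}, optionally \code{species_class} and
#'   \code{hybrid_index}.
#' @param panel a \code{kasp_panel}
#' @param vaff,flag optional matrices aligned with \code{dosage}; flags are
#'   "clear", "near_cutoff" or "failed".
#' @return object of class \code{genotype_matrix}
#' @export
genotype_matrix <- function(dosage, samples, panel, vaff = NULL, flag = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  bad <- setdiff(colnames(dosage), panel$marker_id)
  if (length(bad))
    stop("marker column(s) absent from panel: ", paste(bad, collapse = ", "))
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (!setequal(rownames(dosage), samples$individual_id) ||
      anyDuplicated(samples$individual_id))
    stop("samples must list each dosage row exactly once")
  samples <- samples[match(rownames(dosage), samples$individual_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  storage.mode(dosage) <- "integer"
  structure(list(dosage = dosage, samples = samples, panel = panel,
                 vaff = vaff, flag = flag),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers\n")
  cat("  populations:", length(unique(x$samples$population_id)),
      " periods:", paste(sort(unique(x$samples$period)), collapse = ", "), "\n")
  cat("  missing dosages:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  with(object, {
    cat("Calls per marker (0/1/2/NA):\n")
    print(apply(dosage, 2, function(d)
      c(`0` = sum(d == 0, na.rm = TRUE), `1` = sum(d == 1, na.rm = TRUE),
        `2` = sum(d == 2, na.rm = TRUE), `NA` = sum(is.na(d)))))
  })
  invisible(object)
}

#' Default genotype-table dialect
#'
#' The deposited multi-locus genotype tables are plain TSVs whose genotype
#' encoding is not fixed; the dialect block declares it: which single letters
#' stand for the robusta and intestinalis diagnostic alleles, the separator
#' between the two alleles of a genotype (may be empty) and the tokens that
#' mean missing.
#'
#' @param robusta,intestinalis single-character allele codes
#' @param sep separator between the two allele letters ("" for "RI" style)
#' @param missing character vector of missing-data tokens
#' @return a named list understood by \code{\link{read_genotype_table}}
#' @export
genotype_dialect <- function(robusta = "R", intestinalis = "I", sep = "",
                             missing = c("NA", "", "-", "./.")) {
  stopifnot(nchar(robusta) == 1, nchar(intestinalis) == 1,
            robusta != intestinalis)
  list(robusta = robusta, intestinalis = intestinalis, sep = sep,
       missing = missing)
}

#' Read a multi-locus genotype table
#'
#' Reads a TSV with one row per individual (columns \code{individual_id},
#' \code{population_id}, \code{period}, then one column per marker) into a
#' \code{\link{genotype_matrix}}. Cells are decoded through the dialect;
#' undeclared encodings become missing dosages and their count is reported
#' with a message rather than silently dropped.
#'
#' @param path TSV file
#' @param panel a \code{kasp_panel}
#' @param dialect see \code{\link{genotype_dialect}}
#' @return a \code{genotype_matrix}
#' @export
read_genotype_table <- function(path, panel, dialect = genotype_dialect()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  meta_cols <- c("individual_id", "population_id", "period")
  missing_meta <- setdiff(meta_cols, names(x))
  if (length(missing_meta))
    stop("genotype table is missing columns: ",
         paste(missing_meta, collapse = ", "))
  marker_cols <- setdiff(names(x), meta_cols)
  bad <- setdiff(marker_cols, panel$marker_id)
  if (length(bad))
    stop("marker column(s) absent from panel: ", paste(bad, collapse = ", "))

  code <- genotype_codes(dialect)
  cells <- as.matrix(x[, marker_cols, drop = FALSE])
  dos <- matrix(code$dosage[match(cells, code$token)],
                nrow = nrow(cells), dimnames = list(x$individual_id, marker_cols))
  unknown <- !is.na(cells) & !(cells %in% code$token) &
    !(cells %in% dialect$missing)
  if (any(unknown))
    message(sum(unknown), " genotype cell(s) with undeclared encoding set to missing")
  genotype_matrix(dos, x[, meta_cols], panel)
}

genotype_codes <- function(dialect) {
  r <- dialect$robusta; i <- dialect$intestinalis; s <- dialect$sep
  tok <- c(paste0(r, s, r), paste0(r, s, i), paste0(i, s, r), paste0(i, s, i))
  list(token = tok, dosage = c(2L, 1L, 1L, 0L))
}

#' Write a genotype matrix in the tabular dialect
#'
#' Inverse of \code{\link{read_genotype_table}} (up to normalisation of
#' missing tokens and heterozygote letter order).
#'
#' @inheritParams read_genotype_table
#' @param gm a \code{genotype_matrix}
#' @return invisibly, \code{path}
#' @export
write_genotype_table <- function(gm, path, dialect = genotype_dialect()) {
  code <- genotype_codes(dialect)
  enc <- c(code$token[4], code$token[2], code$token[1])  # dosage 0,1,2
  cells <- matrix(enc[gm$dosage + 1L], nrow = nrow(gm$dosage),
                  dimnames = dimnames(gm$dosage))
  cells[is.na(gm$dosage)] <- dialect$missing[1]
  out <- cbind(gm$samples[, c("individual_id", "population_id", "period")],
               as.data.frame(cells, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = dialect$missing[1], eol = "\n")
  invisible(path)
}
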