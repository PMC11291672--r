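CONTROL_CLASSES <- c("robusta", "intestinalis_plain", "intestinalis_introgressed")

#' Read a plate-level fluorescence table
#'
#' One row per (individual, assay) with the two end-point fluorescence
#' channels of a KASP reaction. Rows with zero total signal are flagged as
#' failed rather than dropped, so QC output can account for them.
#'
#' @param path CSV or TSV file (separator auto-detected from the header line)
#'   with columns \code{individual_id}, \code{population_id}, \code{period},
#'   \code{run_id}, \code{assay_id}, \code{f1}, \code{f2}, \code{is_control}
#'   and optionally \code{control_class}.
#' @param panel a \code{kasp_panel}; assay ids must be panel marker ids or
#'   the literal \code{"multiplex"}.
#' @return data.frame of validated records with an added logical column
#'   \code{failed} (TRUE where f1 + f2 == 0).
#' @export
read_fluorescence <- function(path, panel) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  validate_fluorescence(x, panel)
}

validate_fluorescence <- function(x, panel) {
  req <- c("individual_id", "population_id", "period", "run_id",
           "assay_id", "f1", "f2", "is_control")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("fluorescence table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.null(x$control_class)) x$control_class <- NA_character_
  x$control_class[x$control_class %in% c("", "NA")] <- NA_character_
  x$f1 <- as.numeric(x$f1)
  x$f2 <- as.numeric(x$f2)
  x$is_control <- as.logical(x$is_control)
  for (col in c("individual_id", "population_id", "period", "run_id",
                "assay_id", "control_class"))
    x[[col]] <- as.character(x[[col]])

  if (any(!is.finite(x$f1)) || any(!is.finite(x$f2)))
    stop("non-numeric fluorescence values")
  if (any(x$f1 < 0) || any(x$f2 < 0))
    stop("negative fluorescence values")
  known <- c(panel$marker_id, "multiplex")
  bad <- setdiff(unique(x$assay_id), known)
  if (length(bad))
    stop("unknown assay_id(s): ", paste(bad, collapse = ", "))
  bad_cc <- x$is_control & !(x$control_class %in% CONTROL_CLASSES)
  if (any(bad_cc))
    stop("control records must carry a control_class in {",
         paste(CONTROL_CLASSES, collapse = ", "), "}")
  x$failed <- (x$f1 + x$f2) == 0
  x
}

#' Write result tables as deterministic TSV files
#'
#' Each element of \code{results} is written to \code{<dir>/<name>.tsv} with
#' a fixed column order (the data.frame's own order), no row names, and no
#' quoting surprises, so identical inputs produce byte-identical files.
#'
#' @param results named list of data.frames
#' @param dir output directory, created if needed
#' @return invisibly, the paths written
#' @export
write_report <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- as.data.frame(results[[nm]])
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", eol = "\n")
    paths <- c(paths, p)
  }
  invisible(paths)
}
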