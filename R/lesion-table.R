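#' @title Longitudinal lesion-observation tables
#' @description
#' All pipeline stages exchange one flat CSV schema, one row per
#' animal x lesion x scan day:
#' \describe{
#'   \item{animal_id}{animal identifier (character)}
#'   \item{lesion_id}{lesion/site identifier, unique within animal (character)}
#'   \item{day}{days since inoculation, >= 0}
#'   \item{volume_mm3}{lesion volume in mm^3, >= 0}
#'   \item{surface_mm2}{lesion surface area in mm^2 (optional, may be NA)}
#'   \item{detected}{logical; FALSE rows must carry volume 0 (baseline scans
#'     and lesions below the detection limit or fully regressed)}
#' }
#' @name lesion_table
NULL

lesion_table_columns <- c("animal_id", "lesion_id", "day",
                          "volume_mm3", "surface_mm2", "detected")

#' Validate a longitudinal lesion-observation table
#'
#' Checks the schema described in [lesion_table]: required columns, value
#' ranges, and that volume 0 occurs only on undetected rows.
#'
#' @param table A data.frame.
#' @return The table, invisibly, with columns in canonical order.
#' @export
validate_lesion_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(setdiff(lesion_table_columns, "surface_mm2"),
                     names(table))
  if (length(missing) > 0) {
    stop("lesion table schema violation: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  if (!"surface_mm2" %in% names(table)) table$surface_mm2 <- NA_real_
  if (nrow(table) > 0) {
    if (any(!is.finite(table$day)) || any(table$day < 0)) {
      stop("lesion table schema violation: 'day' must be >= 0", call. = FALSE)
    }
    if (any(!is.finite(table$volume_mm3)) || any(table$volume_mm3 < 0)) {
      stop("lesion table schema violation: 'volume_mm3' must be >= 0",
           call. = FALSE)
    }
    if (!is.logical(table$detected)) {
      stop("lesion table schema violation: 'detected' must be logical",
           call. = FALSE)
    }
    bad <- table$volume_mm3 == 0 & table$detected
    if (any(bad)) {
      stop("lesion table schema violation: volume 0 is permitted only when ",
           "detected is FALSE (", sum(bad), " offending row(s))",
           call. = FALSE)
    }
    key <- paste(table$animal_id, table$lesion_id, table$day, sep = "\r")
    if (anyDuplicated(key)) {
      stop("lesion table schema violation: duplicate (animal_id, lesion_id, ",
           "day) rows", call. = FALSE)
    }
  }
  invisible(table[, lesion_table_columns])
}

#' Read a longitudinal lesion-observation CSV
#'
#' @param path Path to a CSV with the [lesion_table] schema.
#' @return A validated data.frame.
#' @export
read_lesion_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$animal_id <- as.character(tab$animal_id)
  tab$lesion_id <- as.character(tab$lesion_id)
  if ("detected" %in% names(tab)) tab$detected <- as.logical(tab$detected)
  validate_lesion_table(tab)
  tab[, intersect(lesion_table_columns, names(tab))]
}

#' Write a longitudinal lesion-observation CSV
#'
#' @param table A data.frame with the [lesion_table] schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(table, path) {
  table <- validate_lesion_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
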