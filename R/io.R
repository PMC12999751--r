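# Plain-text readers and writers for the package's two table schemas and for
# SMILES line files.

#' Read a compound table
#'
#' Reads a CSV of compounds with columns \code{id}, \code{name},
#' \code{smiles} and \code{ec50_mg_per_L} (optionally \code{label}). EC50
#' entries of the form \code{">20"} are kept as character and understood as
#' right-censored by \code{\link{labelFromEc50}}.
#'
#' @param path CSV file path.
#' @param label when TRUE (default) ensure a \code{label} column, deriving it
#'   from EC50 via \code{\link{labelFromEc50}} when absent.
#' @param threshold labeling threshold in mg/L.
#' @return data.frame of compound records.
#' @export
readCompoundTable <- function(path, label = TRUE, threshold = 20) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(ec50_mg_per_L = "character"))
  need <- c("id", "smiles", "ec50_mg_per_L")
  if (!all(need %in% names(d))) {
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  }
  if (label && is.null(d$label)) d$label <- labelFromEc50(d$ec50_mg_per_L, threshold)
  d
}

#' Write a compound table
#' @param records compound data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCompoundTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an assay table
#'
#' Reads the long-format assay CSV produced by \code{\link{simulateCulture}}
#' (columns \code{strain}, \code{treatment}, \code{dose_mg_per_L},
#' \code{replicate}, \code{time_h}, \code{nitrite_uM},
#' \code{addition_time_h}) and validates the schema.
#'
#' @param path CSV file path.
#' @return data.frame of nitrite observations.
#' @export
readAssayTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "treatment", "dose_mg_per_L", "replicate", "time_h",
            "nitrite_uM", "addition_time_h")
  if (!all(need %in% names(d))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$nitrite_uM < 0)) stop("nitrite concentrations must be >= 0")
  d
}

#' Write an assay table
#' @param assay assay data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeAssayTable <- function(assay, path) {
  utils::write.csv(assay, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a SMILES line file
#'
#' One molecule per line, \code{id<TAB>smiles}, with an optional third column
#' carrying the tautomer-group (parent) id used as the leakage key of
#' augmented files.
#'
#' @param ids molecule identifiers.
#' @param smiles SMILES strings.
#' @param path output path.
#' @param groupIds optional parent ids (third column).
#' @return the path, invisibly.
#' @export
writeSmilesFile <- function(ids, smiles, path, groupIds = NULL) {
  stopifnot(length(ids) == length(smiles))
  lines <- if (is.null(groupIds)) paste(ids, smiles, sep = "\t")
           else paste(ids, smiles, groupIds, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SMILES line file
#' @param path input path (1-3 tab-separated columns: id, smiles, group id;
#'   a single column is read as bare SMILES).
#' @return data.frame with columns \code{id}, \code{smiles} and optionally
#'   \code{group_id}.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1) stop("inconsistent column count in SMILES file")
  if (ncol == 1) {
    data.frame(id = sprintf("mol_%04d", seq_along(lines)),
               smiles = vapply(parts, `[`, character(1), 1),
               stringsAsFactors = FALSE)
  } else {
    d <- data.frame(id = vapply(parts, `[`, character(1), 1),
                    smiles = vapply(parts, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
    if (ncol >= 3) d$group_id <- vapply(parts, `[`, character(1), 3)
    d
  }
}
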