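# Event-record CSV dialect (NONMEM convention): one row per dose
# (EVID = 1, MDV = 1) or observation (EVID = 0), times in hours from the
# first dose, amounts in mg, rates in mg/h, concentrations in mg/L, plus
# per-patient covariate columns. Written files are canonical (fixed column
# order, 4-decimal times) so identical datasets produce identical bytes.

.tdm_columns <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV",
                  "SEX", "AGE", "WT", "HT", "SCR", "CYSC")

#' Validate an event-record dataset
#'
#' Checks column presence, per-patient dose/observation integrity and time
#' monotonicity; errors name the offending rows.
#'
#' @param dataset Event-record data frame.
#' @return The dataset, invisibly, if valid.
#' @export
validate_tdm <- function(dataset) {
  miss <- setdiff(setdiff(.tdm_columns, "CYSC"), names(dataset))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!dataset$EVID %in% c(0L, 1L))
  if (length(bad)) stop("EVID must be 0 or 1 (rows ", paste(bad, collapse = ", "), ")",
                        call. = FALSE)
  bad <- which(dataset$EVID == 0 & is.na(dataset$DV))
  if (length(bad)) {
    stop("observation rows lacking DV: rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(dataset$TIME < 0)
  if (length(bad)) stop("negative TIME: rows ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (id in unique(dataset$ID)) {
    idx <- which(dataset$ID == id)
    rows <- dataset[idx, ]
    if (!any(rows$EVID == 1)) {
      stop("patient ", id, " has no dose records", call. = FALSE)
    }
    if (is.unsorted(rows$TIME)) {
      stop("non-monotone times within patient ", id, " (rows ",
           paste(idx, collapse = ", "), ")", call. = FALSE)
    }
    first_dose <- min(rows$TIME[rows$EVID == 1])
    bad <- idx[rows$EVID == 0 & rows$TIME < first_dose]
    if (length(bad)) {
      stop("observation before first dose for patient ", id, " (rows ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  invisible(dataset)
}

#' Write an event-record dataset to CSV
#'
#' Canonical column order, times rounded to 4 decimals, deterministic bytes
#' for a given dataset. Missing cystatin C is written as an empty cell.
#'
#' @param dataset Event-record data frame.
#' @param path Output path.
#' @export
write_tdm <- function(dataset, path) {
  validate_tdm(dataset)
  out <- dataset
  if (!"CYSC" %in% names(out)) out$CYSC <- NA_real_
  out <- out[, .tdm_columns]
  for (cc in c("TIME", "DV")) out[[cc]] <- round(out[[cc]], 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an event-record dataset from CSV
#'
#' Parses, validates and re-derives the body-size and renal covariates.
#'
#' @param path Input path.
#' @return Validated event-record data frame with derived covariate columns
#'   appended.
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(.tdm_columns, "CYSC"), names(raw))
  if (length(miss)) {
    stop("header lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  raw$ID <- as.character(raw$ID)
  if (!"CYSC" %in% names(raw)) raw$CYSC <- NA_real_
  validate_tdm(raw)
  derive_covariates(raw)
}
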