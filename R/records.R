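#' Verbal-autopsy death records
#'
#' A `va_records` object is a data.frame with one row per deceased child.
#' Design columns: `record_id`, `wave`, `age_days`, `sex`, `weight`
#' (sampling weight), `stratum_id`, `psu_id`.  Every further column is a
#' symptom indicator named by a codebook code with values `"yes"`, `"no"`
#' or `"missing"`.  Ages are stored in completed days; deaths at 0-27 days
#' are neonatal, 28-1825 days are the 1-59-month group.
#'
#' @param df Data.frame with the columns described above.
#' @param codebook A [va_codebook] the symptom columns are validated against.
#' @return A validated `va_records` data.frame carrying the codebook as an
#'   attribute.
#' @export
va_records <- function(df, codebook) {
  stopifnot(is.data.frame(df), inherits(codebook, "va_codebook"))
  missing_cols <- setdiff(VA_DESIGN_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  symptom_cols <- setdiff(names(df), VA_DESIGN_COLS)
  unknown <- setdiff(symptom_cols, codebook$code)
  if (length(unknown) > 0) {
    stop("unknown symptom column(s) not in codebook: ",
         paste(unknown, collapse = ", "))
  }
  df$record_id <- as.character(df$record_id)
  df$wave <- as.character(df$wave)
  df$age_days <- as.integer(df$age_days)
  df$weight <- as.numeric(df$weight)
  df$stratum_id <- as.character(df$stratum_id)
  df$psu_id <- as.character(df$psu_id)
  if (anyNA(df$age_days) || any(df$age_days < 0) || any(df$age_days >= 1826)) {
    stop("age_days must be an integer in [0, 1825] (an under-5 death)")
  }
  if (anyNA(df$weight) || any(df$weight <= 0)) {
    stop("sampling weights must be positive")
  }
  bad_wave <- setdiff(unique(df$wave), codebook_waves(codebook))
  if (length(bad_wave) > 0) {
    stop("wave label(s) not covered by the codebook: ",
         paste(bad_wave, collapse = ", "))
  }
  df$sex <- as.character(df$sex)
  df$sex[!(df$sex %in% c("male", "female"))] <- "unknown"

  n_bad <- 0L
  for (col in symptom_cols) {
    v <- tolower(as.character(df[[col]]))
    v[is.na(v) | v == ""] <- "missing"
    bad <- !(v %in% c("yes", "no", "missing"))
    n_bad <- n_bad + sum(bad)
    v[bad] <- "missing"
    df[[col]] <- v
  }
  if (n_bad > 0) {
    warning(n_bad, " symptom value(s) were not yes/no/missing and were ",
            "recorded as missing")
  }
  attr(df, "codebook") <- codebook
  class(df) <- c("va_records", "data.frame")
  df
}

VA_DESIGN_COLS <- c("record_id", "wave", "age_days", "sex", "weight",
                    "stratum_id", "psu_id")

#' @export
print.va_records <- function(x, ...) {
  cat("<va_records> ", nrow(x), " deaths, ",
      length(va_symptom_cols(x)), " symptom columns, waves: ",
      paste(sort(unique(x$wave)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

va_symptom_cols <- function(records) setdiff(names(records), VA_DESIGN_COLS)

va_record_codebook <- function(records) {
  cb <- attr(records, "codebook")
  if (is.null(cb)) stop("records carry no codebook attribute")
  cb
}

is_neonate <- function(records) records$age_days <= 27L

# logical matrix records x symptom codes; TRUE iff the answer is "yes"
# (missing and "no" are both treated as absent evidence)
symptom_matrix <- function(records) {
  cols <- va_symptom_cols(records)
  Y <- vapply(cols, function(cl) records[[cl]] == "yes",
              logical(nrow(records)))
  if (nrow(records) == 1L) Y <- matrix(Y, nrow = 1L, dimnames = list(NULL, cols))
  if (nrow(records) == 0L) Y <- matrix(logical(0), nrow = 0L,
                                       dimnames = list(NULL, cols))
  Y
}

#' Read and write VA record tables
#'
#' Reads a UTF-8 delimited text file (comma by default, tab accepted and
#' auto-detected) with one row per death.  The header must contain the
#' seven design columns (`record_id`, `wave`, `age_days`, `sex`, `weight`,
#' `stratum_id`, `psu_id`); all remaining columns are symptom indicators
#' and must exist in the codebook.  Symptom values other than
#' yes/no/missing are kept as `"missing"` with a warning; a missing design
#' column or an unknown symptom column is a hard error.
#'
#' @param path Path to the delimited text file.
#' @param codebook A [va_codebook].
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return `read_va_table()` returns a [va_records] data.frame.
#' @export
read_va_table <- function(path, codebook, sep = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  va_records(df, codebook)
}

#' @rdname read_va_table
#' @param records A [va_records] object.
#' @export
write_va_table <- function(records, path, sep = ",") {
  stopifnot(inherits(records, "va_records"))
  utils::write.table(as.data.frame(records), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Harmonize records from several survey waves to the common symptom set
#'
#' Comparable multi-wave cause assignment can only use the information that
#' was collected in *every* wave present in the data.  `harmonize_waves()`
#' drops every symptom column whose codebook entry is not available in all
#' waves represented among the records.  The operation is idempotent, and
#' with all three default waves present the surviving serious-infection
#' signs are exactly the five all-wave signs.
#'
#' @param records A [va_records] object (possibly spanning several waves).
#' @param codebook The codebook; defaults to the one attached to `records`.
#' @return A [va_records] object restricted to the common symptom set.
#' @export
harmonize_waves <- function(records, codebook = va_record_codebook(records)) {
  stopifnot(inherits(records, "va_records"))
  waves <- sort(unique(records$wave))
  common <- codebook_common_codes(codebook, waves)
  keep <- intersect(va_symptom_cols(records), common)
  if (length(keep) == 0) {
    stop("no symptom is available in all waves present (",
         paste(waves, collapse = ", "), "); harmonization would drop ",
         "every symptom column")
  }
  out <- records[, c(VA_DESIGN_COLS, keep), drop = FALSE]
  attr(out, "codebook") <- codebook
  attr(out, "harmonized") <- TRUE
  class(out) <- c("va_records", "data.frame")
  out
}
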