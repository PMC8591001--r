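#' Patient cohorts for risk-score validation
#'
#' A cohort is a data frame with one row per patient and the canonical
#' columns `id`, `male`, `albumin_g_l`, `bilirubin_umol_l`, `afp_ug_l`,
#' `tumor_size_cm`, `tumor_number`, `mvi`, `hep_b`, `hep_c`, `rfs_months`,
#' `event`, carrying the covariates of the ERASL risk scores together with
#' the recurrence-free survival outcome (months since surgery, event = 1
#' for observed recurrence, 0 for censoring). Missing covariate values are
#' `NA`; the outcome must always be present.
#'
#' @name cohort
NULL

#' Canonical cohort column names
#'
#' @return Character vector of the canonical column names in order.
#' @export
cohort_columns <- function() {
  c("id", "male", "albumin_g_l", "bilirubin_umol_l", "afp_ug_l",
    "tumor_size_cm", "tumor_number", "mvi", "hep_b", "hep_c",
    "rfs_months", "event")
}

.covariate_columns <- function() {
  setdiff(cohort_columns(), c("id", "rfs_months", "event"))
}

#' Construct and validate a cohort
#'
#' @param data data frame holding (at least) the canonical columns.
#' @param label cohort label, kept as an attribute.
#' @return A validated `survalid_cohort` (a data.frame).
#' @export
as_cohort <- function(data, label = "cohort") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, cohort_columns()]
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    stop("cohort ids must be unique", call. = FALSE)
  }
  validate_outcomes(data$rfs_months, data$event, data$id)
  for (col in c("male", "mvi", "hep_b", "hep_c")) {
    bad <- which(!is.na(data[[col]]) & !data[[col]] %in% c(0, 1))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' must be 0/1; offending row id(s): %s",
                   col, paste(data$id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  for (col in c("albumin_g_l", "bilirubin_umol_l", "afp_ug_l", "tumor_size_cm")) {
    bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("column '%s' must be nonnegative; offending row id(s): %s",
                   col, paste(data$id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  bad <- which(!is.na(data$tumor_number) &
                 (data$tumor_number < 1 | data$tumor_number != round(data$tumor_number)))
  if (length(bad) > 0) {
    stop("tumor_number must be a positive integer; offending row id(s): ",
         paste(data$id[bad], collapse = ", "), call. = FALSE)
  }
  structure(data, label = label,
            class = c("survalid_cohort", "data.frame"))
}

validate_outcomes <- function(time, event, id = seq_along(time)) {
  if (anyNA(time) || anyNA(event)) {
    bad <- which(is.na(time) | is.na(event))
    stop("outcome (rfs_months, event) must be complete; offending row id(s): ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(time < 0)
  if (length(bad) > 0) {
    stop("rfs_months must be nonnegative; offending row id(s): ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(!event %in% c(0, 1))
  if (length(bad) > 0) {
    stop("event must be 0 or 1; offending row id(s): ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a patient cohort from delimited text
#'
#' Reads a delimited file with a header row, maps columns to the canonical
#' cohort fields, and validates the result. Unparseable or blank covariate
#' cells become `NA` (a typed missing marker); the outcome columns must
#' parse for every row.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical field names to
#'   column names in the file. Defaults to the identity mapping on
#'   [cohort_columns()]. Fields absent from the schema and from the file
#'   are filled with `NA` if they are optional covariates (`mvi`, `hep_b`,
#'   `hep_c`).
#' @param delim field delimiter (default comma).
#' @param label cohort label.
#' @return A `survalid_cohort`.
#' @export
read_cohort <- function(path, schema = NULL, delim = ",", label = basename(path)) {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, na.strings = c("", "NA"))
  full_schema <- stats::setNames(cohort_columns(), cohort_columns())
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), cohort_columns())
    if (length(unknown) > 0) {
      stop("schema names must be canonical cohort fields; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    full_schema[names(schema)] <- schema
  }
  optional <- c("mvi", "hep_b", "hep_c")
  required_cols <- full_schema[setdiff(names(full_schema), optional)]
  absent <- required_cols[!required_cols %in% names(raw)]
  if (length(absent) > 0) {
    stop("input file is missing required column(s): ",
         paste(sprintf("%s (for field %s)", absent, names(absent)),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = raw[[full_schema[["id"]]]],
                    stringsAsFactors = FALSE)
  numeric_fields <- setdiff(cohort_columns(), "id")
  for (field in numeric_fields) {
    col <- full_schema[[field]]
    if (col %in% names(raw)) {
      out[[field]] <- suppressWarnings(as.numeric(raw[[col]]))
    } else {
      out[[field]] <- NA_real_  # optional covariate absent from file
    }
  }
  # outcome cells must have parsed; covariate parse failures are missing markers
  as_cohort(out, label = label)
}

#' Write a cohort to CSV in the canonical schema
#'
#' @param cohort a `survalid_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Complete-case filter
#'
#' Retains the records with no missing value among the required fields and
#' summarises exclusions, mirroring the complete-case analysis used when
#' validating a risk score (patients with one or more missing model
#' covariates are excluded).
#'
#' @param cohort a `survalid_cohort`.
#' @param required character vector of required covariate fields.
#' @return List with `cohort` (the filtered cohort), and `exclusions`, a
#'   list holding per-field missing counts (among all input records),
#'   `n_excluded` and `n_retained`.
#' @export
complete_case_filter <- function(cohort,
                                 required = c("male", "albumin_g_l",
                                              "bilirubin_umol_l", "afp_ug_l",
                                              "tumor_size_cm", "tumor_number")) {
  stopifnot(inherits(cohort, "survalid_cohort"))
  bad <- setdiff(required, .covariate_columns())
  if (length(bad) > 0) {
    stop("required fields must be covariate columns; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  miss <- vapply(required, function(f) sum(is.na(cohort[[f]])), integer(1))
  keep <- rowSums(is.na(as.data.frame(cohort)[, required, drop = FALSE])) == 0
  retained <- as_cohort(as.data.frame(cohort)[keep, , drop = FALSE],
                        label = attr(cohort, "label"))
  if (nrow(retained) == 0) {
    warning("complete-case filter excluded every record", call. = FALSE)
  }
  list(cohort = retained,
       exclusions = list(per_field_missing = as.list(miss),
                         n_excluded = sum(!keep),
                         n_retained = sum(keep)))
}

#' Administrative truncation of follow-up
#'
#' Records with follow-up beyond the horizon are censored at the horizon
#' (time set to the horizon, event set to 0); all others are unchanged.
#' The default horizon of 24 months matches the 2-year truncation used for
#' early-recurrence analyses.
#'
#' @param cohort a `survalid_cohort`.
#' @param horizon truncation horizon in months (> 0).
#' @return The truncated cohort.
#' @export
truncate_followup <- function(cohort, horizon = 24) {
  stopifnot(inherits(cohort, "survalid_cohort"), horizon > 0)
  over <- cohort$rfs_months > horizon
  cohort$event[over] <- 0
  cohort$rfs_months[over] <- horizon
  cohort
}

#' @export
print.survalid_cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d patients, %d events, median follow-up %.1f months>\n",
              attr(x, "label"), nrow(x), sum(x$event),
              stats::median(x$rfs_months)))
  invisible(x)
}
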