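#' Load a visit-level cohort from CSV files
#'
#' A cohort is stored as two flat CSV files: `patients.csv` with one row per
#' patient (demographics, background flags, audiometry, interview scores) and
#' `visits.csv` with one row per visit keyed by `patient_id` + `visit_no`
#' (THI total score, tinnitus awareness and treatment descriptors). Missing
#' values are empty cells and are surfaced as `NA`, never as sentinel
#' numbers; the no-response LDL sentinel 999 is a legitimate in-domain value
#' and is preserved verbatim.
#'
#' Every column other than the keys must resolve in the attribute vocabulary
#' and every cell is validated against its declared domain; an out-of-domain
#' value raises an error naming the row and attribute. Unknown columns are
#' kept but reported via the `"unknown_columns"` attribute.
#'
#' @param patients Path to the patients CSV.
#' @param visits Path to the visits CSV.
#' @param vocab Attribute vocabulary (see [trt_vocabulary()]).
#' @return An object of class `trt_cohort`: a list with data frames
#'   `patients` and `visits`.
#' @seealso [save_cohort()], [generate_cohort()]
#' @export
load_cohort <- function(patients, visits, vocab = trt_vocabulary()) {
  for (p in c(patients, visits)) {
    if (!file.exists(p)) stop("cohort file does not exist: ", p)
  }
  pat <- read_cohort_table(patients, key_cols = "patient_id", vocab = vocab)
  vis <- read_cohort_table(visits, key_cols = c("patient_id", "visit_no"), vocab = vocab)
  cohort <- new_cohort(pat, vis)
  validate_cohort(cohort, vocab)
  unknown <- c(attr(pat, "unknown_columns"), attr(vis, "unknown_columns"))
  if (length(unknown)) {
    message("unknown columns (not in vocabulary): ", paste(unknown, collapse = ", "))
    attr(cohort, "unknown_columns") <- unknown
  }
  cohort
}

read_cohort_table <- function(path, key_cols, vocab) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE, colClasses = "character")
  missing_keys <- setdiff(key_cols, names(df))
  if (length(missing_keys)) {
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing_keys, collapse = ", "))
  }
  data_cols <- setdiff(names(df), key_cols)
  unknown <- data_cols[!vapply(data_cols, vocab_has, logical(1), vocab = vocab)]
  known <- setdiff(data_cols, unknown)
  # type coercion from the vocabulary; keys: patient_id character, visit_no integer
  if ("visit_no" %in% names(df)) df$visit_no <- as.integer(df$visit_no)
  for (col in known) {
    dt <- vocab_dtype(col, vocab)
    if (dt %in% c("numeric", "ordinal_0_10")) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    } else if (dt == "binary") {
      df[[col]] <- ifelse(is.na(df[[col]]), NA_character_, norm_binary(df[[col]]))
    }
  }
  # domain validation, reporting row and attribute
  for (col in known) {
    vals <- df[[col]]
    for (i in seq_along(vals)) {
      msg <- validate_value(col, vals[i], vocab)
      if (!is.null(msg)) {
        stop("validation error in ", basename(path), " row ", i, ": ", msg)
      }
    }
  }
  attr(df, "unknown_columns") <- unknown
  df
}

new_cohort <- function(patients, visits) {
  structure(list(patients = patients, visits = visits), class = "trt_cohort")
}

validate_cohort <- function(cohort, vocab = trt_vocabulary()) {
  pat <- cohort$patients
  vis <- cohort$visits
  if (anyDuplicated(pat$patient_id)) {
    stop("duplicate patient_id in patients table")
  }
  orphans <- setdiff(vis$patient_id, pat$patient_id)
  if (length(orphans)) {
    stop("visits reference unknown patient_id: ", paste(utils::head(orphans), collapse = ", "))
  }
  if (nrow(vis)) {
    ord <- split(vis$visit_no, vis$patient_id)
    bad <- names(ord)[!vapply(ord, function(x) !anyDuplicated(x) && all(diff(sort(x)) > 0),
                              logical(1))]
    if (length(bad)) stop("non-increasing or duplicated visit ordinals for patient(s): ",
                          paste(utils::head(bad), collapse = ", "))
  }
  if (all(c("AgeInd", "AgeBeg", "age") %in% names(pat)) && nrow(pat)) {
    ok <- with(pat, is.na(AgeInd) | is.na(AgeBeg) | is.na(age) |
                 (AgeInd <= AgeBeg & AgeBeg <= age))
    if (!all(ok)) stop("AgeInd <= AgeBeg <= age violated for patient row(s): ",
                       paste(utils::head(which(!ok)), collapse = ", "))
  }
  invisible(cohort)
}

#' Save a cohort to CSV files
#'
#' Inverse of [load_cohort()]: writes `patients.csv` and `visits.csv` into
#' `dir`. Missing values are written as empty cells so that the round trip
#' `load_cohort(save_cohort(x))` reproduces `x` field for field.
#'
#' @param cohort A `trt_cohort`.
#' @param dir Output directory (created if needed).
#' @param vocab Attribute vocabulary.
#' @return Invisibly, the two file paths.
#' @export
save_cohort <- function(cohort, dir, vocab = trt_vocabulary()) {
  stopifnot(inherits(cohort, "trt_cohort"))
  validate_cohort(cohort, vocab)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             visits = file.path(dir, "visits.csv"))
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE, na = "")
  utils::write.csv(cohort$visits, paths["visits"], row.names = FALSE, na = "")
  invisible(paths)
}

#' @export
print.trt_cohort <- function(x, ...) {
  cat(sprintf("<trt_cohort> %d patients, %d visits\n",
              nrow(x$patients), nrow(x$visits)))
  invisible(x)
}

#' Number of patients / visits in a cohort
#' @param cohort A `trt_cohort`.
#' @return Named integer vector with elements `patients` and `visits`.
#' @export
cohort_counts <- function(cohort) {
  c(patients = nrow(cohort$patients), visits = nrow(cohort$visits))
}

#' Extract one patient's record
#'
#' @param cohort A `trt_cohort`.
#' @param patient_id Patient identifier.
#' @return A list with the patient row (`profile`) and their visits ordered
#'   by `visit_no` (`visits`).
#' @export
patient_case <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id)
  vis <- cohort$visits[cohort$visits$patient_id == patient_id, , drop = FALSE]
  vis <- vis[order(vis$visit_no), , drop = FALSE]
  structure(list(profile = cohort$patients[i, , drop = FALSE], visits = vis),
            class = "trt_patient_case")
}
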