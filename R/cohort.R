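#' @keywords internal
"_PACKAGE"

# CDKN2A FISH call states; order is wild-type-first for display.
CDKN2A_LEVELS <- c("disomy", "monosomy", "heterozygous_deletion",
                   "homozygous_deletion")

MARKER_COLS <- c("p16_pct", "cd8_pct", "ki67_pct")
SPLIT_LEVELS <- c("test", "validation", "unassigned")

# Classed conditions so callers (and the CLI) can distinguish bad input
# schemas from per-record validation failures and domain errors.
ts_error <- function(message, class) {
  stop(structure(
    class = c(class, "triplescore_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

validation_error <- function(message) ts_error(message, "triplescore_validation_error")
schema_error <- function(message) ts_error(message, "triplescore_schema_error")
domain_error <- function(message) ts_error(message, "triplescore_domain_error")

# Half-up rounding to the integer percent grid (base round() is half-even).
round_half_up <- function(x) floor(x + 0.5)

#' Parse CDKN2A FISH call labels
#'
#' Normalizes copy-number call labels to the four canonical states
#' `disomy`, `monosomy`, `heterozygous_deletion`, `homozygous_deletion`.
#' Matching is case-insensitive and treats spaces and underscores as
#' interchangeable, so display spellings such as `"Homozygous deletion"`
#' are accepted.
#'
#' @param x character vector of status labels.
#' @return factor with the four canonical levels.
#' @examples
#' cdkn2a_status(c("Disomy", "homozygous deletion"))
#' @export
cdkn2a_status <- function(x) {
  key <- gsub("[ _]+", "_", trimws(tolower(as.character(x))))
  bad <- !is.na(key) & !(key %in% CDKN2A_LEVELS)
  if (any(bad)) {
    validation_error(sprintf(
      "unknown CDKN2A status: %s (expected one of %s)",
      paste(unique(x[bad]), collapse = ", "),
      paste(CDKN2A_LEVELS, collapse = ", ")
    ))
  }
  factor(key, levels = CDKN2A_LEVELS)
}

#' CDKN2A status predicates
#'
#' `is_mutated()` is `TRUE` for lesions with homo- or heterozygous CDKN2A
#' deletion (the "CDKN2A-mut" dichotomy used for group statistics);
#' `is_homozygous()` is `TRUE` only for homozygous deletion, the state the
#' triple score is designed to detect. Monosomy and disomy count as
#' CDKN2A-wild type.
#'
#' @param status factor or character vector of CDKN2A states.
#' @return logical vector.
#' @export
is_mutated <- function(status) {
  as.character(cdkn2a_status(status)) %in%
    c("heterozygous_deletion", "homozygous_deletion")
}

#' @rdname is_mutated
#' @export
is_homozygous <- function(status) {
  as.character(cdkn2a_status(status)) == "homozygous_deletion"
}

parse_split <- function(x) {
  key <- gsub("[ _]+", "_", trimws(tolower(as.character(x))))
  key[is.na(key) | key == ""] <- "unassigned"
  bad <- !(key %in% SPLIT_LEVELS)
  if (any(bad)) {
    validation_error(sprintf(
      "unknown split label: %s (expected test, validation or unassigned)",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  factor(key, levels = SPLIT_LEVELS)
}

#' Construct and validate a patient cohort
#'
#' A cohort is a data frame with one row per patient carrying the three
#' marker percentages (integer 0--100), the CDKN2A FISH call, and an
#' optional test/validation split label. `as_cohort()` validates the
#' invariants (percentages in range, unique non-empty patient identifiers)
#' and never silently coerces: non-integer percentages are rounded half-up
#' to the integer grid, anything out of range is an error naming the
#' patient and field.
#'
#' @param x data frame with columns `patient_id`, `p16_pct`, `cd8_pct`,
#'   `ki67_pct`, `cdkn2a` and optionally `split`.
#' @param name cohort name used in printing.
#' @return object of class `cohort` (a validated data frame).
#' @examples
#' as_cohort(data.frame(patient_id = "A1", p16_pct = 0, cd8_pct = 0,
#'                      ki67_pct = 40, cdkn2a = "homozygous_deletion"))
#' @export
as_cohort <- function(x, name = "cohort") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("patient_id", MARKER_COLS, "cdkn2a")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    schema_error(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (!("split" %in% names(x))) x$split <- rep("unassigned", nrow(x))

  out <- data.frame(
    patient_id = as.character(x$patient_id),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0 && any(is.na(out$patient_id) | out$patient_id == "")) {
    validation_error("patient_id must be a non-empty string for every record")
  }
  dup <- duplicated(out$patient_id)
  if (any(dup)) {
    validation_error(sprintf("duplicate patient_id: %s",
                             paste(unique(out$patient_id[dup]), collapse = ", ")))
  }

  for (col in MARKER_COLS) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- is.na(v) | v < 0 | v > 100
    if (any(bad)) {
      validation_error(sprintf(
        "%s out of range [0, 100] (or not numeric) for patient_id %s",
        col, paste(out$patient_id[bad], collapse = ", ")
      ))
    }
    out[[col]] <- as.integer(round_half_up(v))
  }
  out$cdkn2a <- cdkn2a_status(x$cdkn2a)
  if (anyNA(out$cdkn2a) && nrow(out) > 0) {
    validation_error(sprintf(
      "missing CDKN2A status for patient_id %s",
      paste(out$patient_id[is.na(out$cdkn2a)], collapse = ", ")
    ))
  }
  out$split <- parse_split(x$split)

  structure(out, name = name, class = c("cohort", "data.frame"))
}

#' Read a patient cohort from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns
#' `patient_id,p16_pct,cd8_pct,ki67_pct,cdkn2a` and an optional `split`
#' column (`test` / `validation`; empty means unassigned). Status labels
#' are matched case-insensitively, with spaces and underscores
#' interchangeable. A header-only file yields an empty cohort.
#'
#' @param path file path or connection readable by [utils::read.csv()].
#' @param name cohort name; defaults to the file name.
#' @return a [as_cohort()]-validated `cohort`.
#' @export
read_cohort <- function(path, name = NULL) {
  if (is.null(name)) {
    name <- if (is.character(path)) basename(path) else "cohort"
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  as_cohort(df, name = name)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))`
#' reproduces `x` field for field. Unassigned split labels are written as
#' empty strings.
#'
#' @param cohort a `cohort` object.
#' @param path destination path or connection.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort, name = attr(cohort, "name") %||% "cohort")
  out <- as.data.frame(cohort)
  out$cdkn2a <- as.character(out$cdkn2a)
  out$split <- as.character(out$split)
  out$split[out$split == "unassigned"] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The bundled 23-patient melanoma reference cohort
#'
#' Twenty-three multiple-primary / familial melanoma patients with p16,
#' CD8 and Ki67 percentages, CDKN2A FISH calls (7 homozygous deletions,
#' 3 heterozygous deletions, 6 monosomies, 7 disomies) and the original
#' test (11) / validation (12) split. The per-patient total scores
#' originally reported alongside this cohort are available via
#' [bundled_reported_totals()] as regression metadata; the scorer never
#' reads them.
#'
#' @return a `cohort` of 23 records.
#' @examples
#' nrow(bundled_cohort())
#' table(bundled_cohort()$cdkn2a)
#' @export
bundled_cohort <- function() {
  path <- system.file("extdata", "melanoma_cohort.csv",
                      package = "triplescore", mustWork = TRUE)
  read_cohort(path, name = "melanoma_cohort")
}

#' @rdname bundled_cohort
#' @return for `bundled_reported_totals()`: data frame with columns
#'   `patient_id` and `reported_total` (the originally published per-patient
#'   totals, including the one known typesetting inconsistency for CV005).
#' @export
bundled_reported_totals <- function() {
  path <- system.file("extdata", "melanoma_cohort_reported_totals.csv",
                      package = "triplescore", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  attr(x, "name") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d patient(s)\n", attr(x, "name") %||% "cohort",
              nrow(x)))
  if (nrow(x) > 0) {
    cat("CDKN2A: ",
        paste(sprintf("%s=%d", levels(x$cdkn2a), tabulate(x$cdkn2a, 4)),
              collapse = ", "), "\n", sep = "")
    print.data.frame(head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("... and %d more row(s)\n", nrow(x) - 10))
  }
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  cat(sprintf("Cohort '%s': %d patients\n", attr(object, "name") %||% "cohort",
              nrow(object)))
  if (nrow(object) == 0) return(invisible(object))
  cat("\nCDKN2A status:\n")
  print(table(object$cdkn2a))
  cat("\nSplit:\n")
  print(table(object$split))
  cat("\nMarker percentages:\n")
  print(sapply(object[MARKER_COLS], summary))
  invisible(object)
}
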