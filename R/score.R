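# The three ordinal binning scales and the 0-10 composite score.
#
# All bins operate on the integer percent grid 0..100 (inputs are rounded
# half-up at cohort validation). Boundary semantics, fixed constants of the
# method:
#   p16:  51-100 -> 0 | 11-50 -> 1 | 1-10 -> 2 | 0 -> 3   (digressive)
#   CD8:  61-100 -> 0 | 20-60 -> 1 | 1-19 -> 2 | 0 -> 3   (digressive)
#   Ki67: 0-1 -> 0 | 2-5 -> 1 | 6-10 -> 2 | 11-20 -> 3 | 21-100 -> 4
# p16 = 50 scores 1 (the top class is strictly > 50) and CD8 = 20 scores 1
# (the moderate class includes its lower bound).

check_pct <- function(x, what) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) == 0) return(integer(0))
  if (anyNA(x) || any(x < 0 | x > 100)) {
    domain_error(sprintf("%s must be a percentage in [0, 100]", what))
  }
  as.integer(round_half_up(x))
}

#' Ordinal sub-scores of the triple p16-CD8-Ki67 algorithm
#'
#' Each function maps an integer marker percentage to its ordinal class.
#' `score_p16()` and `score_cd8()` are digressive (high marker values are
#' favorable, score 0; complete absence scores 3); `score_ki67()` is
#' progressive (score 0 for an index below 2\%, score 4 above 20\%).
#' Non-integer input is rounded half-up to the integer grid first. All
#' three are vectorized.
#'
#' @param pct numeric vector of percentages in \[0, 100\].
#' @return integer vector of sub-scores (0--3 for p16 and CD8, 0--4 for
#'   Ki67).
#' @examples
#' score_p16(c(0, 10, 50, 100))   # 3 2 1 0
#' score_cd8(c(0, 19, 20, 61))    # 3 2 1 0
#' score_ki67(c(1, 5, 10, 20, 21)) # 0 1 2 3 4
#' @export
score_p16 <- function(pct) {
  x <- check_pct(pct, "p16_pct")
  ifelse(x == 0L, 3L, ifelse(x <= 10L, 2L, ifelse(x <= 50L, 1L, 0L)))
}

#' @rdname score_p16
#' @export
score_cd8 <- function(pct) {
  x <- check_pct(pct, "cd8_pct")
  ifelse(x == 0L, 3L, ifelse(x <= 19L, 2L, ifelse(x <= 60L, 1L, 0L)))
}

#' @rdname score_p16
#' @export
score_ki67 <- function(pct) {
  x <- check_pct(pct, "ki67_pct")
  ifelse(x <= 1L, 0L, ifelse(x <= 5L, 1L,
    ifelse(x <= 10L, 2L, ifelse(x <= 20L, 3L, 4L))))
}

#' Composite triple score from the three marker percentages
#'
#' Sums the three ordinal sub-scores into the 0--10 total. Vectorized;
#' returns one row per input element.
#'
#' @param p16_pct,cd8_pct,ki67_pct numeric percentages in \[0, 100\].
#' @return data frame with columns `p16_score`, `cd8_score`, `ki67_score`,
#'   `total`.
#' @examples
#' triple_score(0, 0, 40)$total  # 10: p16 absent, no TILs, Ki67 > 20%
#' @export
triple_score <- function(p16_pct, cd8_pct, ki67_pct) {
  n <- max(length(p16_pct), length(cd8_pct), length(ki67_pct))
  if (length(p16_pct) != n || length(cd8_pct) != n || length(ki67_pct) != n) {
    domain_error("p16_pct, cd8_pct and ki67_pct must have equal lengths")
  }
  p16 <- score_p16(p16_pct)
  cd8 <- score_cd8(cd8_pct)
  ki67 <- score_ki67(ki67_pct)
  data.frame(p16_score = p16, cd8_score = cd8, ki67_score = ki67,
             total = p16 + cd8 + ki67)
}

check_threshold <- function(threshold) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold != as.integer(threshold) || threshold < 0 || threshold > 10) {
    domain_error("threshold must be a single integer in [0, 10]")
  }
  as.integer(threshold)
}

#' Positivity rule of the triple score
#'
#' A tumor is called positive for CDKN2A homozygous deletion when its
#' total score reaches the cut-off (`total >= threshold`; default 9).
#'
#' @param total integer total score(s) in \[0, 10\].
#' @param threshold integer cut-off in \[0, 10\]; default 9.
#' @return logical vector, `TRUE` where predicted positive.
#' @examples
#' classify_total(c(8, 9, 10))          # FALSE TRUE TRUE
#' classify_total(9, threshold = 10)    # FALSE
#' @export
classify_total <- function(total, threshold = 9) {
  threshold <- check_threshold(threshold)
  if (anyNA(total) || any(total < 0 | total > 10)) {
    domain_error("total must be in [0, 10]")
  }
  total >= threshold
}

#' Score every patient in a cohort
#'
#' Applies the triple score to each record, preserving input order, and
#' attaches the positivity call at the given cut-off.
#'
#' @param cohort a `cohort` (see [as_cohort()]).
#' @param threshold integer cut-off in \[0, 10\]; default 9.
#' @return object of class `scored_cohort`: a data frame with
#'   `patient_id`, the three marker percentages, the three sub-scores,
#'   `total`, `predicted_positive`, `cdkn2a` and `split`; the threshold is
#'   carried as an attribute.
#' @examples
#' scored <- score_cohort(bundled_cohort())
#' subset(scored, patient_id == "HV004")$total  # 10
#' @export
score_cohort <- function(cohort, threshold = 9) {
  cohort <- as_cohort(cohort, name = attr(cohort, "name") %||% "cohort")
  threshold <- check_threshold(threshold)
  sc <- triple_score(cohort$p16_pct, cohort$cd8_pct, cohort$ki67_pct)
  out <- cbind(
    cohort[, c("patient_id", MARKER_COLS), drop = FALSE],
    sc,
    data.frame(
      predicted_positive = if (nrow(sc) > 0) {
        classify_total(sc$total, threshold)
      } else logical(0)
    ),
    cohort[, c("cdkn2a", "split"), drop = FALSE]
  )
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            name = attr(cohort, "name") %||% "cohort",
            class = c("scored_cohort", "data.frame"))
}

#' @export
as.data.frame.scored_cohort <- function(x, ...) {
  attr(x, "name") <- NULL
  attr(x, "threshold") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat(sprintf("<scored_cohort> %s: %d patient(s), cut-off total >= %d\n",
              attr(x, "name") %||% "cohort", nrow(x), attr(x, "threshold")))
  if (nrow(x) > 0) {
    print.data.frame(as.data.frame(x))
  }
  invisible(x)
}

#' Write a scored cohort to CSV
#'
#' @param scored a `scored_cohort` from [score_cohort()].
#' @param path destination path or connection.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path) {
  stopifnot(inherits(scored, "scored_cohort"))
  out <- as.data.frame(scored)[, c("patient_id", "p16_score", "cd8_score",
                                   "ki67_score", "total",
                                   "predicted_positive", "cdkn2a")]
  out$cdkn2a <- as.character(out$cdkn2a)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
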