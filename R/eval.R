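# Diagnostic evaluation of the triple score against the CDKN2A FISH call:
# confusion matrix at a cut-off, sensitivity/specificity, threshold sweep,
# bootstrap intervals, and genotype-group marker statistics.

POSITIVE_DEFINITIONS <- c("homozygous_deletion", "any_mutation")

truth_positive <- function(status, positive_definition) {
  positive_definition <- match.arg(positive_definition, POSITIVE_DEFINITIONS)
  if (positive_definition == "homozygous_deletion") {
    is_homozygous(status)
  } else {
    is_mutated(status)
  }
}

#' Confusion matrix of the triple score at a cut-off
#'
#' Tallies predictions (`total >= threshold`) against the CDKN2A truth
#' label. By default the positive class is homozygous deletion — the state
#' the score targets; `any_mutation` pools homo- and heterozygous
#' deletions.
#'
#' @param scored a `scored_cohort` from [score_cohort()].
#' @param positive_definition `"homozygous_deletion"` (default) or
#'   `"any_mutation"`.
#' @param threshold integer cut-off; defaults to the one the cohort was
#'   scored at.
#' @return object of class `confusion_matrix`: list with counts `tp`,
#'   `fp`, `tn`, `fn`, plus `threshold` and `positive_definition`.
#' @examples
#' cm <- confusion_matrix(score_cohort(bundled_cohort()))
#' sensitivity(cm)  # 1
#' @export
confusion_matrix <- function(scored,
                             positive_definition = "homozygous_deletion",
                             threshold = NULL) {
  stopifnot(inherits(scored, "scored_cohort"))
  if (nrow(scored) == 0) {
    domain_error("cannot tally a confusion matrix for an empty cohort")
  }
  positive_definition <- match.arg(positive_definition, POSITIVE_DEFINITIONS)
  threshold <- check_threshold(threshold %||% attr(scored, "threshold"))
  truth <- truth_positive(scored$cdkn2a, positive_definition)
  pred <- classify_total(scored$total, threshold)
  structure(list(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth),
    threshold = threshold, positive_definition = positive_definition
  ), class = "confusion_matrix")
}

#' Sensitivity and specificity of a confusion matrix
#'
#' `sensitivity()` is the true-positive rate tp/(tp+fn); `specificity()`
#' the true-negative rate tn/(tn+fp). Either is `NA` when its denominator
#' is zero (no positives, respectively no negatives, among the evaluated
#' records).
#'
#' @param cm a `confusion_matrix`.
#' @return proportion in \[0, 1\], or `NA`.
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) return(NA_real_)
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tn + cm$fp == 0) return(NA_real_)
  cm$tn / (cm$tn + cm$fp)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s, cut-off total >= %d\n",
              x$positive_definition, x$threshold))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  m[2, ] <- c(x$fp, x$tn)
  m[1, ] <- c(x$tp, x$fn)
  print(m)
  cat(sprintf("sensitivity = %s, specificity = %s\n",
              format(sensitivity(x)), format(specificity(x))))
  invisible(x)
}

#' Heterozygous-deletion false negatives
#'
#' Number of patients carrying a heterozygous CDKN2A deletion whose total
#' score falls below the cut-off. These are false negatives only under the
#' `any_mutation` reading of the truth label; the score by design does not
#' detect heterozygous loss.
#'
#' @inheritParams confusion_matrix
#' @return non-negative integer count.
#' @export
false_negative_het_count <- function(scored, threshold = NULL) {
  stopifnot(inherits(scored, "scored_cohort"))
  threshold <- check_threshold(threshold %||% attr(scored, "threshold"))
  sum(as.character(scored$cdkn2a) == "heterozygous_deletion" &
        scored$total < threshold)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-tailed Welch t-test with Satterthwaite degrees of freedom, the
#' comparison used for the genotype-group marker statistics. Thin wrapper
#' over [stats::t.test()] returning just the three quantities of interest.
#'
#' @param x,y numeric samples, each of size at least 2; at least one must
#'   have positive variance.
#' @return list with `t_statistic`, `welch_df`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2 || anyNA(x) || anyNA(y)) {
    domain_error("welch_t_test requires two complete samples of size >= 2")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    domain_error("welch_t_test is undefined for two zero-variance samples")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t_statistic = unname(tt$statistic),
       welch_df = unname(tt$parameter),
       p_value = unname(tt$p.value))
}

#' Genotype-group means and Welch test for one marker
#'
#' Splits the cohort into CDKN2A-wild type (disomy or monosomy) and
#' CDKN2A-mutated (homo- or heterozygous deletion) and compares the
#' marker's mean percentage between the groups with Welch's t-test.
#'
#' @param cohort a `cohort`.
#' @param marker `"p16"`, `"cd8"` or `"ki67"`.
#' @return object of class `group_comparison`: list with `marker`,
#'   `mean_wt`, `mean_mut`, `n_wt`, `n_mut`, `t_statistic`, `welch_df`,
#'   `p_value`.
#' @examples
#' group_means(bundled_cohort(), "p16")
#' @export
group_means <- function(cohort, marker = c("p16", "cd8", "ki67")) {
  cohort <- as_cohort(cohort, name = attr(cohort, "name") %||% "cohort")
  marker <- match.arg(marker)
  col <- paste0(marker, "_pct")
  mut <- is_mutated(cohort$cdkn2a)
  x_wt <- cohort[[col]][!mut]
  x_mut <- cohort[[col]][mut]
  if (length(x_wt) == 0 || length(x_mut) == 0) {
    domain_error("both CDKN2A-wt and CDKN2A-mut groups must be non-empty")
  }
  w <- welch_t_test(x_wt, x_mut)
  structure(list(
    marker = marker,
    mean_wt = mean(x_wt), mean_mut = mean(x_mut),
    n_wt = length(x_wt), n_mut = length(x_mut),
    t_statistic = w$t_statistic, welch_df = w$welch_df, p_value = w$p_value
  ), class = "group_comparison")
}

# Display rounding: half-up to 2 decimals; internal values keep full precision.
display_round <- function(x, digits = 2) round_half_up(x * 10^digits) / 10^digits

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: wt mean %.2f%% (n=%d), mut mean %.2f%% (n=%d)\n",
    x$marker, display_round(x$mean_wt), x$n_wt,
    display_round(x$mean_mut), x$n_mut))
  cat(sprintf("  Welch t = %.4f, df = %.2f, two-tailed p = %.6g\n",
              x$t_statistic, x$welch_df, x$p_value))
  invisible(x)
}

#' Group-statistics summary table for all three markers
#'
#' @param cohort a `cohort`.
#' @return data frame with one row per marker: group means (full
#'   precision), group sizes and Welch test statistics.
#' @export
group_summary <- function(cohort) {
  rows <- lapply(c("p16", "cd8", "ki67"), function(m) {
    g <- group_means(cohort, m)
    data.frame(marker = g$marker, mean_wt = g$mean_wt, mean_mut = g$mean_mut,
               n_wt = g$n_wt, n_mut = g$n_mut, t_statistic = g$t_statistic,
               welch_df = g$welch_df, p_value = g$p_value)
  })
  do.call(rbind, rows)
}

#' Sensitivity/specificity sweep over all cut-offs
#'
#' Evaluates the confusion matrix at every integer threshold 0..10.
#' Because positivity is `total >= threshold`, sensitivity is
#' non-increasing and specificity non-decreasing in the threshold. The
#' Youden index (sensitivity + specificity - 1) ranks candidate cut-offs.
#'
#' @inheritParams confusion_matrix
#' @return data frame with columns `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
threshold_sweep <- function(scored,
                            positive_definition = "homozygous_deletion") {
  stopifnot(inherits(scored, "scored_cohort"))
  if (nrow(scored) == 0) domain_error("cannot sweep an empty cohort")
  rows <- lapply(0:10, function(th) {
    cm <- confusion_matrix(scored, positive_definition, threshold = th)
    se <- sensitivity(cm); sp <- specificity(cm)
    data.frame(threshold = th, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, sensitivity = se, specificity = sp,
               youden = se + sp - 1)
  })
  do.call(rbind, rows)
}

#' Percentile bootstrap interval for sensitivity or specificity
#'
#' Case-resampling bootstrap: patients are resampled with replacement and
#' the metric recomputed per replicate; the 2.5/97.5 percentiles of the
#' replicates form the interval. Replicates in which the metric is
#' undefined (no positives, respectively negatives, drawn) are resampled;
#' if more than half of all draws are undefined the cohort is too small
#' and an error is raised.
#'
#' @inheritParams confusion_matrix
#' @param metric `"sensitivity"` or `"specificity"`.
#' @param n_boot number of bootstrap replicates (at least 100).
#' @param seed integer seed; the interval is deterministic given the seed.
#' @return named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scored, metric = c("sensitivity", "specificity"),
                         n_boot = 2000, seed = 1,
                         positive_definition = "homozygous_deletion",
                         threshold = NULL) {
  stopifnot(inherits(scored, "scored_cohort"))
  metric <- match.arg(metric)
  if (n_boot < 100) domain_error("n_boot must be at least 100")
  if (nrow(scored) == 0) domain_error("cannot bootstrap an empty cohort")
  positive_definition <- match.arg(positive_definition, POSITIVE_DEFINITIONS)
  threshold <- check_threshold(threshold %||% attr(scored, "threshold"))

  truth <- truth_positive(scored$cdkn2a, positive_definition)
  pred <- classify_total(scored$total, threshold)
  n <- length(truth)
  metric_fun <- if (metric == "sensitivity") {
    function(idx) {
      pos <- truth[idx]
      if (!any(pos)) return(NA_real_)
      sum(pred[idx] & pos) / sum(pos)
    }
  } else {
    function(idx) {
      neg <- !truth[idx]
      if (!any(neg)) return(NA_real_)
      sum(!pred[idx] & neg) / sum(neg)
    }
  }

  max_draws <- 2L * n_boot
  reps <- with_seed(seed, {
    vals <- numeric(0)
    draws <- 0L
    while (length(vals) < n_boot && draws < max_draws) {
      v <- metric_fun(sample.int(n, n, replace = TRUE))
      draws <- draws + 1L
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) < n_boot) {
      domain_error(paste0(
        metric, " undefined in more than half of bootstrap replicates; ",
        "a larger cohort is needed for a stable interval"))
    }
    vals
  })
  q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Full diagnostic evaluation of a cohort
#'
#' Scores the cohort (optionally restricted to one split), tallies the
#' confusion matrix at the cut-off, attaches the threshold sweep, the
#' heterozygous-deletion false-negative count and the genotype-group
#' marker comparisons.
#'
#' @param cohort a `cohort`.
#' @param threshold integer cut-off in \[0, 10\]; default 9.
#' @param positive_definition `"homozygous_deletion"` (default) or
#'   `"any_mutation"`.
#' @param split `"all"` (default, pools test and validation), `"test"` or
#'   `"validation"`.
#' @return object of class `cdkn2a_eval`: list with the evaluation inputs,
#'   counts, `sensitivity`, `specificity`, `fn_heterozygous`, `sweep`,
#'   `group_comparisons` and explanatory `notes`.
#' @examples
#' ev <- evaluate_cohort(bundled_cohort())
#' ev$sensitivity  # 1
#' @export
evaluate_cohort <- function(cohort, threshold = 9,
                            positive_definition = "homozygous_deletion",
                            split = c("all", "test", "validation")) {
  cohort <- as_cohort(cohort, name = attr(cohort, "name") %||% "cohort")
  split <- match.arg(split)
  positive_definition <- match.arg(positive_definition, POSITIVE_DEFINITIONS)
  if (split != "all") {
    cohort <- as_cohort(cohort[cohort$split == split, , drop = FALSE],
                        name = paste0(attr(cohort, "name"), ":", split))
  }
  if (nrow(cohort) == 0) domain_error("no records to evaluate")

  scored <- score_cohort(cohort, threshold)
  cm <- confusion_matrix(scored, positive_definition)
  notes <- c(
    "sensitivity = tp/(tp+fn); specificity = tn/(tn+fp) over all evaluated records",
    "group comparisons use Welch's unequal-variance two-tailed t-test on the CDKN2A-wt vs CDKN2A-mut dichotomy"
  )
  comparisons <- list()
  for (m in c("p16", "cd8", "ki67")) {
    comparisons[[m]] <- tryCatch(group_means(cohort, m), triplescore_error =
      function(e) {
        notes <<- c(notes, sprintf("group comparison for %s unavailable: %s",
                                   m, conditionMessage(e)))
        NULL
      })
  }
  structure(list(
    name = attr(cohort, "name"),
    n = nrow(cohort),
    threshold = check_threshold(threshold),
    positive_definition = positive_definition,
    split = split,
    counts = list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn),
    sensitivity = sensitivity(cm),
    specificity = specificity(cm),
    fn_heterozygous = false_negative_het_count(scored),
    sweep = threshold_sweep(scored, positive_definition),
    group_comparisons = Filter(Negate(is.null), comparisons),
    notes = notes
  ), class = "cdkn2a_eval")
}

#' @export
print.cdkn2a_eval <- function(x, ...) {
  cat(sprintf("<cdkn2a_eval> %s (n = %d, split = %s)\n", x$name, x$n, x$split))
  cat(sprintf("cut-off total >= %d, positive class: %s\n",
              x$threshold, x$positive_definition))
  cat(sprintf("tp = %d, fp = %d, tn = %d, fn = %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  cat(sprintf("sensitivity = %.2f%%, specificity = %.2f%%\n",
              display_round(100 * x$sensitivity),
              display_round(100 * x$specificity)))
  cat(sprintf("heterozygous deletions below cut-off: %d\n", x$fn_heterozygous))
  if (length(x$group_comparisons) > 0) {
    cat("\nGroup comparisons (wt vs mut):\n")
    for (g in x$group_comparisons) {
      cat(sprintf("  %-4s mean %6.2f%% vs %6.2f%%  p = %.6g\n", g$marker,
                  display_round(g$mean_wt), display_round(g$mean_mut),
                  g$p_value))
    }
  }
  invisible(x)
}

eval_to_list <- function(ev) {
  x <- list(
    cohort = ev$name,
    n = ev$n,
    threshold = ev$threshold,
    positive_definition = ev$positive_definition,
    split = ev$split,
    counts = ev$counts,
    sensitivity = ev$sensitivity,
    specificity = ev$specificity,
    sensitivity_pct_display = display_round(100 * ev$sensitivity),
    specificity_pct_display = display_round(100 * ev$specificity),
    fn_heterozygous = ev$fn_heterozygous,
    sweep = ev$sweep,
    group_comparisons = lapply(unname(ev$group_comparisons), function(g) {
      c(unclass(g),
        list(mean_wt_display = display_round(g$mean_wt),
             mean_mut_display = display_round(g$mean_mut)))
    }),
    notes = as.list(ev$notes)
  )
  if (!is.null(ev$bootstrap)) x$bootstrap <- ev$bootstrap
  x
}

#' Write a JSON evaluation report
#'
#' Serializes a [evaluate_cohort()] result. Numeric values are written at
#' full precision; separately rounded `*_display` fields carry the 2-decimal
#' half-up presentation values so downstream regression checks need no
#' tolerance. No timestamp is included unless requested, keeping reports
#' byte-identical across runs.
#'
#' @param ev a `cdkn2a_eval`.
#' @param path destination path or connection.
#' @param timestamp include a generation timestamp? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(ev, path, timestamp = FALSE) {
  stopifnot(inherits(ev, "cdkn2a_eval"))
  x <- eval_to_list(ev)
  if (isTRUE(timestamp)) x$generated_at <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
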