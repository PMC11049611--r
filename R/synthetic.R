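# Genotype-conditional synthetic cohorts. Markers are modelled as
# categorical distributions on the integer percent grid, one distribution
# per (CDKN2A status, marker) pair; within a genotype the three markers are
# drawn independently. Sampling uses R's default Mersenne-Twister stream,
# seeded locally so the caller's RNG state is untouched.

MARKERS <- c("p16", "cd8", "ki67")

# Evaluate expr under a local RNG seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Construct a synthetic-cohort configuration
#'
#' A configuration holds, for each CDKN2A status, the number of patients
#' to generate and one categorical marker distribution per marker:
#' integer support values in \[0, 100\] with probabilities summing to 1.
#' Statuses absent from `n_per_status` are simply not generated.
#'
#' @param n_per_status named integer vector (names among the four CDKN2A
#'   states) of patients per status.
#' @param distributions nested list `distributions[[status]][[marker]]`,
#'   each element a list with numeric `values` (integers in \[0, 100\]) and
#'   `probs` (same length, non-negative, summing to 1 within 1e-12).
#' @param seed integer root seed used by [generate_cohort()].
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_status, distributions, seed = 1) {
  if (is.null(names(n_per_status)) ||
      !all(names(n_per_status) %in% CDKN2A_LEVELS)) {
    validation_error("n_per_status must be named by CDKN2A status")
  }
  n_per_status <- vapply(n_per_status, as.integer, integer(1))
  if (any(n_per_status < 0)) validation_error("n_per_status must be >= 0")
  for (st in names(n_per_status)) {
    d <- distributions[[st]]
    if (!all(MARKERS %in% names(d))) {
      validation_error(sprintf(
        "distributions for status %s must cover markers %s", st,
        paste(MARKERS, collapse = ", ")))
    }
    for (m in MARKERS) {
      dm <- d[[m]]
      v <- dm$values; p <- dm$probs
      if (length(v) == 0 || length(v) != length(p)) {
        validation_error(sprintf("empty or mismatched distribution: %s/%s",
                                 st, m))
      }
      if (any(v != round(v)) || any(v < 0 | v > 100)) {
        validation_error(sprintf(
          "support of %s/%s must be integers in [0, 100]", st, m))
      }
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
        validation_error(sprintf(
          "probabilities of %s/%s must be non-negative and sum to 1", st, m))
      }
    }
  }
  structure(list(n_per_status = n_per_status,
                 distributions = distributions[names(n_per_status)],
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> seed =", x$seed, "\n")
  for (st in names(x$n_per_status)) {
    cat(sprintf("  %s: n = %d; support sizes %s\n", st, x$n_per_status[[st]],
                paste(vapply(MARKERS, function(m)
                  length(x$distributions[[st]][[m]]$values), integer(1)),
                  collapse = "/")))
  }
  invisible(x)
}

#' Empirical configuration from an observed cohort
#'
#' Builds the per-status, per-marker categorical distributions with the
#' observed relative frequencies, and copies the per-status counts. A
#' status absent from the cohort is omitted from the configuration.
#'
#' @param cohort a non-empty `cohort`.
#' @param seed root seed stored in the configuration.
#' @return a `synthetic_config`.
#' @examples
#' cfg <- empirical_config(bundled_cohort(), seed = 1)
#' cfg$n_per_status
#' @export
empirical_config <- function(cohort, seed = 1) {
  cohort <- as_cohort(cohort, name = attr(cohort, "name") %||% "cohort")
  if (nrow(cohort) == 0) domain_error("empirical_config needs a non-empty cohort")
  present <- levels(cohort$cdkn2a)[tabulate(cohort$cdkn2a, 4) > 0]
  n_per_status <- vapply(present, function(st)
    sum(cohort$cdkn2a == st), integer(1))
  distributions <- lapply(present, function(st) {
    sub <- cohort[cohort$cdkn2a == st, , drop = FALSE]
    out <- lapply(MARKERS, function(m) {
      tab <- table(sub[[paste0(m, "_pct")]])
      list(values = as.integer(names(tab)),
           probs = as.numeric(tab) / nrow(sub))
    })
    names(out) <- MARKERS
    out
  })
  names(distributions) <- present
  synthetic_config(n_per_status, distributions, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws each patient's marker percentages independently from the
#' configured categorical distributions. Deterministic given the seed;
#' patient identifiers are synthetic (`SYN0001`, ...) and all split labels
#' are unassigned.
#'
#' @param config a `synthetic_config`.
#' @param seed overrides the configuration's root seed if given.
#' @return a `cohort` with `sum(n_per_status)` records, grouped by status
#'   in configuration order.
#' @examples
#' gen <- generate_cohort(empirical_config(bundled_cohort()), seed = 7)
#' identical(gen, generate_cohort(empirical_config(bundled_cohort()), seed = 7))
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "synthetic_config")) {
    config <- synthetic_config(config$n_per_status, config$distributions,
                               config$seed %||% 1)
  }
  seed <- seed %||% config$seed
  n_total <- sum(config$n_per_status)
  draw_one <- function(dm, n) {
    if (length(dm$values) == 1) rep(dm$values, n)
    else sample(dm$values, n, replace = TRUE, prob = dm$probs)
  }
  rows <- with_seed(seed, {
    lapply(names(config$n_per_status), function(st) {
      n <- config$n_per_status[[st]]
      d <- config$distributions[[st]]
      data.frame(
        p16_pct = draw_one(d$p16, n),
        cd8_pct = draw_one(d$cd8, n),
        ki67_pct = draw_one(d$ki67, n),
        cdkn2a = rep(st, n)
      )
    })
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(patient_id = character(0), p16_pct = integer(0),
                     cd8_pct = integer(0), ki67_pct = integer(0),
                     cdkn2a = character(0))
  } else {
    df <- cbind(patient_id = sprintf("SYN%04d", seq_len(nrow(df))), df)
  }
  as_cohort(df, name = "synthetic")
}

#' Stratified random test/validation split
#'
#' Assigns split labels by stratified random sampling within the
#' CDKN2A-wt / CDKN2A-mut dichotomy, so each stratum contributes its
#' proportional share to the test set (sizes differ by at most 1 per
#' stratum at a 0.5 fraction). Deterministic given the seed. A stratum
#' with fewer than 2 records cannot be split and is assigned entirely to
#' the test set, with a warning.
#'
#' @param cohort a `cohort`.
#' @param fraction_test proportion in (0, 1) assigned to the test split.
#' @param seed integer seed.
#' @return the cohort with `split` set to `test` or `validation`.
#' @export
split_cohort <- function(cohort, fraction_test = 0.5, seed = 1) {
  cohort <- as_cohort(cohort, name = attr(cohort, "name") %||% "cohort")
  if (fraction_test <= 0 || fraction_test >= 1) {
    domain_error("fraction_test must be strictly between 0 and 1")
  }
  split <- rep("validation", nrow(cohort))
  with_seed(seed, {
    for (stratum in list(wt = !is_mutated(cohort$cdkn2a),
                         mut = is_mutated(cohort$cdkn2a))) {
      idx <- which(stratum)
      if (length(idx) == 0) next
      if (length(idx) < 2) {
        warning("stratum with fewer than 2 records assigned entirely to the test set")
        split[idx] <- "test"
        next
      }
      n_test <- as.integer(round_half_up(length(idx) * fraction_test))
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      split[sample(idx, n_test)] <- "test"
    }
  })
  cohort$split <- factor(split, levels = SPLIT_LEVELS)
  cohort
}

#' Read and write synthetic configurations as JSON
#'
#' @param config a `synthetic_config`.
#' @param path file path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns a validated `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  jsonlite::write_json(
    list(seed = config$seed,
         n_per_status = as.list(config$n_per_status),
         distributions = config$distributions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$n_per_status) || is.null(x$distributions)) {
    schema_error("config JSON must contain n_per_status and distributions")
  }
  synthetic_config(unlist(x$n_per_status), x$distributions,
                   seed = x$seed %||% 1)
}
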