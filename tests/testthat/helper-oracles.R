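# Independent oracles, written from the class definitions directly and
# kept free of the package's binning/tallying code paths.

# Full lookup tables over the integer grid 0..100, index = pct + 1.
p16_lookup <- c(3L, rep(2L, 10), rep(1L, 40), rep(0L, 50))
cd8_lookup <- c(3L, rep(2L, 19), rep(1L, 41), rep(0L, 40))
ki67_lookup <- c(rep(0L, 2), rep(1L, 4), rep(2L, 5), rep(3L, 10), rep(4L, 80))

stopifnot(length(p16_lookup) == 101, length(cd8_lookup) == 101,
          length(ki67_lookup) == 101)

# Naive per-record confusion tally.
oracle_confusion <- function(total, truth, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(total)) {
    pred <- total[i] >= threshold
    if (pred && truth[i]) tp <- tp + 1L
    else if (pred && !truth[i]) fp <- fp + 1L
    else if (!pred && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Welch's t statistic, Satterthwaite df and two-tailed p from the
# closed-form formulas.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_statistic = t_stat, welch_df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

# Random valid cohort drawn with plain base-R sampling (independent of the
# package's generator) for round-trip and oracle-equivalence properties.
random_cohort <- function(n, seed) {
  set.seed(seed)
  as_cohort(data.frame(
    patient_id = sprintf("R%05d", seq_len(n)),
    p16_pct = sample(0:100, n, replace = TRUE),
    cd8_pct = sample(0:100, n, replace = TRUE),
    ki67_pct = sample(0:100, n, replace = TRUE),
    cdkn2a = sample(c("disomy", "monosomy", "heterozygous_deletion",
                      "homozygous_deletion"), n, replace = TRUE),
    split = sample(c("test", "validation", ""), n, replace = TRUE)
  ))
}
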