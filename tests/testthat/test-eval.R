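fixture_scored <- score_cohort(bundled_cohort())

test_that("confusion matrix on the reference cohort gives the headline counts", {
  cm <- confusion_matrix(fixture_scored)
  expect_equal(cm$tp, 7)
  expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 15)
  expect_equal(cm$fn, 0)
  expect_equal(sensitivity(cm), 1)
  expect_equal(specificity(cm), 15 / 16)
  expect_error(confusion_matrix(fixture_scored[0, ]),
               class = "triplescore_domain_error")
})

test_that("confusion matrix equals a naive per-record tally on random cohorts", {
  for (seed in c(11, 12)) {
    co <- random_cohort(300, seed)
    sc <- score_cohort(co)
    for (pos in c("homozygous_deletion", "any_mutation")) {
      truth <- if (pos == "homozygous_deletion") {
        is_homozygous(sc$cdkn2a)
      } else is_mutated(sc$cdkn2a)
      for (th in c(0, 5, 9, 10)) {
        cm <- confusion_matrix(sc, pos, threshold = th)
        expect_equal(cm[c("tp", "fp", "tn", "fn")],
                     oracle_confusion(sc$total, truth, th))
      }
    }
  }
})

test_that("heterozygous deletions below the cut-off are counted correctly", {
  expect_equal(false_negative_het_count(fixture_scored), 3)
  het <- as.character(fixture_scored$cdkn2a) == "heterozygous_deletion"
  for (th in 0:10) {
    expect_equal(false_negative_het_count(fixture_scored, th),
                 sum(het & fixture_scored$total < th))
  }
  no_het <- score_cohort(
    bundled_cohort()[!het, ])
  expect_equal(false_negative_het_count(no_het), 0)
})

test_that("welch_t_test matches the closed-form formulas to 1e-9", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    got <- welch_t_test(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t_statistic, want$t_statistic, tolerance = 1e-9)
    expect_equal(got$welch_df, want$welch_df, tolerance = 1e-9)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
    # swapping samples flips t and keeps p; rescaling changes neither
    swapped <- welch_t_test(y, x)
    expect_equal(swapped$t_statistic, -got$t_statistic, tolerance = 1e-12)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
    scaled <- welch_t_test(3.7 * x, 3.7 * y)
    expect_equal(scaled$t_statistic, got$t_statistic, tolerance = 1e-9)
    expect_equal(scaled$p_value, got$p_value, tolerance = 1e-9)
  }
})

test_that("welch_t_test handles identity and degenerate inputs", {
  x <- c(1, 4, 9, 16)
  same <- welch_t_test(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), class = "triplescore_domain_error")
  expect_error(welch_t_test(c(2, 2, 2), c(2, 2)),
               class = "triplescore_domain_error")
})

test_that("group means reproduce the published group statistics", {
  co <- bundled_cohort()
  p16 <- group_means(co, "p16")
  expect_equal(p16$mean_wt, 550 / 13)   # displays as 42.30
  expect_equal(p16$mean_mut, 15)
  expect_equal(p16$n_wt, 13)
  expect_equal(p16$n_mut, 10)
  expect_equal(p16$p_value, 0.009045612, tolerance = 1e-3)

  cd8 <- group_means(co, "cd8")
  expect_equal(cd8$mean_wt, 255 / 13)   # displays as 19.61
  expect_equal(cd8$mean_mut, 5)

  ki67 <- group_means(co, "ki67")
  expect_equal(ki67$mean_wt, 460 / 13)  # displays as 35.38
  expect_equal(ki67$mean_mut, 42.5)
  expect_equal(ki67$p_value, 0.430718946, tolerance = 1e-2)

  # Satterthwaite df bounded by the pooled and the smaller-sample limits
  for (g in list(p16, cd8, ki67)) {
    expect_gt(g$welch_df, min(g$n_wt, g$n_mut) - 1)
    expect_lte(g$welch_df, g$n_wt + g$n_mut - 2)
  }

  expect_error(group_means(co[co$cdkn2a == "disomy", ], "p16"),
               class = "triplescore_domain_error")
})

test_that("threshold sweep matches per-threshold tallies and is monotone", {
  sw <- threshold_sweep(fixture_scored)
  expect_equal(sw$threshold, 0:10)
  for (i in seq_len(nrow(sw))) {
    cm <- confusion_matrix(fixture_scored, threshold = sw$threshold[i])
    expect_equal(sw$sensitivity[i], sensitivity(cm))
    expect_equal(sw$specificity[i], specificity(cm))
    expect_equal(sw$youden[i], sensitivity(cm) + specificity(cm) - 1)
  }
  expect_true(all(diff(sw$sensitivity) <= 0))
  expect_true(all(diff(sw$specificity) >= 0))
  expect_equal(sw$sensitivity[1], 1)
  expect_equal(sw$specificity[1], 0)
  # 9 attains full sensitivity with the best specificity among such cut-offs
  full_sens <- sw[sw$sensitivity == 1, ]
  expect_equal(full_sens$threshold[which.max(full_sens$specificity)], 9)

  # monotonicity also holds on random synthetic cohorts
  for (seed in c(21, 22)) {
    sw2 <- threshold_sweep(score_cohort(random_cohort(150, seed)))
    expect_true(all(diff(sw2$sensitivity) <= 0))
    expect_true(all(diff(sw2$specificity) >= 0))
  }
})

test_that("bootstrap intervals are deterministic, sane, and error when unstable", {
  ci1 <- bootstrap_ci(fixture_scored, "sensitivity", n_boot = 200, seed = 7)
  ci2 <- bootstrap_ci(fixture_scored, "sensitivity", n_boot = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(all(ci1 >= 0 & ci1 <= 1))
  cm <- confusion_matrix(fixture_scored)
  expect_true(ci1[["lower"]] <= sensitivity(cm) &&
                sensitivity(cm) <= ci1[["upper"]])

  ci_sp <- bootstrap_ci(fixture_scored, "specificity", n_boot = 200, seed = 7)
  expect_true(ci_sp[["lower"]] <= specificity(cm) &&
                specificity(cm) <= ci_sp[["upper"]])

  expect_error(bootstrap_ci(fixture_scored, "sensitivity", n_boot = 50),
               class = "triplescore_domain_error")

  # two wild-type records: sensitivity undefined in every replicate
  tiny <- score_cohort(bundled_cohort()[
    bundled_cohort()$cdkn2a == "disomy", ][1:2, ])
  expect_error(
    bootstrap_ci(tiny, "sensitivity", n_boot = 100, seed = 1),
    "larger cohort", class = "triplescore_domain_error")
})

test_that("evaluate_cohort assembles the full report and honors the split filter", {
  ev <- evaluate_cohort(bundled_cohort())
  expect_s3_class(ev, "cdkn2a_eval")
  expect_equal(ev$n, 23)
  expect_equal(ev$counts, list(tp = 7, fp = 1, tn = 15, fn = 0))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 15 / 16)
  expect_equal(ev$fn_heterozygous, 3)
  expect_equal(nrow(ev$sweep), 11)
  expect_equal(names(ev$group_comparisons), c("p16", "cd8", "ki67"))

  ev_val <- evaluate_cohort(bundled_cohort(), split = "validation")
  expect_equal(ev_val$n, 12)
  expect_equal(ev_val$counts$tp, 5)   # validation holds 5 homozygous deletions
  expect_equal(ev_val$counts$fp, 1)   # VS019 sits in the validation split
  expect_equal(ev_val$sensitivity, 1)

  ev_test <- evaluate_cohort(bundled_cohort(), split = "test")
  expect_equal(ev_test$n, 11)
  expect_equal(ev_test$counts$tp, 2)
  expect_equal(ev_test$counts$fp, 0)
})

test_that("JSON reports are reproducible byte-for-byte and parse back", {
  ev <- evaluate_cohort(bundled_cohort())
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, f1)
  write_eval_report(ev, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- jsonlite::read_json(f1, simplifyVector = TRUE)
  expect_equal(back$counts$tp, 7)
  expect_equal(back$sensitivity, 1)
  expect_equal(back$specificity, 0.9375)
  expect_equal(back$specificity_pct_display, 93.75)
  expect_equal(nrow(back$sweep), 11)
})
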