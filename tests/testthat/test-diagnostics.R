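test_that("confusion matrices count against the gold standard, ignoring exclusions", {
  # hand-built six-respondent fixture: 2 AA positive, 1 AA negative,
  # 1 non-AA positive, 2 non-AA negative
  gold <- c(a = "patchy", b = "totalis_universalis", c = "patchy",
            d = "other_hair_loss", e = "other_hair_loss", f = "other_hair_loss")
  labels <- c(a = "positive", b = "positive", c = "negative",
              d = "positive", e = "negative", f = "negative")
  cm <- confusion_matrix(labels, gold)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 1, 1, 2))
  # excluded ids contribute to no cell
  labels["a"] <- "excluded"
  cm2 <- confusion_matrix(labels, gold)
  expect_equal(c(cm2$tp, cm2$n_excluded), c(1, 1))
  expect_equal(cm2$tp + cm2$fp + cm2$tn + cm2$fn, 5)
  # all-positive labels on an all-AA cohort
  allpos <- stats::setNames(rep("positive", 10), paste0("x", 1:10))
  allaa <- stats::setNames(rep("patchy", 10), paste0("x", 1:10))
  cm3 <- confusion_matrix(allpos, allaa)
  expect_equal(c(cm3$tp, cm3$fp, cm3$tn, cm3$fn), c(10, 0, 0, 0))
  # unknown id is an error
  expect_error(confusion_matrix(c(zz = "positive"), gold), "absent from gold")
})

test_that("Clopper-Pearson intervals reproduce published table bounds", {
  expect_equal(round_half_away(100 * unlist(
    clopper_pearson(53, 59)[c("lower", "upper")])), c(79.2, 96.2),
    ignore_attr = TRUE)
  expect_equal(round_half_away(100 * unlist(
    clopper_pearson(176, 180)[c("lower", "upper")])), c(94.4, 99.4),
    ignore_attr = TRUE)
  expect_equal(round_half_away(100 * unlist(
    clopper_pearson(29, 59)[c("lower", "upper")])), c(35.9, 62.5),
    ignore_attr = TRUE)
  ci0 <- clopper_pearson(0, 20)
  expect_identical(ci0$lower, 0)
  ci1 <- clopper_pearson(20, 20)
  expect_identical(ci1$upper, 1)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(2, 10, alpha = 0), "alpha")
})

test_that("Clopper-Pearson equals the binomial tail-inversion oracle to 1e-8", {
  grid <- expand.grid(k = c(0, 1, 2, 5, 10, 29, 53, 59),
                      n = c(10, 20, 59, 180))
  grid <- grid[grid$k <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    ci <- clopper_pearson(grid$k[i], grid$n[i])
    or <- oracle_cp(grid$k[i], grid$n[i])
    expect_equal(ci$lower, unname(or["lower"]), tolerance = 1e-8,
                 info = paste(grid$k[i], grid$n[i]))
    expect_equal(ci$upper, unname(or["upper"]), tolerance = 1e-8,
                 info = paste(grid$k[i], grid$n[i]))
  }
})

test_that("exact intervals are conservative: empirical coverage >= nominal", {
  set.seed(2024)
  reps <- 2000
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(20, 59, 180)) {
      k <- stats::rbinom(reps, n, p)
      lo <- ifelse(k == 0, 0, stats::qbeta(0.025, k, n - k + 1))
      hi <- ifelse(k == n, 1, stats::qbeta(0.975, k + 1, n - k))
      cover <- mean(lo <= p & p <= hi)
      mc_err <- sqrt(0.95 * 0.05 / reps)
      expect_gte(cover, 0.95 - 3 * mc_err)
    }
  }
})

test_that("summaries reproduce the published PPV/NPV arithmetic", {
  s5 <- summarize_diagnostics(confusion_cells(tp = 53, fp = 31, tn = 149, fn = 6))
  expect_equal(s5$n_positive, 84)
  expect_equal(round_half_away(100 * s5$ppv$point), 63.1)
  expect_equal(round_half_away(100 * s5$npv$point), 96.1)
  expect_equal(format_pct_ci(s5$sensitivity), "89.8 (79.2, 96.2)")
  expect_equal(format_pct_ci(s5$npv), "96.1 (91.8, 98.6)")

  s3 <- summarize_diagnostics(confusion_cells(tp = 29, fp = 4, tn = 176, fn = 30))
  expect_equal(round_half_away(100 * s3$ppv$point), 87.9)
  expect_equal(round_half_away(100 * s3$npv$point), 85.4)

  perfect <- summarize_diagnostics(confusion_cells(10, 0, 10, 0))
  expect_equal(perfect$sensitivity$point, 1)
  expect_equal(perfect$specificity$point, 1)
  expect_equal(perfect$ppv$point, 1)
  expect_equal(perfect$npv$point, 1)

  # empty gold class is an error; PPV undefined when nothing screens positive
  expect_error(summarize_diagnostics(confusion_cells(0, 0, 5, 0)),
               "gold-positive")
  s0 <- summarize_diagnostics(confusion_cells(0, 0, 5, 5))
  expect_null(s0$ppv)
  expect_equal(format_pct_ci(s0$ppv), "-")
})

test_that("reconstruction recovers the published confusion matrices", {
  m5 <- reconstruct_confusion(89.8, 82.8, 59, 180)
  expect_length(m5, 1)
  expect_equal(c(m5[[1]]$tp, m5[[1]]$fn, m5[[1]]$tn, m5[[1]]$fp),
               c(53, 6, 149, 31))
  expect_equal(m5[[1]]$tp + m5[[1]]$fp, 84)

  m1 <- reconstruct_confusion(88.1, 92.8, 59, 180)
  found <- Filter(function(m) m$tp == 52 && m$tn == 167, m1)
  expect_length(found, 1)
  expect_equal(found[[1]]$tp + found[[1]]$fp, 65)

  trivial <- reconstruct_confusion(100, 100, 10, 10)
  expect_length(trivial, 1)
  expect_equal(c(trivial[[1]]$tp, trivial[[1]]$fn), c(10, 0))

  # inconsistent inputs give an empty list, not an error
  expect_length(reconstruct_confusion(50.0, 50.0, 3, 3), 0)
})

test_that("reconstruction round-trips random matrices with margins <= 500", {
  set.seed(99)
  for (i in 1:40) {
    n_case <- sample(1:500, 1)
    n_control <- sample(1:500, 1)
    tp <- sample(0:n_case, 1)
    tn <- sample(0:n_control, 1)
    cands <- reconstruct_confusion(round_half_away(100 * tp / n_case),
                                   round_half_away(100 * tn / n_control),
                                   n_case, n_control)
    hit <- Filter(function(m) m$tp == tp && m$tn == tn, cands)
    expect_length(hit, 1)
  }
})

test_that("summaries conserve evaluable counts and tabulate per algorithm", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 8)
  algos <- alto_algorithms()
  suppressMessages(rep3 <- table3_report(cohort, algos))
  expect_equal(rep3$algorithm, c(1, 3, 5))
  expect_equal(rep3$tp + rep3$fp + rep3$tn + rep3$fn + rep3$n_excluded,
               rep(nrow(cohort), 3))
  expect_equal(rep3$n_positive, rep3$tp + rep3$fp)
  # every printed interval contains its point estimate
  for (col in c("sensitivity", "specificity", "ppv", "npv")) {
    nums <- regmatches(rep3[[col]], gregexpr("[0-9.]+", rep3[[col]]))
    for (v in nums) {
      v <- as.numeric(v)
      expect_true(v[2] <= v[1] && v[1] <= v[3])
    }
  }
  # an always-positive rule has sensitivity 100, specificity 0
  always <- list(structure(list(id = 99L, rule = parse_rule("Q1 | any(Q2,Q3,Q4,Q5)"),
                                description = "", source_confidence = "text_verified"),
                 class = "alto_algorithm"))
  forced <- cohort
  forced$q1 <- "yes"
  rep_always <- table3_report(forced, always)
  expect_match(rep_always$sensitivity, "^100.0")
  expect_match(rep_always$specificity, "^0.0")
})

test_that("simulate-evaluate-reconstruct round-trips the pipeline", {
  # the full chain: a simulated cohort's printed (rounded) sensitivity and
  # specificity, fed back through reconstruction with the evaluable group
  # sizes, must recover the evaluate stage's exact confusion matrix
  cohort <- generate_cohort(default_cohort_spec(), seed = 314)
  algos <- alto_algorithms()
  suppressMessages(rep3 <- table3_report(cohort, algos))
  for (i in seq_len(nrow(rep3))) {
    sens_printed <- as.numeric(sub(" .*", "", rep3$sensitivity[i]))
    spec_printed <- as.numeric(sub(" .*", "", rep3$specificity[i]))
    cands <- reconstruct_confusion(sens_printed, spec_printed,
                                   n_case = rep3$tp[i] + rep3$fn[i],
                                   n_control = rep3$fp[i] + rep3$tn[i])
    hit <- Filter(function(m) m$tp == rep3$tp[i] && m$tn == rep3$tn[i], cands)
    expect_length(hit, 1)
  }
})

test_that("global exclusion mode removes the same respondents from every row", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 21)
  algos <- alto_algorithms()
  suppressMessages(glob <- table3_report(cohort, algos, exclusion_mode = "global"))
  expect_equal(length(unique(glob$n_excluded)), 1)
  suppressMessages(per <- table3_report(cohort, algos))
  # per-algorithm exclusion can only drop fewer or equal respondents
  expect_true(all(per$n_excluded <= glob$n_excluded))
})
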