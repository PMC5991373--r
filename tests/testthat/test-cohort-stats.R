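test_that("Fisher's exact test matches hand-enumerable cases", {
  # diagonal 2x2: only the two permutation-extreme tables, p = 2/252
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-10)
  # perfectly balanced table: every margin-consistent table is as probable
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2)), 1)
  # the published sex-by-diagnosis comparison prints 0.004
  sex_tab <- matrix(c(9, 4, 37, 9, 167, 13), nrow = 2)
  expect_equal(round_half_away(fisher_exact(sex_tab), 3), 0.004)
  # enumeration bound: large tables must opt in to Monte-Carlo
  big <- matrix(c(300, 150, 200, 100), 2)
  expect_error(fisher_exact(big), "monte_carlo")
  set.seed(1)
  expect_true(fisher_exact(big, monte_carlo = TRUE, B = 2000) <= 1)
})

test_that("Fisher's exact test equals full margin enumeration on small tables", {
  set.seed(314)
  # exhaustive sweep of small 2x2 tables
  for (n in 2:12) {
    cells <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    cells <- cells[rowSums(cells) <= n, ]
    pick <- cells[sample(nrow(cells), min(25, nrow(cells))), ]
    for (i in seq_len(nrow(pick))) {
      tab <- matrix(c(pick$a[i], pick$b[i], pick$c[i],
                      n - pick$a[i] - pick$b[i] - pick$c[i]), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-8,
                   info = paste(tab, collapse = ","))
    }
  }
  # random 2x3 and 3x3 tables with total <= 30
  for (i in 1:40) {
    dims <- if (i %% 2) c(2, 3) else c(3, 3)
    tab <- matrix(stats::rpois(prod(dims), 2), dims[1])
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 30) next
    expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-8,
                 info = paste(tab, collapse = ","))
  }
})

test_that("one-way ANOVA matches the hand decomposition", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(res$F, 3)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  or <- oracle_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$p, or$p, tolerance = 1e-12)
  # identical groups: F = 0
  expect_equal(one_way_anova(list(a = c(1, 2), b = c(1, 2)))$F, 0)
  # degenerate inputs error
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "variance")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  for (i in 1:10) {
    a <- stats::rnorm(sample(3:20, 1), mean = stats::runif(1, 0, 5))
    b <- stats::rnorm(sample(3:20, 1))
    f <- one_way_anova(list(a = a, b = b))$F
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("ANOVA F is invariant under location shift and scaling", {
  set.seed(5)
  gs <- list(a = stats::rnorm(8, 1), b = stats::rnorm(10, 2),
             c = stats::rnorm(12, 3))
  f0 <- one_way_anova(gs)$F
  expect_equal(one_way_anova(lapply(gs, `+`, 100))$F, f0, tolerance = 1e-10)
  expect_equal(one_way_anova(lapply(gs, `*`, 7))$F, f0, tolerance = 1e-10)
})

test_that("Sidak adjustment has its closed form and monotonicity", {
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(0.5, 2), 0.75)
  expect_equal(sidak_adjust(1, 4), 1)
  p <- seq(0, 1, by = 0.05)
  adj <- vapply(p, sidak_adjust, numeric(1), m = 3)
  expect_true(all(diff(adj) >= 0))       # monotone in p
  expect_true(all(adj >= p))             # adjusted >= raw
  expect_true(all(sidak_adjust(0.2, 5) >= sidak_adjust(0.2, 2)))  # monotone in m
  expect_error(sidak_adjust(1.2, 2), "p")
})

test_that("the participant-characteristics report summarises a cohort", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 4)
  rep1 <- table1_report(cohort)
  expect_equal(as.vector(rep1$n), c(13, 46, 180))
  expect_equal(nrow(rep1$age$pairwise), 3)
  expect_true(all(rep1$age$pairwise$p_sidak >= rep1$age$pairwise$p_raw,
                  na.rm = TRUE))
  expect_true(rep1$sex$p >= 0 && rep1$sex$p <= 1)
  # percents are over known values only
  expect_equal(colSums(rep1$race$percent)[colSums(rep1$race$counts) > 0],
               c(totalis_universalis = 100, patchy = 100,
                 other_hair_loss = 100), tolerance = 1e-9)
  # all ages equal: degenerate ANOVA is flagged, not crashed
  flat <- cohort
  flat$age <- 50L
  repf <- table1_report(flat)
  expect_true(is.na(repf$age$anova$F))
  expect_false(is.null(repf$age$anova$degenerate))
})

test_that("patchy cases are detectably younger in simulated cohorts", {
  # power check for the age contrast the study reports as significant
  spec <- default_cohort_spec()
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    cohort <- generate_cohort(spec, seed = 9000 + r)
    rep1 <- table1_report(cohort)
    pw <- rep1$age$pairwise
    pair <- (pw$group1 == "patchy" & pw$group2 == "other_hair_loss") |
      (pw$group1 == "other_hair_loss" & pw$group2 == "patchy")
    if (pw$p_sidak[pair] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("item-response breakdown uses answered denominators and skip logic", {
  cohort <- make_cohort(
    make_resp(id = "a", diagnosis = "patchy", q3 = "yes", q3a = "yes",
              q3b = "no", q6 = "A;C"),
    make_resp(id = "b", diagnosis = "patchy", q3 = "no", q6 = "E"),
    make_resp(id = "c", diagnosis = "patchy", q3 = "missing", q6 = "missing"),
    make_resp(id = "d", diagnosis = "other_hair_loss", q1 = "yes",
              q3 = "yes", q3a = "missing", q3b = "yes", q6 = "none")
  )
  t2 <- table2_report(cohort)
  q3_patchy <- t2[t2$item == "Q3" & t2$class == "patchy", ]
  expect_equal(c(q3_patchy$n_yes, q3_patchy$n_answered), c(1, 2))
  # Q3A denominator: administered (Q3 = yes) and answered
  q3a_other <- t2[t2$item == "Q3A" & t2$class == "other_hair_loss", ]
  expect_equal(c(q3a_other$n_yes, q3a_other$n_answered), c(0, 0))
  q3a_patchy <- t2[t2$item == "Q3A" & t2$class == "patchy", ]
  expect_equal(c(q3a_patchy$n_yes, q3a_patchy$n_answered), c(1, 1))
  # picture denominators count answered forms only (e.g. "none" counts)
  picA_patchy <- t2[t2$item == "pic_A" & t2$class == "patchy", ]
  expect_equal(c(picA_patchy$n_yes, picA_patchy$n_answered), c(1, 2))
  picE_patchy <- t2[t2$item == "pic_E" & t2$class == "patchy", ]
  expect_equal(picE_patchy$n_yes, 1)
  pic_other <- t2[t2$item == "pic_A" & t2$class == "other_hair_loss", ]
  expect_equal(pic_other$n_answered, 1)
  # the any-of aggregate row
  any_patchy <- t2[t2$item == "any_yes" & t2$class == "patchy", ]
  expect_equal(c(any_patchy$n_yes, any_patchy$n_answered), c(1, 3))
})
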