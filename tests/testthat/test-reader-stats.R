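test_that("confusion tabulation uses printed as the positive class", {
  rs <- perfect_responses(8)
  cm <- tabulate_confusion(rs)
  expect_equal(c(cm$fp, cm$fn), c(0L, 0L))
  expect_equal(cm$tp + cm$tn, 8L)

  # miscalls land in the off-diagonal cells
  rs2 <- rs
  rs2$call[1] <- "patient"   # printed case called patient -> fn
  rs2$call[2] <- "printed"   # patient case called printed -> fp
  cm2 <- tabulate_confusion(rs2)
  expect_equal(cm2$fn, 1L)
  expect_equal(cm2$fp, 1L)

  expect_error(tabulate_confusion(rs[rs$experience == "resident", ]),
               "no responses")
})

test_that("published contingency tables reproduce their printed rates", {
  fx <- printed_count_fixtures()
  overall <- classification_rates(fx$overall)
  expect_equal(overall$accuracy, 53.5)
  expect_equal(overall$tpr, 52.5)
  expect_equal(overall$tnr, 55.5)
  expect_equal(overall$fnr, 47.5)
  expect_equal(overall$fpr, 44.5)

  senior <- classification_rates(fx$senior)
  expect_equal(senior$accuracy, 45.4)
  expect_equal(senior$fnr, 57.6)

  resident <- classification_rates(fx$resident)
  expect_equal(resident$tnr, 57.1)
  expect_equal(resident$fnr, 43.3)

  perfect <- classification_rates(confusion_matrix(1, 0, 0, 1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$tpr, 100)
  expect_equal(perfect$fnr, 0)

  # an absent class yields undefined class-conditional rates, not zero
  onesided <- classification_rates(confusion_matrix(5, 0, 2, 0))
  expect_true(is.na(onesided$tnr))
  expect_true(is.na(onesided$fpr))
  expect_false(is.na(onesided$tpr))
})

test_that("rate pairs are complementary for arbitrary confusion matrices", {
  set.seed(4)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(1:200, 1), sample(1:200, 1),
                           sample(1:200, 1), sample(1:200, 1))
    r <- classification_rates(cm)
    expect_lte(abs(r$tpr + r$fnr - 100), 0.1)
    expect_lte(abs(r$tnr + r$fpr - 100), 0.1)
  }
})

test_that("chi-square goodness of fit matches hand-computed statistics", {
  # exact fit
  g0 <- chi2_goodness_of_fit(50, 50, 0.5)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)
  # all-readers correct/incorrect split against guessing
  g1 <- chi2_goodness_of_fit(573, 498, 0.5)
  expect_equal(g1$statistic, 2 * 37.5^2 / 535.5, tolerance = 1e-12)
  expect_lt(abs(g1$statistic - 5.2522), 1e-4)
  g2 <- chi2_goodness_of_fit(143, 172, 0.5)
  expect_lt(abs(g2$statistic - 2.6698), 1e-4)
  # p-value from the chi-square distribution with 1 df
  expect_equal(g1$p_value, pchisq(g1$statistic, 1, lower.tail = FALSE))
  expect_error(chi2_goodness_of_fit(-1, 5), "non-negative")
  expect_error(chi2_goodness_of_fit(5, 5, 0), "strictly")
  expect_error(chi2_goodness_of_fit(0, 0), "observations")
})

test_that("Conger's kappa matches hand calculation and perfect agreement", {
  same <- cbind(c(1, 2, 1, 2, 2), c(1, 2, 1, 2, 2), c(1, 2, 1, 2, 2))
  expect_equal(conger_kappa(same)$kappa, 1)

  k <- conger_kappa(cbind(c(1, 1, 2, 2), c(1, 2, 2, 2)))
  expect_equal(k$po, 0.75)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.5)

  # single category everywhere: chance agreement 1, kappa undefined
  const <- matrix(1, 4, 3)
  expect_true(is.na(conger_kappa(const)$kappa))

  expect_error(conger_kappa(matrix(1, 1, 3)), "at least 2")
})

test_that("two-rater Conger's kappa reduces to Cohen's kappa", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    k_cat <- sample(2:4, 1)
    a <- sample(seq_len(k_cat), n, replace = TRUE)
    b <- sample(seq_len(k_cat), n, replace = TRUE)
    expected <- cohen_kappa(a, b)
    got <- conger_kappa(cbind(a, b))$kappa
    if (is.na(expected) || !is.finite(expected)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("independent guessing yields near-zero multi-rater agreement", {
  set.seed(1)
  ratings <- matrix(sample(1:2, 63 * 17, replace = TRUE), 63, 17)
  k <- conger_kappa(ratings)
  expect_lt(abs(k$kappa), 0.05)
  expect_equal(k$n_raters, 17L)
  expect_equal(k$n_items, 63L)
})

test_that("bootstrap intervals are seeded, degenerate-safe and calibrated", {
  # degenerate distribution: all responses correct
  ci <- bootstrap_ci(perfect_responses(20), "accuracy", B = 200, seed = 2)
  expect_equal(ci, c(100, 100))

  # determinism
  rs <- bernoulli_responses(300, 0.5, seed = 5)
  ci1 <- bootstrap_ci(rs, "accuracy", B = 300, seed = 11)
  ci2 <- bootstrap_ci(rs, "accuracy", B = 300, seed = 11)
  expect_identical(ci1, ci2)

  # width agrees with the normal approximation 2 * 1.96 * sqrt(p q / n)
  big <- bernoulli_responses(1000, 0.5, seed = 1)
  ciw <- bootstrap_ci(big, "accuracy", B = 2000, seed = 7)
  expect_gt(diff(ciw) / 100, 0.04)
  expect_lt(diff(ciw) / 100, 0.09)

  # reader- and case-level units run and contain the point estimate
  rr <- make_synthetic_responses(response_recipe(seed = 3))
  acc <- unname(100 * mean(rr$call == rr$truth))
  for (unit in c("reader", "case")) {
    ciu <- bootstrap_ci(rr, "accuracy", unit = unit, B = 200, seed = 13)
    expect_gte(acc, ciu[1] - 5)
    expect_lte(acc, ciu[2] + 5)
  }
})

test_that("confidence summary reports proportions and likelihood ratios", {
  # identical confidence distributions: all defined ratios are 1
  truth <- rep(c("printed", "patient"), each = 10)
  call <- c(rep("printed", 5), rep("patient", 5),
            rep("patient", 5), rep("printed", 5))
  correct_idx <- c(1:5, 11:15)
  conf <- integer(20)
  conf[correct_idx] <- rep(c(2L, 3L), 5)   # correct group: 5 x 2, 5 x 3
  conf[-correct_idx] <- rep(c(2L, 3L), 5)  # incorrect group: identical
  rs <- response_set(data.frame(reader_id = "R01", experience = "senior",
                                case_id = sprintf("C%02d", 1:20),
                                presentation = 1L, truth = truth,
                                call = call, confidence = conf))
  cs <- confidence_summary(rs)
  expect_equal(cs$lr[cs$confidence %in% c(2, 3)], c(1, 1))
  expect_true(all(is.na(cs$lr[cs$confidence %in% c(1, 4, 5)])))

  # point mass at level 5
  rs5 <- perfect_responses(6)
  cs5 <- confidence_summary(rs5)
  expect_equal(cs5$n[cs5$confidence == 5], 6L)
  expect_equal(sum(cs5$n), 6L)

  # correct (10 x lvl4, 10 x lvl2) vs incorrect (5 x lvl4, 15 x lvl2)
  truth2 <- rep("printed", 40)
  call2 <- c(rep("printed", 20), rep("patient", 20))
  conf2 <- c(rep(4L, 10), rep(2L, 10), rep(4L, 5), rep(2L, 15))
  rs2 <- response_set(data.frame(reader_id = "R01", experience = "senior",
                                 case_id = "C01", presentation = 1L,
                                 truth = truth2, call = call2,
                                 confidence = conf2))
  cs2 <- confidence_summary(rs2)
  expect_equal(cs2$lr[cs2$confidence == 4], 2)
  expect_equal(cs2$lr[cs2$confidence == 2], (10 / 20) / (15 / 20))
})

test_that("response CSV round trips through the schema validator", {
  rs <- make_synthetic_responses(response_recipe(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_responses(rs, path)
  back <- read_responses(path)
  expect_equal(nrow(back), nrow(rs))
  expect_equal(back$call, rs$call)
  bad <- as.data.frame(rs)[, -3]
  path2 <- tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_responses(path2), "lacks columns")
})
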