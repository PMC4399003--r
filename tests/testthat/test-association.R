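test_that("PAP classification uses strict thresholds with an uncertain zone", {
  expect_equal(classify_status(c(94, 30, 45, 50, 39)),
               c("affected", "unaffected", "indeterminate",
                 "indeterminate", "indeterminate"))
  # replication-herd convention: affected at PAP >= 45, unaffected <= 39
  expect_equal(classify_status(c(45, 39), affected_min = 45,
                               unaffected_max = 39,
                               affected_inclusive = TRUE,
                               unaffected_inclusive = TRUE),
               c("affected", "unaffected"))
  expect_error(classify_status(50, affected_min = 39, unaffected_max = 50),
               "inverted")
})

test_that("Pearson chi-square matches closed form and stats::chisq.test", {
  res <- chi2_2x2(herd1_table())
  expect_equal(res$statistic, 12.8968, tolerance = 1e-4)
  expect_equal(res$p.value, 3.3e-4, tolerance = 0.01)

  # proportional rows carry no association
  flat <- chi2_2x2(contingency_2x2(10, 10, 5, 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  # swapping rows or columns leaves the p-value unchanged
  expect_equal(chi2_2x2(c(4, 17, 15, 5))$p.value, res$p.value)
  expect_equal(chi2_2x2(c(5, 15, 17, 4))$p.value, res$p.value)

  expect_true(is.na(chi2_2x2(contingency_2x2(0, 0, 4, 17))$statistic))

  # the optional exact route agrees on the direction of evidence
  expect_lt(fisher_2x2(herd1_table())$p.value, 0.01)

  set.seed(21)
  for (i in 1:50) {
    cells <- rpois(4, 8) + 1
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(chi2_2x2(cells)$p.value,
                 suppressWarnings(chisq.test(m, correct = FALSE))$p.value)
    expect_equal(chi2_2x2(cells, yates = TRUE)$p.value,
                 suppressWarnings(chisq.test(m, correct = TRUE))$p.value)
  }
  # Yates deviation is floored at zero, never negative
  expect_equal(chi2_2x2(c(5, 5, 5, 5), yates = TRUE)$statistic, 0)
})

test_that("Armitage trend matches stats::prop.trend.test and collapses to
           the carrier chi-square under dominant weights", {
  flat <- armitage_trend(matrix(c(6, 3, 1, 12, 6, 2), 2, byrow = TRUE))
  expect_equal(flat$p.value, 1)

  set.seed(22)
  for (i in 1:50) {
    counts <- matrix(rpois(6, 6) + 1, 2, byrow = TRUE)
    ours <- armitage_trend(counts)
    ref <- suppressWarnings(
      prop.trend.test(counts[1, ], colSums(counts), score = c(0, 1, 2)))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value)

    # weights (0,1,1) reproduce the uncorrected carrier chi-square
    dom <- armitage_trend(counts, weights = c(0, 1, 1))
    tab <- contingency_2x2(counts[1, 2] + counts[1, 3], counts[1, 1],
                           counts[2, 2] + counts[2, 3], counts[2, 1])
    expect_equal(dom$statistic, chi2_2x2(tab)$statistic)
  }

  degenerate <- matrix(c(5, 0, 0, 7, 0, 0), 2, byrow = TRUE)
  expect_true(is.na(armitage_trend(degenerate)$statistic))
})

test_that("exact rank-sum agrees with enumeration limits and wilcox.test", {
  expect_equal(rank_sum(c(3, 5, 9), c(3, 5, 9))$p.value, 1)
  # complete separation of 3 vs 3: 2 of the 20 rank splits are as extreme
  expect_equal(rank_sum(c(1, 2, 3), c(10, 11, 12))$p.value, 0.1)

  set.seed(23)
  for (i in 1:30) {
    n_a <- sample(2:6, 1)
    n_b <- sample(2:6, 1)
    a <- rnorm(n_a)  # continuous, tie-free
    b <- rnorm(n_b)
    ours <- rank_sum(a, b, mode = "exact")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value)
  }
})

test_that("normal-approximation rank-sum tracks the exact path", {
  set.seed(24)
  rel_err <- replicate(20, {
    a <- rnorm(15)  # tie-free, so the exact reference is well defined
    b <- rnorm(15, mean = 0.6)
    pe <- wilcox.test(a, b, exact = TRUE)$p.value
    pn <- rank_sum(a, b, mode = "normal_approx")$p.value
    abs(pn - pe) / pe
  })
  expect_lt(median(rel_err), 0.10)
  # mid-ranks make the tied-data path well defined in both modes
  a <- c(1, 2, 2, 3, 5, 5, 6, 8)
  b <- c(2, 3, 3, 5, 7, 7, 8, 9)
  expect_gt(rank_sum(a, b, mode = "exact")$p.value, 0)
  expect_gt(rank_sum(a, b, mode = "normal_approx")$p.value, 0)
})

test_that("relative risk and odds ratio follow log-scale Wald closed forms", {
  rr <- relative_risk(herd1_table())
  expect_equal(rr$estimate, (15 / 19) / (5 / 22))
  or <- odds_ratio(herd1_table())
  expect_equal(or$estimate, 12.75)

  flat <- relative_risk(contingency_2x2(10, 10, 10, 10))
  expect_equal(flat$estimate, 1)
  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10))$estimate, 1)

  # OR reciprocity when the status rows are exchanged
  set.seed(25)
  for (i in 1:25) {
    cells <- rpois(4, 10) + 1
    o1 <- odds_ratio(cells)$estimate
    o2 <- odds_ratio(cells[c(3, 4, 1, 2)])$estimate
    expect_equal(o1 * o2, 1)

    # independently coded Wald intervals
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    se_rr <- sqrt(1 / a - 1 / (a + c) + 1 / b - 1 / (b + d))
    rr_i <- relative_risk(cells)
    expect_equal(rr_i$conf_low, rr_i$estimate * exp(-1.96 * se_rr))
    se_or <- sqrt(sum(1 / cells))
    or_i <- odds_ratio(cells)
    expect_equal(or_i$conf_high, or_i$estimate * exp(1.96 * se_or))
  }

  # symmetric CI in log space for the unit table
  unit <- odds_ratio(contingency_2x2(1, 1, 1, 1))
  expect_equal(log(unit$conf_low), -log(unit$conf_high))

  zero <- relative_risk(contingency_2x2(0, 5, 4, 17))
  expect_true(is.na(zero$conf_low))
  corrected <- odds_ratio(contingency_2x2(0, 5, 4, 17), correct = TRUE)
  expect_false(is.na(corrected$conf_low))
})

test_that("Wald RR interval attains nominal coverage on simulated tables", {
  set.seed(26)
  n1 <- 120; n2 <- 120; p1 <- 0.5; p2 <- 0.25
  true_rr <- p1 / p2
  covered <- replicate(1500, {
    a <- rbinom(1, n1, p1)
    b <- rbinom(1, n2, p2)
    if (a == 0 || b == 0) return(NA)
    rr <- relative_risk(c(a, b, n1 - a, n2 - b))
    rr$conf_low <= true_rr && true_rr <= rr$conf_high
  })
  expect_gt(mean(covered, na.rm = TRUE), 0.925)
  expect_lt(mean(covered, na.rm = TRUE), 0.975)
})

test_that("predictive values obey Bayes rule, bounds and monotonicity", {
  pv <- predictive_values(15 / 20, 17 / 21, 0.5)
  expect_equal(round(100 * pv$ppv, 1), 79.7)
  expect_equal(round(100 * pv$npv, 1), 76.4)

  perfect <- predictive_values(1, 1, 0.3)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  prevs <- seq(0.05, 0.95, by = 0.05)
  ppvs <- vapply(prevs,
                 function(p) predictive_values(0.75, 0.81, p)$ppv, numeric(1))
  npvs <- vapply(prevs,
                 function(p) predictive_values(0.75, 0.81, p)$npv, numeric(1))
  expect_true(all(diff(ppvs) >= 0))
  expect_true(all(diff(npvs) <= 0))
  expect_error(predictive_values(1.2, 0.5, 0.5), "lie in")
})

test_that("pooling tables is cell-wise, order-invariant and identity-safe", {
  pooled <- pool_tables(list(herd1_table(), herd2_table()))
  expect_equal(unlist(pooled[c("a", "b", "c", "d")]),
               c(a = 26, b = 9, c = 8, d = 29))
  swapped <- pool_tables(list(herd2_table(), herd1_table()))
  expect_identical(pooled, swapped)
  single <- pool_tables(list(herd1_table()))
  expect_identical(single, herd1_table())
})
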