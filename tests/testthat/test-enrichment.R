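make_groups <- function(n = 5) {
  list(affected = sprintf("A%02d", seq_len(n)),
       unaffected = sprintf("U%02d", seq_len(n)))
}

# deterministic expression matrix: named per-gene group means, tiny noise
mock_expr <- function(mean_aff, mean_un, groups, sd = 0.05, seed = 91) {
  set.seed(seed)
  genes <- names(mean_aff)
  n_a <- length(groups$affected)
  n_u <- length(groups$unaffected)
  m <- cbind(
    matrix(rnorm(length(genes) * n_a, rep(mean_aff, n_a), sd),
           ncol = n_a),
    matrix(rnorm(length(genes) * n_u, rep(mean_un, n_u), sd),
           ncol = n_u))
  dimnames(m) <- list(genes, c(groups$affected, groups$unaffected))
  m
}

test_that("expression floor keeps genes expressed in either group", {
  groups <- make_groups()
  mean_aff <- c(hi_both = 9, hi_aff = 8, hi_un = 2, lo = 2, at_floor = 7)
  mean_un <- c(hi_both = 9, hi_aff = 2, hi_un = 8, lo = 2, at_floor = 7)
  expr <- mock_expr(mean_aff, mean_un, groups, sd = 0)
  kept <- expressed_subset(expr, names(mean_aff), groups, floor = 7)
  # strict inequality: a gene exactly at the floor in both groups is out
  expect_setequal(kept, c("hi_both", "hi_aff", "hi_un"))
  # floor of -Inf keeps every mapped gene
  expect_setequal(expressed_subset(expr, names(mean_aff), groups,
                                   floor = -Inf),
                  names(mean_aff))
  expect_warning(expressed_subset(expr, c("hi_both", "ghost"), groups),
                 "absent")
})

test_that("direction calls require both significance and fold change", {
  groups <- make_groups(10)
  mean_aff <- c(up = 10, down = 8.5, fc_only = 10)
  mean_un <- c(up = 9, down = 9.5, fc_only = 9.9)
  expr <- mock_expr(mean_aff, mean_un, groups, sd = 0.05)
  calls <- call_direction(expr, names(mean_aff), groups)
  expect_equal(unname(calls["up"]), "up")
  expect_equal(unname(calls["down"]), "down")
  # significant but under the 1.25-fold threshold
  expect_equal(unname(calls["fc_only"]), "neither")

  # noise-free boundary: fold change exactly at the threshold fails the
  # strict inequality; a flat zero-variance gene is never called
  edge <- mock_expr(c(exact_fc = 9 + log2(1.25), flat = 9),
                    c(exact_fc = 9, flat = 9), groups, sd = 0)
  edge_calls <- call_direction(edge, c("exact_fc", "flat"), groups)
  expect_equal(unname(edge_calls), c("neither", "neither"))

  # identical constant values in both groups: no call, no error
  const <- matrix(5, 2, 20,
                  dimnames = list(c("g1", "g2"),
                                  c(groups$affected, groups$unaffected)))
  expect_equal(unname(call_direction(const, c("g1", "g2"), groups)),
               c("neither", "neither"))
  expect_error(call_direction(expr, "up", make_groups(1)), ">= 2 samples")
})

test_that("vectorized t-test matches stats::t.test gene by gene", {
  set.seed(92)
  groups <- make_groups(6)
  genes <- sprintf("g%02d", 1:30)
  expr <- mock_expr(setNames(runif(30, 8, 11), genes),
                    setNames(runif(30, 8, 11), genes), groups, sd = 0.5)
  a <- expr[, groups$affected]
  b <- expr[, groups$unaffected]
  for (flavor in c("welch", "student")) {
    got <- haphseg:::row_t_test(a, b, flavor)
    for (g in sample(genes, 8)) {
      ref <- t.test(a[g, ], b[g, ], var.equal = flavor == "student")
      expect_equal(unname(got$p[match(g, genes)]), ref$p.value)
    }
  }
})

test_that("background rates recover planted up/down fractions", {
  groups <- make_groups()
  genes <- sprintf("g%03d", 1:100)
  mean_un <- setNames(rep(9, 100), genes)
  mean_aff <- mean_un
  mean_aff[1:7] <- 10    # 7% up
  mean_aff[8:15] <- 8    # 8% down
  expr <- mock_expr(mean_aff, mean_un, groups, sd = 0.05)
  rates <- background_rates(expr, groups)
  expect_equal(rates$p_up, 0.07)
  expect_equal(rates$p_down, 0.08)
  expect_equal(rates$n_background, 100)

  low <- mock_expr(setNames(rep(3, 5), letters[1:5]),
                   setNames(rep(3, 5), letters[1:5]), groups)
  expect_error(background_rates(low, groups), "floor")
})

test_that("three-category chi-square handles both expectation modes", {
  res <- enrichment_chi2(c(26, 1, 41), 68, c(0.07, 0.08),
                         mode = "rounded_counts")
  expect_equal(unname(res$expected), c(5, 5, 58))
  expect_equal(res$statistic, 96.4, tolerance = 1e-3)
  expect_equal(res$df, 2L)
  expect_lt(res$p.value, 1e-4)

  raw <- enrichment_chi2(c(26, 1, 41), 68, c(0.07, 0.08),
                         mode = "raw_proportions")
  # direct evaluation against E = (4.76, 5.44, 57.8)
  expect_equal(raw$statistic,
               sum((c(26, 1, 41) - c(4.76, 5.44, 57.8))^2 /
                     c(4.76, 5.44, 57.8)))

  eq <- enrichment_chi2(c(5, 5, 58), 68, c(0.07, 0.08))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  # invariant to swapping the two tail categories
  swap <- enrichment_chi2(c(1, 26, 41), 68, c(0.08, 0.07))
  expect_equal(swap$statistic, res$statistic)

  # statistic strictly increases as the up-count moves away from expected
  stats_up <- vapply(c(6, 10, 20, 26), function(u)
    enrichment_chi2(c(u, 5, 63 - u), 68, c(0.07, 0.08))$statistic,
    numeric(1))
  expect_true(all(diff(stats_up) > 0))

  undef <- enrichment_chi2(c(2, 0, 18), 20, c(0.1, 0.001))
  expect_true(is.na(undef$statistic))
  expect_match(undef$note, "zero expected")

  expect_error(enrichment_chi2(c(1, 2, 3), 7, c(0.1, 0.1)), "sum")
})

test_that("end-to-end enrichment on a simulated cohort detects the shift", {
  cohort <- simulate_cohort(cohort_config(
    n_affected = 10, n_unaffected = 10, penetrance = 1, phenocopy = 0,
    background_variants = 0, seed = 95))
  gs <- sprintf("HIF_%02d", 1:27)
  expr <- simulate_expression(cohort, gs, upshift = 2,
                              n_background_genes = 800, noise_sd = 0.5,
                              seed = 96)
  groups <- list(
    affected = cohort$phenotypes$sample_id[
      cohort$phenotypes$status == "affected"],
    unaffected = cohort$phenotypes$sample_id[
      cohort$phenotypes$status == "unaffected"])
  res <- run_enrichment(expr, gs, groups)
  expect_s3_class(res, "enrichment_result")
  expect_equal(sum(res$observed), res$n_expressed)
  expect_gt(res$observed["up"], res$expected["up"])
  expect_lt(res$p.value, 0.01)
  expect_length(res$calls, res$n_expressed)
})
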