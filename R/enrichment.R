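#' Configuration of the expression-enrichment test
#'
#' @param expression_floor minimum log2 group-mean expression for a gene
#'   to count as reliably measured (default 7, strict inequality).
#' @param p_threshold per-gene alpha for the uncorrected t-test
#'   (default 0.05).
#' @param fc_threshold linear fold-change threshold (> 1, default 1.25);
#'   fold change is computed from anti-logged group means,
#'   `2^(mean_affected - mean_unaffected)`.
#' @param expected_mode `"rounded_counts"` (expected category counts
#'   rounded to integers, remainder absorbed by the "neither" category)
#'   or `"raw_proportions"` (fractional expected counts).
#' @param t_flavor `"welch"` (default) or `"student"`
#'   (pooled variance).
#' @return list of class `enrichment_config`.
#' @export
enrichment_config <- function(expression_floor = 7, p_threshold = 0.05,
                              fc_threshold = 1.25,
                              expected_mode = c("rounded_counts",
                                                "raw_proportions"),
                              t_flavor = c("welch", "student")) {
  expected_mode <- match.arg(expected_mode)
  t_flavor <- match.arg(t_flavor)
  if (!is.finite(expression_floor)) stopf("expression_floor must be finite")
  if (!is_prob(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stopf("p_threshold must lie strictly in (0, 1)")
  if (fc_threshold <= 1) stopf("fc_threshold must exceed 1")
  structure(list(expression_floor = expression_floor,
                 p_threshold = p_threshold, fc_threshold = fc_threshold,
                 expected_mode = expected_mode, t_flavor = t_flavor),
            class = "enrichment_config")
}

check_groups <- function(expr, groups) {
  if (!is.list(groups) || !all(c("affected", "unaffected") %in% names(groups)))
    stopf("groups must be list(affected = ids, unaffected = ids)")
  miss <- setdiff(c(groups$affected, groups$unaffected), colnames(expr))
  if (length(miss) > 0L)
    stopf("sample(s) absent from expression table: %s",
          paste(miss, collapse = ", "))
  groups
}

#' Restrict a gene set to reliably expressed genes
#'
#' A gene is retained iff its mean log2 expression strictly exceeds the
#' floor in the affected group or in the unaffected group. Symbols
#' absent from the table are dropped with a warning.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param genes character vector of gene symbols.
#' @param groups `list(affected = ids, unaffected = ids)`.
#' @param floor log2 expression floor (default 7).
#' @return character vector of retained symbols (input order).
#' @export
expressed_subset <- function(expr, genes, groups, floor = 7) {
  groups <- check_groups(expr, groups)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0L)
    warnf("%d gene-set symbol(s) absent from expression table (dropped)",
          length(absent))
  genes <- intersect(genes, rownames(expr))
  m_aff <- rowMeans(expr[genes, groups$affected, drop = FALSE], na.rm = TRUE)
  m_un <- rowMeans(expr[genes, groups$unaffected, drop = FALSE], na.rm = TRUE)
  genes[m_aff > floor | m_un > floor]
}

# vectorized two-sample t-test over rows of two matrices
row_t_test <- function(a, b, flavor = "welch") {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (flavor == "welch") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  }
  tt <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate zero-variance rows: equal means carry no evidence (p = 1),
  # unequal means are infinitely significant (p = 0)
  nan <- is.nan(p)
  p[nan] <- ifelse(abs(ma - mb)[nan] > 0, 0, 1)
  list(t = tt, df = df, p = p, diff = ma - mb)
}

#' Call per-gene differential-expression direction
#'
#' A gene is called `up` iff the two-sided uncorrected t-test p-value is
#' below `p_threshold` and the linear fold change
#' `2^(mean_affected - mean_unaffected)` strictly exceeds
#' `fc_threshold`; `down` symmetrically with the reciprocal fold
#' change; otherwise `neither`.
#'
#' @param expr log2 expression matrix.
#' @param genes symbols to call (must be rows of `expr`).
#' @param groups `list(affected = ids, unaffected = ids)`, each with
#'   >= 2 samples.
#' @param cfg an [enrichment_config()].
#' @return named character vector over `genes` with values
#'   `up`/`down`/`neither`.
#' @export
call_direction <- function(expr, genes, groups, cfg = enrichment_config()) {
  groups <- check_groups(expr, groups)
  if (length(groups$affected) < 2L || length(groups$unaffected) < 2L)
    stopf("need >= 2 samples per group for a t-test")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss) > 0L)
    stopf("gene(s) absent from expression table: %s",
          paste(utils::head(miss, 3L), collapse = ", "))
  a <- expr[genes, groups$affected, drop = FALSE]
  b <- expr[genes, groups$unaffected, drop = FALSE]
  tt <- row_t_test(a, b, cfg$t_flavor)
  fc <- 2^tt$diff
  out <- rep("neither", length(genes))
  sig <- !is.na(tt$p) & tt$p < cfg$p_threshold
  out[sig & fc > cfg$fc_threshold] <- "up"
  out[sig & fc < 1 / cfg$fc_threshold] <- "down"
  stats::setNames(out, genes)
}

#' Empirical background up/down call rates
#'
#' Applies the expression floor and [call_direction()] to every gene of
#' the genome-wide table and returns the fractions called up and down —
#' the empirical expectation under random variation for the enrichment
#' test.
#'
#' @param expr genome-wide log2 expression matrix.
#' @param groups `list(affected = ids, unaffected = ids)`.
#' @param cfg an [enrichment_config()].
#' @return list with `p_up`, `p_down`, `n_background` (floor-passing
#'   gene count).
#' @export
background_rates <- function(expr, groups, cfg = enrichment_config()) {
  groups <- check_groups(expr, groups)
  expressed <- expressed_subset(expr, rownames(expr), groups,
                                floor = cfg$expression_floor)
  if (length(expressed) == 0L)
    stopf("no genes pass the expression floor of %g", cfg$expression_floor)
  calls <- call_direction(expr, expressed, groups, cfg)
  list(p_up = mean(calls == "up"), p_down = mean(calls == "down"),
       n_background = length(expressed))
}

#' Three-category enrichment chi-square
#'
#' Compares observed (up, down, neither) counts within the expressed
#' gene set against expected counts from background rates. In
#' `rounded_counts` mode each expected tail count is rounded to the
#' nearest integer and the "neither" category absorbs the remainder; in
#' `raw_proportions` mode expected counts stay fractional. Pearson
#' chi-square with 2 degrees of freedom.
#'
#' @param observed numeric length-3 vector `(up, down, neither)`.
#' @param n expressed gene-set size; must equal `sum(observed)`.
#' @param rates list or numeric with `p_up` and `p_down`.
#' @param mode `"rounded_counts"` or `"raw_proportions"`.
#' @return object of class `enrichment_result`: list with `observed`,
#'   `expected`, `statistic`, `df = 2`, `p.value`, `mode`, `note`.
#' @export
enrichment_chi2 <- function(observed, n, rates,
                            mode = c("rounded_counts", "raw_proportions")) {
  mode <- match.arg(mode)
  if (length(observed) != 3L || any(observed < 0))
    stopf("observed must be (up, down, neither) counts")
  if (sum(observed) != n)
    stopf("observed counts sum to %d, not n = %d", sum(observed), n)
  p_up <- if (is.list(rates)) rates$p_up else rates[1]
  p_down <- if (is.list(rates)) rates$p_down else rates[2]
  if (!is_prob(p_up) || !is_prob(p_down) || p_up + p_down > 1)
    stopf("rates must be proportions with p_up + p_down <= 1")
  if (mode == "rounded_counts") {
    e_up <- round(n * p_up)
    e_down <- round(n * p_down)
    expected <- c(e_up, e_down, n - e_up - e_down)
  } else {
    expected <- c(n * p_up, n * p_down, n * (1 - p_up - p_down))
  }
  names(expected) <- names(observed) <- c("up", "down", "neither")
  if (any(expected == 0))
    return(structure(list(observed = observed, expected = expected,
                          statistic = NA_real_, df = 2L, p.value = NA_real_,
                          mode = mode, note = "undefined: zero expected count"),
                     class = "enrichment_result"))
  stat <- sum((observed - expected)^2 / expected)
  structure(list(observed = observed, expected = expected, statistic = stat,
                 df = 2L,
                 p.value = stats::pchisq(stat, df = 2L, lower.tail = FALSE),
                 mode = mode, note = ""),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("gene-set enrichment (three-category chi-square)\n")
  cat(sprintf("  observed: up=%g down=%g neither=%g\n",
              x$observed[1], x$observed[2], x$observed[3]))
  cat(sprintf("  expected: up=%g down=%g neither=%g (%s)\n",
              x$expected[1], x$expected[2], x$expected[3], x$mode))
  if (is.na(x$statistic)) cat(sprintf("  %s\n", x$note))
  else cat(sprintf("  chi-square = %.4g, df = %d, p = %.3g\n",
                   x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Run the full expression-enrichment procedure
#'
#' Floor-filters the gene set, calls per-gene direction inside it,
#' estimates background up/down rates from the genome-wide table with
#' the same criteria, and computes the three-category chi-square.
#'
#' @param expr genome-wide log2 expression matrix.
#' @param gene_set character vector of gene symbols.
#' @param groups `list(affected = ids, unaffected = ids)`.
#' @param cfg an [enrichment_config()].
#' @return an `enrichment_result` with extra elements `n_expressed`,
#'   `calls` (named per-gene direction vector) and `rates`.
#' @export
run_enrichment <- function(expr, gene_set, groups,
                           cfg = enrichment_config()) {
  if (length(gene_set) == 0L) stopf("gene set is empty")
  expressed <- expressed_subset(expr, gene_set, groups,
                                floor = cfg$expression_floor)
  if (length(expressed) == 0L)
    stopf("no gene-set genes pass the expression floor")
  calls <- call_direction(expr, expressed, groups, cfg)
  observed <- c(sum(calls == "up"), sum(calls == "down"),
                sum(calls == "neither"))
  rates <- background_rates(expr, groups, cfg)
  res <- enrichment_chi2(observed, length(expressed), rates,
                         mode = cfg$expected_mode)
  res$n_expressed <- length(expressed)
  res$calls <- calls
  res$rates <- rates
  res
}
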