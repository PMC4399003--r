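#' 2x2 carrier-by-status contingency table
#'
#' Cell layout: `a` affected carriers, `b` affected non-carriers,
#' `c` unaffected carriers, `d` unaffected non-carriers.
#'
#' @param a,b,c,d non-negative integer counts, total >= 1.
#' @return object of class `ctab2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!vapply(cells, is_count, logical(1))))
    stopf("all four cells must be non-negative integers")
  if (sum(cells) < 1) stopf("table total must be >= 1")
  structure(as.list(cells), class = "ctab2x2")
}

#' @export
print.ctab2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("affected", "unaffected"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

#' Build the carrier-by-status table from carrier flags and statuses
#'
#' @param carrier named logical vector of carrier flags.
#' @param status named character vector (`affected`/`unaffected`) over
#'   the same sample ids.
#' @return a [contingency_2x2()].
#' @export
tabulate_carriers <- function(carrier, status) {
  ids <- intersect(names(carrier), names(status))
  keep <- ids[status[ids] %in% c("affected", "unaffected")]
  carrier <- carrier[keep]
  status <- status[keep]
  contingency_2x2(sum(carrier & status == "affected"),
                  sum(!carrier & status == "affected"),
                  sum(carrier & status == "unaffected"),
                  sum(!carrier & status == "unaffected"))
}

#' Classify disease status from mean PAP
#'
#' Strict thresholds by default, matching extreme-group definitions:
#' PAP above `affected_min` is affected, below `unaffected_max` is
#' unaffected, anything between falls in the indeterminate zone.
#' Inclusive bounds (e.g. affected at PAP >= 45 for a replication herd)
#' are available via the `*_inclusive` flags.
#'
#' @param pap numeric vector of mean PAP values (mm Hg).
#' @param affected_min affected threshold (default 50).
#' @param unaffected_max unaffected threshold (default 39).
#' @param affected_inclusive,unaffected_inclusive use `>=` / `<=`
#'   instead of strict inequalities.
#' @return character vector in
#'   `{"affected", "unaffected", "indeterminate"}`.
#' @export
classify_status <- function(pap, affected_min = 50, unaffected_max = 39,
                            affected_inclusive = FALSE,
                            unaffected_inclusive = FALSE) {
  if (unaffected_max >= affected_min)
    stopf("thresholds inverted: unaffected_max must be < affected_min")
  aff <- if (affected_inclusive) pap >= affected_min else pap > affected_min
  un <- if (unaffected_inclusive) pap <= unaffected_max else pap < unaffected_max
  out <- rep("indeterminate", length(pap))
  out[aff] <- "affected"
  out[un] <- "unaffected"
  out
}

as_ctab <- function(t) {
  if (inherits(t, "ctab2x2")) return(t)
  if (is.numeric(t) && length(t) == 4L)
    return(contingency_2x2(t[1], t[2], t[3], t[4]))
  stopf("expected a ctab2x2 or a length-4 numeric (a, b, c, d)")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with a
#' 1-df chi-square reference; the Yates variant subtracts `n/2` from
#' `|ad - bc|` (floored at zero) before squaring. No continuity
#' correction by default. A zero margin makes the statistic undefined
#' and is reported as `NA` with a note.
#'
#' @param t a [contingency_2x2()] or length-4 numeric `(a, b, c, d)`.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `df`, `p.value`, `yates`, `note`.
#' @export
chi2_2x2 <- function(t, yates = FALSE) {
  t <- as_ctab(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(list(statistic = NA_real_, df = 1L, p.value = NA_real_,
                yates = yates, note = "undefined: zero margin"))
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       yates = yates, note = "")
}

#' Fisher's exact test on a 2x2 table
#'
#' Optional small-cell alternative to [chi2_2x2()]; never the default
#' reporting route. Thin wrapper over [stats::fisher.test()].
#'
#' @param t a [contingency_2x2()] or length-4 numeric `(a, b, c, d)`.
#' @return list with `p.value` and the conditional MLE `or`.
#' @export
fisher_2x2 <- function(t) {
  t <- as_ctab(t)
  ft <- stats::fisher.test(matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE))
  list(p.value = ft$p.value, or = unname(ft$estimate))
}

#' Cochran-Armitage trend test on genotype counts
#'
#' Standard trend chi-square with dose weights (default 0/1/2 for
#' hom-ref/het/hom-alt), two-sided p from a 1-df chi-square. With
#' weights `(0, 1, 1)` the statistic reduces to the uncorrected Pearson
#' chi-square on the collapsed carrier table.
#'
#' @param counts 2x3 matrix of genotype counts, rows =
#'   affected/unaffected, columns = hom-ref/het/hom-alt.
#' @param weights numeric dose weights, one per genotype column.
#' @return list with `statistic`, `df`, `p.value`, `note`.
#' @export
armitage_trend <- function(counts, weights = c(0, 1, 2)) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 3L)))
    stopf("counts must be a 2x3 matrix (status x genotype)")
  if (length(weights) != 3L) stopf("need one weight per genotype column")
  n_col <- colSums(counts)
  N <- sum(counts)
  if (N < 1L) stopf("need at least one subject")
  R <- sum(counts[1L, ])
  if (sum(n_col > 0) <= 1L)
    return(list(statistic = NA_real_, df = 1L, p.value = NA_real_,
                note = "undefined: all subjects in one genotype column"))
  p_bar <- R / N
  num <- sum(weights * (counts[1L, ] - n_col * p_bar))
  v <- p_bar * (1 - p_bar) *
    (sum(weights^2 * n_col) - sum(weights * n_col)^2 / N)
  if (v <= 0)
    return(list(statistic = NA_real_, df = 1L, p.value = NA_real_,
                note = "undefined: zero trend variance"))
  stat <- num^2 / v
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       note = "")
}

# exact two-sided rank-sum p by enumeration of all group-A rank subsets
rank_sum_exact_p <- function(ranks, n_a) {
  n <- length(ranks)
  w <- sum(ranks[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  combos <- utils::combn(n, n_a)
  sums <- colSums(matrix(ranks[combos], nrow = n_a))
  eps <- sqrt(.Machine$double.eps)
  mean(abs(sums - mu) >= abs(w - mu) - eps)
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Ranks the pooled values with mid-ranks for ties. For small samples
#' (total n <= 20 under `mode = "auto"`) the two-sided p is computed by
#' full enumeration of all group assignments of the observed ranks
#' (p = proportion of assignments whose rank sum deviates from its mean
#' at least as much as observed). Larger samples use the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param values_a,values_b numeric vectors (non-empty), e.g. PAP values
#'   of carriers and non-carriers.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param exact_max_n total-size cutoff for the exact path under
#'   `"auto"`.
#' @return list with `statistic` (rank sum of group A), `p.value`,
#'   `mode` used.
#' @export
rank_sum <- function(values_a, values_b,
                     mode = c("auto", "exact", "normal_approx"),
                     exact_max_n = 20L) {
  mode <- match.arg(mode)
  if (length(values_a) == 0L || length(values_b) == 0L)
    stopf("both groups must be non-empty")
  n_a <- length(values_a)
  n_b <- length(values_b)
  n <- n_a + n_b
  ranks <- rank(c(values_a, values_b))  # mid-ranks for ties
  w <- sum(ranks[seq_len(n_a)])
  use_exact <- mode == "exact" || (mode == "auto" && n <= exact_max_n)
  if (use_exact) {
    p <- rank_sum_exact_p(ranks, n_a)
    used <- "exact"
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    used <- "normal_approx"
  }
  list(statistic = w, p.value = p, mode = used)
}

screening_estimate <- function(estimate, lower, upper, scale, note = "") {
  structure(list(estimate = estimate, conf_low = lower, conf_high = upper,
                 scale = scale, note = note),
            class = "screening_estimate")
}

#' @export
print.screening_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CI %.3f-%.3f)%s\n", x$scale, x$estimate,
              x$conf_low, x$conf_high,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Relative risk of disease for carriers vs non-carriers
#'
#' RR = (a/(a+c)) / (b/(b+d)) with a log-scale Wald 95% interval
#' `exp(log RR +/- 1.96 sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d)))`.
#'
#' @param t a [contingency_2x2()] or length-4 numeric.
#' @param correct add 0.5 to every cell (continuity correction for zero
#'   cells) before estimating.
#' @return a `screening_estimate` (scale `"relative risk"`); with a
#'   zero cell and `correct = FALSE` the point estimate is returned with
#'   an undefined CI.
#' @export
relative_risk <- function(t, correct = FALSE) {
  t <- as_ctab(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (correct) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (a + c == 0 || b + d == 0)
    stopf("carrier and non-carrier groups must both be non-empty")
  rr <- (a / (a + c)) / (b / (b + d))
  if (a == 0 || b == 0)
    return(screening_estimate(rr, NA_real_, NA_real_, "relative risk",
                              "CI undefined: zero cell"))
  se <- sqrt(1 / a - 1 / (a + c) + 1 / b - 1 / (b + d))
  screening_estimate(rr, rr * exp(-1.96 * se), rr * exp(1.96 * se),
                     "relative risk")
}

#' Odds ratio of carrier status between affected and unaffected
#'
#' OR = ad/(bc) with the Woolf/Wald log-scale 95% interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t a [contingency_2x2()] or length-4 numeric.
#' @param correct apply the Haldane-Anscombe 0.5 correction to every
#'   cell (needed for a finite estimate with a zero cell).
#' @return a `screening_estimate` (scale `"odds ratio"`).
#' @export
odds_ratio <- function(t, correct = FALSE) {
  t <- as_ctab(t)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (correct) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  if (any(c(a, b, c, d) == 0))
    return(screening_estimate(or, NA_real_, NA_real_, "odds ratio",
                              "CI undefined: zero cell"))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  screening_estimate(or, or * exp(-1.96 * se), or * exp(1.96 * se),
                     "odds ratio")
}

#' Positive and negative predictive values under assumed prevalence
#'
#' Bayes-rule post-test probabilities:
#' PPV = sens * prev / (sens * prev + (1 - spec)(1 - prev)),
#' NPV = spec (1 - prev) / (spec (1 - prev) + (1 - sens) prev).
#'
#' @param sensitivity,specificity,prevalence proportions in `[0, 1]`.
#' @return list with `ppv` and `npv` (proportions; `NA` with a note if
#'   a denominator vanishes).
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  if (!is_prob(sensitivity) || !is_prob(specificity) || !is_prob(prevalence))
    stopf("sensitivity, specificity and prevalence must lie in [0, 1]")
  den_p <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  den_n <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  list(ppv = if (den_p > 0) sensitivity * prevalence / den_p else NA_real_,
       npv = if (den_n > 0) specificity * (1 - prevalence) / den_n
             else NA_real_,
       note = if (den_p == 0 || den_n == 0) "undefined: zero denominator"
              else "")
}

#' Pool contingency tables across herds
#'
#' Cell-wise sums, the simple pooling used for a joint multi-herd
#' analysis.
#'
#' @param tables list of [contingency_2x2()] tables (>= 1).
#' @return a pooled `ctab2x2`.
#' @export
pool_tables <- function(tables) {
  if (length(tables) < 1L) stopf("need at least one table")
  tables <- lapply(tables, as_ctab)
  contingency_2x2(sum(vapply(tables, `[[`, numeric(1), "a")),
                  sum(vapply(tables, `[[`, numeric(1), "b")),
                  sum(vapply(tables, `[[`, numeric(1), "c")),
                  sum(vapply(tables, `[[`, numeric(1), "d")))
}
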