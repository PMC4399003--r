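# multiset intersection size of two unordered allele pairs
allele_pair_shared <- function(x, y) {
  shared <- 0L
  for (a in x) {
    m <- match(a, y)
    if (!is.na(m)) {
      shared <- shared + 1L
      y <- y[-m]
    }
  }
  shared
}

#' Pairwise microsatellite allele-difference distance matrix
#'
#' For each pair of samples and each marker the contribution is
#' `2 - |multiset intersection|` of the two unordered allele pairs
#' (0 if both alleles are shared, 1 if one is, 2 if none); the total
#' distance is the sum over markers. Markers with a missing allele in
#' either sample contribute 0 and the number of such skipped
#' marker-pairs is recorded in `attr(, "n_missing_pairs")`.
#'
#' @param profiles microsatellite profile data.frame as returned by
#'   [read_microsatellites()] (all samples on the same marker panel).
#' @return symmetric integer matrix of allele-difference counts with
#'   zero diagonal, sample ids as dimnames.
#' @export
pairwise_distance <- function(profiles) {
  markers <- attr(profiles, "markers")
  if (is.null(markers)) {
    acols <- grep("_a$", names(profiles), value = TRUE)
    markers <- sub("_a$", "", acols)
  }
  need <- as.vector(rbind(paste0(markers, "_a"), paste0(markers, "_b")))
  miss <- setdiff(need, names(profiles))
  if (length(markers) == 0L || length(miss) > 0L)
    stopf("profiles lack allele columns for the marker panel: %s",
          paste(miss, collapse = ", "))
  ids <- profiles$sample_id
  n <- length(ids)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  n_missing <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      tot <- 0L
      for (mk in markers) {
        x <- c(profiles[[paste0(mk, "_a")]][i], profiles[[paste0(mk, "_b")]][i])
        y <- c(profiles[[paste0(mk, "_a")]][j], profiles[[paste0(mk, "_b")]][j])
        if (anyNA(x) || anyNA(y)) {
          n_missing <- n_missing + 1L
          next
        }
        tot <- tot + 2L - allele_pair_shared(x, y)
      }
      d[i, j] <- d[j, i] <- tot
    }
  }
  attr(d, "n_missing_pairs") <- n_missing
  if (n_missing > 0L)
    message(sprintf("pairwise_distance: %d marker-pair(s) skipped %s",
                    n_missing, "due to missing alleles (contributed 0)"))
  d
}

subset_total_distance <- function(dist, ids) {
  sum(dist[ids, ids]) / 2
}

#' Select a maximally diverse subset within a phenotype group
#'
#' Returns the `k` samples of the requested status group maximising the
#' total within-subset pairwise distance. All subsets are enumerated
#' when their count is within `budget`; beyond that a greedy max-min
#' heuristic is used (seeded with the farthest pair, then repeatedly
#' adding the sample with the largest minimum distance to the current
#' selection) and flagged via `attr(, "method")`. Ties are broken by
#' lexicographic sample-id order.
#'
#' @param dist distance matrix from [pairwise_distance()].
#' @param phenotypes phenotype data.frame with `sample_id` and `status`.
#' @param k subset size.
#' @param group status label to select within (default `"affected"`).
#' @param budget maximum number of subsets for exhaustive search.
#' @return character vector of `k` sample ids (sorted), with attributes
#'   `method` (`"exhaustive"` or `"greedy"`) and `total_distance`.
#' @export
select_diverse_subset <- function(dist, phenotypes, k,
                                  group = "affected", budget = 1e6) {
  ids <- sort(phenotypes$sample_id[!is.na(phenotypes$status) &
                                     phenotypes$status == group])
  ids <- intersect(ids, rownames(dist))
  if (k > length(ids))
    stopf("k = %d exceeds the %d samples with status '%s'",
          k, length(ids), group)
  if (k == length(ids)) {
    out <- ids
    method <- "exhaustive"
  } else if (choose(length(ids), k) <= budget) {
    combos <- utils::combn(ids, k)
    totals <- apply(combos, 2L, function(s) subset_total_distance(dist, s))
    # first max over lexicographically ordered combinations wins ties
    out <- combos[, which.max(totals)]
    method <- "exhaustive"
  } else {
    # multi-start greedy max-min growth with 1-swap steepest-ascent
    # refinement of the total-distance objective
    refine <- function(sel) {
      repeat {
        best_total <- subset_total_distance(dist, sel)
        swap <- NULL
        for (s in sel) {
          for (r in setdiff(ids, sel)) {
            tot <- subset_total_distance(dist, c(setdiff(sel, s), r))
            if (tot > best_total) {
              best_total <- tot
              swap <- c(s, r)
            }
          }
        }
        if (is.null(swap)) return(sel)
        sel <- c(setdiff(sel, swap[1]), swap[2])
      }
    }
    out <- NULL
    best <- -1
    for (start in ids) {
      sel <- start
      while (length(sel) < k) {
        rest <- setdiff(ids, sel)
        minds <- vapply(rest, function(s) min(dist[s, sel]), numeric(1))
        sel <- c(sel, rest[which.max(minds)])
      }
      sel <- sort(refine(sel))
      tot <- subset_total_distance(dist, sel)
      if (tot > best || (tot == best && paste(sel, collapse = ",") <
                           paste(out, collapse = ","))) {
        best <- tot
        out <- sel
      }
    }
    method <- "greedy"
  }
  out <- sort(out)
  attr(out, "method") <- method
  attr(out, "total_distance") <- subset_total_distance(dist, out)
  out
}
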