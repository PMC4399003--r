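#' Configuration of one dominant co-segregation filter stage
#'
#' A variant passes a stage iff at least `min_affected_carriers` of the
#' affected samples carry it and at most `max_unaffected_carriers` of
#' the unaffected samples do (dominant model: het or hom-alt counts as
#' carrier).
#'
#' @param min_affected_carriers minimum carrier count among affected.
#' @param max_unaffected_carriers maximum carrier count among unaffected.
#' @param n_affected,n_unaffected design group sizes (for validation;
#'   `NULL` skips the bound checks).
#' @param variant_classes consequence classes admitted by
#'   [class_filter()]; defaults to non-synonymous substitutions and
#'   short coding insertions/deletions.
#' @param missing_policy how a missing genotype is treated:
#'   `"as_noncarrier"` (default), `"as_fail"` (a variant with any
#'   missing call among status-assigned samples fails), or
#'   `"exclude_sample"` (the sample is dropped from that variant's
#'   carrier counts).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_affected_carriers, max_unaffected_carriers,
                          n_affected = NULL, n_unaffected = NULL,
                          variant_classes = c("nonsynonymous", "stopgain",
                                              "stoploss",
                                              "frameshift_insertion",
                                              "frameshift_deletion",
                                              "nonframeshift_insertion",
                                              "nonframeshift_deletion"),
                          missing_policy = c("as_noncarrier", "as_fail",
                                             "exclude_sample")) {
  missing_policy <- match.arg(missing_policy)
  if (!is_count(min_affected_carriers) || !is_count(max_unaffected_carriers))
    stopf("carrier thresholds must be non-negative integers")
  if (!is.null(n_affected) && min_affected_carriers > n_affected)
    stopf("min_affected_carriers exceeds n_affected")
  if (!is.null(n_unaffected) && max_unaffected_carriers > n_unaffected)
    stopf("max_unaffected_carriers exceeds n_unaffected")
  structure(list(min_affected_carriers = as.integer(min_affected_carriers),
                 max_unaffected_carriers = as.integer(max_unaffected_carriers),
                 n_affected = n_affected, n_unaffected = n_unaffected,
                 variant_classes = variant_classes,
                 missing_policy = missing_policy),
            class = "filter_config")
}

#' Per-sample dominant carrier flags for one variant
#'
#' Maps copy counts to carrier status under the dominant model: het and
#' hom-alt are carriers, hom-ref is not. Missing calls follow
#' `missing_policy`: `as_noncarrier` maps them to `FALSE`; the other
#' policies keep `NA` so counting code can fail the variant or exclude
#' the sample.
#'
#' @param genotypes integer vector of alt-allele copy counts (0/1/2/NA).
#' @param missing_policy see [filter_config()].
#' @return logical vector (`NA` possible unless `as_noncarrier`).
#' @export
carrier_vector <- function(genotypes,
                           missing_policy = c("as_noncarrier", "as_fail",
                                              "exclude_sample")) {
  missing_policy <- match.arg(missing_policy)
  carr <- genotypes >= 1L
  if (missing_policy == "as_noncarrier") carr[is.na(carr)] <- FALSE
  carr
}

#' Filter variant records by consequence class
#'
#' @param gm a [genotype_matrix()].
#' @param classes allowed consequence classes.
#' @param unannotated `"drop"` (default) or `"keep"` for records with
#'   an empty/missing class; either way a warning is raised.
#' @return the `genotype_matrix` restricted to admitted records.
#' @export
class_filter <- function(gm, classes, unannotated = c("drop", "keep")) {
  unannotated <- match.arg(unannotated)
  cls <- gm$variants$class
  blank <- is.na(cls) | !nzchar(cls)
  if (any(blank))
    warnf("%d record(s) lack a consequence class (%s)",
          sum(blank), if (unannotated == "drop") "dropped" else "kept")
  keep <- (!blank & cls %in% classes) | (blank & unannotated == "keep")
  subset_variants(gm, which(keep))
}

# per-variant carrier counts among a sample subset, honouring the
# missing policy; returns matrix with columns carriers / n_missing
count_carriers <- function(gm, sample_ids, missing_policy) {
  g <- gm$geno[, sample_ids, drop = FALSE]
  carr <- g >= 1L
  n_missing <- rowSums(is.na(carr))
  if (missing_policy == "as_noncarrier") carr[is.na(carr)] <- FALSE
  cbind(carriers = rowSums(carr, na.rm = TRUE), n_missing = n_missing)
}

check_status <- function(gm, status) {
  status <- status[gm$samples]
  if (anyNA(status) || !all(status %in% c("affected", "unaffected")))
    stopf("every genotyped sample needs status affected/unaffected; %s",
          "exclude indeterminate samples upstream")
  status
}

#' Dominant-model co-segregation filter
#'
#' Keeps variants whose carrier counts satisfy the stage thresholds:
#' carriers among affected >= `min_affected_carriers` and carriers
#' among unaffected <= `max_unaffected_carriers`.
#'
#' @param gm a [genotype_matrix()].
#' @param status named character vector (`affected`/`unaffected`) over
#'   all samples of `gm`; a missing or indeterminate status is an error.
#' @param cfg a [filter_config()].
#' @return the passing `genotype_matrix`; per-variant carrier counts are
#'   attached as `attr(, "counts")` (data.frame with `id`, `gene`,
#'   `affected_carriers`, `unaffected_carriers`, `pass`).
#' @export
dominant_filter <- function(gm, status, cfg) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "filter_config"))
  status <- check_status(gm, status)
  aff_ids <- gm$samples[status == "affected"]
  un_ids <- gm$samples[status == "unaffected"]
  ca <- count_carriers(gm, aff_ids, cfg$missing_policy)
  cu <- count_carriers(gm, un_ids, cfg$missing_policy)
  pass <- ca[, "carriers"] >= cfg$min_affected_carriers &
    cu[, "carriers"] <= cfg$max_unaffected_carriers
  if (cfg$missing_policy == "as_fail")
    pass <- pass & ca[, "n_missing"] == 0L & cu[, "n_missing"] == 0L
  counts <- data.frame(id = gm$variants$id, gene = gm$variants$gene,
                       affected_carriers = unname(ca[, "carriers"]),
                       unaffected_carriers = unname(cu[, "carriers"]),
                       pass = unname(pass), stringsAsFactors = FALSE)
  out <- subset_variants(gm, which(pass))
  attr(out, "counts") <- counts
  out
}

#' Run the co-segregation filter cascade
#'
#' Applies [class_filter()] once, then evaluates each stage
#' independently on the class-filtered variants (stages are not chained:
#' the looser stages are reported alongside the strict one, as in an
#' exome screen narrative). A gene passes a stage iff at least one of
#' its variants passes. Passing variants of each stage are additionally
#' collapsed into cis-haplotype units.
#'
#' @param gm a [genotype_matrix()].
#' @param status named status vector, see [dominant_filter()].
#' @param stages list of `c(min_affected, max_unaffected)` pairs or
#'   [filter_config()] objects; default `list(c(5,0), c(4,1), c(4,0))`
#'   for a 5 vs 5 extreme design.
#' @param variant_classes,missing_policy,unannotated passed to
#'   [filter_config()] / [class_filter()] when `stages` are given as
#'   threshold pairs.
#' @return An object of class `filter_report`: list with `summary`
#'   (data.frame: stage, min_affected, max_unaffected, n_variants,
#'   n_genes, n_haplotype_units), `details` (per-stage passing-variant
#'   data.frame), `units` (per-stage [collapse_cis()] results) and
#'   `genes` (per-stage character vectors).
#' @export
run_cascade <- function(gm, status,
                        stages = list(c(5, 0), c(4, 1), c(4, 0)),
                        variant_classes = NULL,
                        missing_policy = "as_noncarrier",
                        unannotated = "drop") {
  if (length(stages) < 1L) stopf("need at least one filter stage")
  stages <- lapply(stages, function(s) {
    if (inherits(s, "filter_config")) return(s)
    if (is.null(variant_classes))
      filter_config(s[1], s[2], missing_policy = missing_policy)
    else
      filter_config(s[1], s[2], variant_classes = variant_classes,
                    missing_policy = missing_policy)
  })
  classes <- stages[[1]]$variant_classes
  filtered <- class_filter(gm, classes, unannotated = unannotated)
  details <- list()
  units <- list()
  genes <- list()
  summ <- data.frame()
  for (s in seq_along(stages)) {
    cfg <- stages[[s]]
    passing <- dominant_filter(filtered, status, cfg)
    counts <- attr(passing, "counts")
    det <- counts[counts$pass, c("id", "gene", "affected_carriers",
                                 "unaffected_carriers")]
    det <- cbind(stage = rep(s, nrow(det)), det)
    rownames(det) <- NULL
    u <- collapse_cis(passing)
    stage_genes <- sort(unique(det$gene[nzchar(det$gene)]))
    details[[s]] <- det
    units[[s]] <- u
    genes[[s]] <- stage_genes
    summ <- rbind(summ, data.frame(
      stage = s, min_affected = cfg$min_affected_carriers,
      max_unaffected = cfg$max_unaffected_carriers,
      n_variants = nrow(det), n_genes = length(stage_genes),
      n_haplotype_units = nrow(u$units)))
  }
  structure(list(summary = summ, details = do.call(rbind, details),
                 units = units, genes = genes,
                 n_input_variants = nrow(gm$geno),
                 n_class_filtered = nrow(filtered$geno)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d variant(s) in, %d after class filter\n",
              x$n_input_variants, x$n_class_filtered))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Collapse cis haplotypes: merge same-gene variants with identical
#' carrier sets
#'
#' Variants in one gene whose carrier vectors are bit-identical are
#' merged into a single haplotype unit (the signature of variants
#' travelling together on one chromosome copy); all other variants
#' become single-member units. Idempotent: collapsing a collapsed
#' result returns it unchanged.
#'
#' @param x a [genotype_matrix()] (typically the passing set of a
#'   filter stage) or a previous `haplotype_units` result.
#' @param missing_policy policy used to form carrier vectors.
#' @return An object of class `haplotype_units`: list with `units`
#'   (data.frame: unit_id, gene, n_members, member_ids, n_carriers),
#'   `carriers` (logical matrix units x samples) and `samples`.
#' @export
collapse_cis <- function(x, missing_policy = "as_noncarrier") {
  UseMethod("collapse_cis")
}

build_units <- function(gene, member_ids, carriers, samples) {
  if (length(gene) == 0L) {
    units <- data.frame(unit_id = character(), gene = character(),
                        n_members = integer(), member_ids = character(),
                        n_carriers = integer(), stringsAsFactors = FALSE)
    carr <- matrix(FALSE, 0L, length(samples),
                   dimnames = list(NULL, samples))
    return(structure(list(units = units, carriers = carr, samples = samples),
                     class = "haplotype_units"))
  }
  key <- paste(gene, apply(carriers, 1L, paste, collapse = ""), sep = "|")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  units <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(gene = gene[ix[1L]], n_members = length(ix),
               member_ids = paste(member_ids[ix], collapse = ","),
               n_carriers = sum(carriers[ix[1L], ]),
               stringsAsFactors = FALSE)
  }))
  carr <- do.call(rbind, lapply(groups,
                                function(ix) carriers[ix[1L], , drop = FALSE]))
  units <- cbind(unit_id = sprintf("hu_%03d", seq_len(nrow(units))), units)
  rownames(units) <- NULL
  rownames(carr) <- units$unit_id
  colnames(carr) <- samples
  structure(list(units = units, carriers = carr, samples = samples),
            class = "haplotype_units")
}

#' @export
collapse_cis.genotype_matrix <- function(x, missing_policy = "as_noncarrier") {
  carr <- x$geno >= 1L
  if (missing_policy == "as_noncarrier") carr[is.na(carr)] <- FALSE
  if (nrow(carr) == 0L)
    return(build_units(character(0), character(0),
                       matrix(FALSE, 0, ncol(x$geno)), x$samples))
  build_units(x$variants$gene, x$variants$id, carr, x$samples)
}

#' @export
collapse_cis.haplotype_units <- function(x, missing_policy = "as_noncarrier") {
  if (nrow(x$units) == 0L) return(x)
  out <- build_units(x$units$gene, x$units$member_ids, x$carriers, x$samples)
  # preserve member counts through re-collapse
  out$units$n_members <- vapply(strsplit(out$units$member_ids, ","),
                                length, integer(1))
  out
}

#' @export
print.haplotype_units <- function(x, ...) {
  cat(sprintf("haplotype_units: %d unit(s) over %d sample(s)\n",
              nrow(x$units), length(x$samples)))
  if (nrow(x$units) > 0L) print(x$units, row.names = FALSE)
  invisible(x)
}
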