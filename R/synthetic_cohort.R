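#' Configuration for the synthetic HAPH cohort generator
#'
#' Defaults emulate the study conditions of the original high-altitude
#' herd: 20 affected and 21 unaffected animals; mean PAP 94.2 +/- 5.3
#' mm Hg among affected extremes and 30.8 +/- 0.8 among unaffected;
#' a causal cis-haplotype (two variants in one gene with identical
#' carrier sets) carried dominantly with incomplete penetrance; carrier
#' frequency 0.41 as observed in lowland cattle; ten microsatellite
#' markers. Penetrance defaults to 0.75 and the phenocopy rate (an
#' affected non-carrier) to 0.05, reflecting the incomplete
#' genotype-phenotype concordance seen in the herd data.
#'
#' @param n_affected,n_unaffected group sizes to fill (case-control).
#' @param penetrance probability that an at-altitude carrier is affected.
#' @param phenocopy probability that a non-carrier is affected.
#' @param carrier_freq population frequency of the carrier state for the
#'   causal haplotype.
#' @param background_variants number of non-causal variants, each with a
#'   carrier frequency drawn uniformly from `background_alt_freq_range`
#'   and carrier status independent of phenotype.
#' @param background_alt_freq_range length-2 numeric interval in (0,1).
#' @param pap_affected_mean,pap_affected_sd,pap_unaffected_mean,pap_unaffected_sd
#'   parameters (mm Hg) of the status-specific PAP normals, truncated
#'   below at 15 mm Hg.
#' @param n_microsat_markers,n_alleles_per_marker microsatellite panel
#'   shape; alleles are drawn uniformly per marker.
#' @param hardy_weinberg if `TRUE`, carriers are split het/hom-alt by
#'   Hardy-Weinberg conditional proportions; by default all carriers are
#'   emitted heterozygous.
#' @param seed integer seed; all generation is a pure function of
#'   (config, seed).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_affected = 20L, n_unaffected = 21L,
                          penetrance = 0.75, phenocopy = 0.05,
                          carrier_freq = 0.41,
                          background_variants = 200L,
                          background_alt_freq_range = c(0.05, 0.5),
                          pap_affected_mean = 94.2, pap_affected_sd = 5.3,
                          pap_unaffected_mean = 30.8, pap_unaffected_sd = 0.8,
                          n_microsat_markers = 10L, n_alleles_per_marker = 8L,
                          hardy_weinberg = FALSE, seed = 1L) {
  cfg <- list(n_affected = as.integer(n_affected),
              n_unaffected = as.integer(n_unaffected),
              penetrance = penetrance, phenocopy = phenocopy,
              carrier_freq = carrier_freq,
              background_variants = as.integer(background_variants),
              background_alt_freq_range = as.numeric(background_alt_freq_range),
              pap_affected_mean = pap_affected_mean,
              pap_affected_sd = pap_affected_sd,
              pap_unaffected_mean = pap_unaffected_mean,
              pap_unaffected_sd = pap_unaffected_sd,
              n_microsat_markers = as.integer(n_microsat_markers),
              n_alleles_per_marker = as.integer(n_alleles_per_marker),
              hardy_weinberg = isTRUE(hardy_weinberg),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!is_prob(cfg$penetrance) || !is_prob(cfg$phenocopy))
    stopf("penetrance and phenocopy must lie in [0, 1]")
  if (!is_prob(cfg$carrier_freq) || cfg$carrier_freq <= 0 ||
      cfg$carrier_freq >= 1)
    stopf("carrier_freq must lie strictly in (0, 1)")
  if (cfg$pap_affected_sd <= 0 || cfg$pap_unaffected_sd <= 0)
    stopf("PAP standard deviations must be positive")
  if (cfg$n_affected < 1L || cfg$n_unaffected < 1L)
    stopf("group sizes must be >= 1")
  r <- cfg$background_alt_freq_range
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stopf("background_alt_freq_range must be an interval within (0, 1)")
  p_aff <- cfg$carrier_freq * cfg$penetrance +
    (1 - cfg$carrier_freq) * cfg$phenocopy
  if (p_aff == 0 && cfg$n_affected > 0L)
    stopf("impossible fill: penetrance and phenocopy both 0 %s",
          "with n_affected > 0")
  if (p_aff == 1 && cfg$n_unaffected > 0L)
    stopf("impossible fill: every animal would be affected %s",
          "with n_unaffected > 0")
  invisible(cfg)
}

# genotype copy count for a carrier under the chosen zygosity model
carrier_copies <- function(n, carrier_freq, hardy_weinberg) {
  if (!hardy_weinberg) return(rep(1L, n))
  q <- 1 - sqrt(1 - carrier_freq)        # allele freq with 1-(1-q)^2 = cf
  p_hom_given_carrier <- q^2 / carrier_freq
  ifelse(stats::runif(n) < p_hom_given_carrier, 2L, 1L)
}

#' Simulate a case-control HAPH cohort
#'
#' Draws animals from a population in which the causal cis-haplotype
#' carrier state has frequency `carrier_freq`; carriers become affected
#' with probability `penetrance` and non-carriers with probability
#' `phenocopy`; animals are accepted until the requested
#' affected/unaffected group sizes are filled (rejection sampling
#' conditioned on status). PAP is drawn from the status-specific normal
#' truncated below at 15 mm Hg. The causal haplotype is emitted as two
#' heterozygous variant records in one gene with identical carrier sets;
#' background variants are independent of status.
#'
#' @param config a [cohort_config()].
#' @return A list of class `simulated_cohort` with elements `genotypes`
#'   (a [genotype_matrix()]), `phenotypes` (phenotype data.frame),
#'   `microsatellites` (profile data.frame), `truth` (carrier sample
#'   ids, causal variant ids and causal gene) and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_aff <- config$n_affected
  n_un <- config$n_unaffected

  aff_carrier <- logical(0)
  un_carrier <- logical(0)
  max_iter <- 1e6L
  drawn <- 0L
  while ((length(aff_carrier) < n_aff || length(un_carrier) < n_un) &&
         drawn < max_iter) {
    drawn <- drawn + 1L
    carrier <- stats::runif(1) < config$carrier_freq
    p_aff <- if (carrier) config$penetrance else config$phenocopy
    affected <- stats::runif(1) < p_aff
    if (affected && length(aff_carrier) < n_aff)
      aff_carrier <- c(aff_carrier, carrier)
    else if (!affected && length(un_carrier) < n_un)
      un_carrier <- c(un_carrier, carrier)
  }
  if (length(aff_carrier) < n_aff || length(un_carrier) < n_un)
    stopf("could not fill case-control groups in %d draws; %s",
          max_iter, "check penetrance/phenocopy/carrier_freq")

  n <- n_aff + n_un
  ids <- c(sprintf("A%03d", seq_len(n_aff)), sprintf("U%03d", seq_len(n_un)))
  status <- rep(c("affected", "unaffected"), c(n_aff, n_un))
  carrier <- c(aff_carrier, un_carrier)

  pap <- numeric(n)
  pap[status == "affected"] <-
    rnorm_trunc(n_aff, config$pap_affected_mean, config$pap_affected_sd, 15)
  pap[status == "unaffected"] <-
    rnorm_trunc(n_un, config$pap_unaffected_mean, config$pap_unaffected_sd, 15)
  phenotypes <- data.frame(
    sample_id = ids,
    herd = "herd1",
    altitude_ft = sample(c(4850, 7200, 8590), n, replace = TRUE),
    mean_pap = round(pap, 1),
    status = status,
    stringsAsFactors = FALSE)

  # causal pair: two non-synonymous variants in cis in one gene,
  # identical carrier sets by construction
  causal_gene <- "EPAS1"
  causal_ids <- c("causal_1", "causal_2")
  copies <- integer(n)
  copies[carrier] <- carrier_copies(sum(carrier), config$carrier_freq,
                                    config$hardy_weinberg)
  causal_geno <- rbind(copies, copies)
  causal_variants <- data.frame(
    chrom = "11", pos = c(28662654L, 28662666L), id = causal_ids,
    ref = "G", alt = "A", gene = causal_gene, class = "nonsynonymous",
    annotation = c("c.G1816A:p.A606T", "c.G1828A:p.G610S"),
    stringsAsFactors = FALSE)

  nb <- config$background_variants
  if (nb > 0L) {
    r <- config$background_alt_freq_range
    freqs <- stats::runif(nb, r[1], r[2])
    bg_geno <- matrix(0L, nrow = nb, ncol = n)
    for (j in seq_len(nb)) {
      carr_j <- stats::runif(n) < freqs[j]
      bg_geno[j, carr_j] <- carrier_copies(sum(carr_j), freqs[j],
                                           config$hardy_weinberg)
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nb, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    bg_variants <- data.frame(
      chrom = as.character(sample(1:29, nb, replace = TRUE)),
      pos = sample.int(1e8L, nb), id = sprintf("bg_%04d", seq_len(nb)),
      ref = ref, alt = alt, gene = sprintf("GENE%04d", seq_len(nb)),
      class = "nonsynonymous", annotation = "",
      stringsAsFactors = FALSE)
    variants <- rbind(causal_variants, bg_variants)
    geno <- rbind(causal_geno, bg_geno)
  } else {
    variants <- causal_variants
    geno <- causal_geno
  }
  rownames(variants) <- NULL
  genotypes <- genotype_matrix(variants, geno, ids)

  nm <- config$n_microsat_markers
  labels <- 100L + 2L * seq_len(config$n_alleles_per_marker)
  ms <- matrix(sample(labels, 2L * nm * n, replace = TRUE), nrow = n)
  microsat <- data.frame(sample_id = ids, ms, stringsAsFactors = FALSE)
  names(microsat) <- c("sample_id",
                       as.vector(rbind(sprintf("marker%d_a", seq_len(nm)),
                                       sprintf("marker%d_b", seq_len(nm)))))
  attr(microsat, "markers") <- sprintf("marker%d", seq_len(nm))

  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 microsatellites = microsat,
                 truth = list(carriers = ids[carrier],
                              causal_variant_ids = causal_ids,
                              causal_gene = causal_gene),
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: %d affected / %d unaffected, %s\n",
              sum(x$phenotypes$status == "affected"),
              sum(x$phenotypes$status == "unaffected"),
              sprintf("%d carrier(s) of the causal haplotype",
                      length(x$truth$carriers))))
  print(x$genotypes)
  invisible(x)
}

#' Simulate a log2 expression matrix over a cohort
#'
#' Background genes are drawn from Normal(baseline, `noise_sd`) in every
#' sample; genes in `gene_set` receive an additive `upshift` (log2
#' units) in affected carrier samples only, emulating target-gene
#' upregulation downstream of a stabilised transcription factor. A
#' fraction `floor_fraction` of all genes is assigned a low baseline
#' (`low_baseline`) so the expression-floor filter is exercised.
#'
#' @param cohort a `simulated_cohort`.
#' @param gene_set character vector of gene symbols to shift (must be
#'   non-empty).
#' @param upshift log2 shift (>= 0) applied in affected carriers.
#' @param n_background_genes number of unshifted background genes added.
#' @param noise_sd log2 residual standard deviation (> 0).
#' @param seed integer seed.
#' @param baseline baseline log2 expression of well-measured genes.
#' @param floor_fraction fraction of all genes placed below the
#'   expression floor.
#' @param low_baseline baseline assigned to below-floor genes.
#' @return numeric matrix, genes x samples, log2 units.
#' @export
simulate_expression <- function(cohort, gene_set, upshift = 2,
                                n_background_genes = 1000L, noise_sd = 0.5,
                                seed = 1L, baseline = 10,
                                floor_fraction = 0.1, low_baseline = 5) {
  if (length(gene_set) == 0L) stopf("gene_set must be non-empty")
  if (upshift < 0) stopf("upshift must be >= 0")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  set.seed(as.integer(seed))
  ids <- cohort$phenotypes$sample_id
  affected_carriers <- intersect(
    cohort$phenotypes$sample_id[cohort$phenotypes$status == "affected"],
    cohort$truth$carriers)
  genes <- c(gene_set, sprintf("BG%05d", seq_len(n_background_genes)))
  base <- rep(baseline, length(genes))
  n_low <- floor(floor_fraction * length(genes))
  if (n_low > 0L) base[sample.int(length(genes), n_low)] <- low_baseline
  m <- matrix(stats::rnorm(length(genes) * length(ids), mean = base,
                           sd = noise_sd),
              nrow = length(genes), ncol = length(ids))
  shift_rows <- which(genes %in% gene_set)
  shift_cols <- which(ids %in% affected_carriers)
  if (length(shift_rows) && length(shift_cols))
    m[shift_rows, shift_cols] <- m[shift_rows, shift_cols] + upshift
  dimnames(m) <- list(genes, ids)
  m
}

#' Estimate filter power and false-pass burden of a study design
#'
#' Repeatedly simulates a cohort under `config`, applies
#' [dominant_filter()] with `filter_cfg`, and reports the fraction of
#' replicates in which the planted causal haplotype survives the filter
#' together with the mean number of passing non-causal genes.
#'
#' @param config a [cohort_config()] (its seed field is ignored; seeds
#'   are derived per replicate from `seed`).
#' @param filter_cfg a [filter_config()].
#' @param reps number of replicates (>= 1).
#' @param seed integer seed.
#' @return list with `survival_prob`, `mean_false_genes`,
#'   `false_pass_rate` (per background variant) and `reps`.
#' @export
power_of_design <- function(config, filter_cfg, reps = 100L, seed = 1L) {
  if (!is_count(reps) || reps < 1L) stopf("reps must be >= 1")
  survived <- logical(reps)
  false_genes <- integer(reps)
  false_variants <- integer(reps)
  for (r in seq_len(reps)) {
    cfg_r <- config
    cfg_r$seed <- as.integer(seed) + r
    cohort <- simulate_cohort(cfg_r)
    status <- stats::setNames(cohort$phenotypes$status,
                              cohort$phenotypes$sample_id)
    passing <- dominant_filter(cohort$genotypes, status, filter_cfg)
    ids <- passing$variants$id
    survived[r] <- all(cohort$truth$causal_variant_ids %in% ids)
    other <- setdiff(unique(passing$variants$gene), cohort$truth$causal_gene)
    false_genes[r] <- length(other)
    false_variants[r] <-
      sum(!ids %in% cohort$truth$causal_variant_ids)
  }
  list(survival_prob = mean(survived),
       mean_false_genes = mean(false_genes),
       false_pass_rate = mean(false_variants) /
         max(1L, config$background_variants),
       reps = as.integer(reps))
}
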