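status_5v5 <- function(gm) {
  setNames(rep(c("affected", "unaffected"), each = 5), gm$samples)
}

test_that("carrier flags follow the dominant model and missing policy", {
  g <- c(0L, 1L, 2L, NA)
  expect_equal(carrier_vector(g, "as_noncarrier"),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(carrier_vector(g, "as_fail"), c(FALSE, TRUE, TRUE, NA))
  expect_equal(carrier_vector(g, "exclude_sample"), c(FALSE, TRUE, TRUE, NA))
})

test_that("class filter admits non-synonymous and short coding indels", {
  v <- data.frame(chrom = "1", pos = 1:4, id = paste0("v", 1:4),
                  ref = "A", alt = "T", gene = paste0("G", 1:4),
                  class = c("synonymous", "nonsynonymous",
                            "frameshift_insertion", ""),
                  annotation = "", stringsAsFactors = FALSE)
  gm <- genotype_matrix(v, matrix(0L, 4, 2), c("S1", "S2"))
  default_classes <- filter_config(4, 0)$variant_classes
  expect_warning(kept <- class_filter(gm, default_classes), "class")
  expect_equal(kept$variants$id, c("v2", "v3"))
  expect_warning(kept2 <- class_filter(gm, default_classes,
                                       unannotated = "keep"))
  expect_equal(kept2$variants$id, c("v2", "v3", "v4"))
  expect_warning(none <- class_filter(gm, character(0)))
  expect_equal(nrow(none$geno), 0L)
})

test_that("dominant filter applies the stage thresholds", {
  samples <- sprintf("S%02d", 1:10)
  gm <- random_gm(3, samples, p_carrier = 0)
  gm$geno[1, 1:5] <- 1L            # all affected, no unaffected
  gm$geno[2, ] <- 1L               # everyone carries
  gm$geno[3, c(1:4, 6)] <- c(1L, 1L, 2L, 1L, 1L)  # 4/5 affected, 1 unaffected
  st <- status_5v5(gm)
  pass50 <- dominant_filter(gm, st, filter_config(5, 0))
  expect_equal(pass50$variants$id, "v001")
  pass41 <- dominant_filter(gm, st, filter_config(4, 1))
  expect_setequal(pass41$variants$id, c("v001", "v003"))
  # a universal carrier fails any stage bounding unaffected carriers
  expect_false("v002" %in% dominant_filter(gm, st,
                                           filter_config(4, 4))$variants$id)

  st_bad <- st[-1]
  expect_error(dominant_filter(gm, st_bad, filter_config(4, 0)), "status")
})

test_that("dominant filter equals the brute-force counting oracle", {
  set.seed(31)
  samples <- sprintf("S%02d", 1:10)
  for (i in 1:20) {
    gm <- random_gm(200, samples, p_carrier = runif(1, 0.1, 0.6),
                    p_missing = 0.05)
    st <- status_5v5(gm)
    for (policy in c("as_noncarrier", "as_fail", "exclude_sample")) {
      cfg <- filter_config(sample(3:5, 1), sample(0:2, 1),
                           missing_policy = policy)
      got <- dominant_filter(gm, st, cfg)$variants$id
      want <- gm$variants$id[oracle_dominant_pass(
        gm, st, cfg$min_affected_carriers, cfg$max_unaffected_carriers,
        policy)]
      expect_identical(got, want)
    }
  }
})

test_that("loosening thresholds never drops a passing variant", {
  set.seed(32)
  samples <- sprintf("S%02d", 1:10)
  for (i in 1:10) {
    gm <- random_gm(100, samples, p_carrier = runif(1, 0.2, 0.5),
                    p_missing = 0.03)
    st <- status_5v5(gm)
    strict <- dominant_filter(gm, st, filter_config(5, 0))$variants$id
    looser_aff <- dominant_filter(gm, st, filter_config(4, 0))$variants$id
    looser_un <- dominant_filter(gm, st, filter_config(5, 1))$variants$id
    expect_true(all(strict %in% looser_aff))
    expect_true(all(strict %in% looser_un))
  }
})

test_that("cascade reports nested stage gene sets and a planted haplotype", {
  cfg <- cohort_config(n_affected = 5, n_unaffected = 5, penetrance = 1,
                       phenocopy = 0, background_variants = 120, seed = 33)
  cohort <- simulate_cohort(cfg)
  st <- setNames(cohort$phenotypes$status, cohort$phenotypes$sample_id)
  rep <- run_cascade(cohort$genotypes, st)
  expect_s3_class(rep, "filter_report")
  # full penetrance: the planted haplotype survives the strictest stage
  expect_true(cohort$truth$causal_gene %in% rep$genes[[1]])
  # S(5,0) subset of S(4,0) subset of S(4,1)
  expect_true(all(rep$genes[[1]] %in% rep$genes[[3]]))
  expect_true(all(rep$genes[[3]] %in% rep$genes[[2]]))
  expect_equal(rep$summary$n_genes, unname(lengths(rep$genes)))
  # oracle recount of stage pass totals
  for (s in 1:3) {
    cfg_s <- filter_config(rep$summary$min_affected[s],
                           rep$summary$max_unaffected[s])
    oracle <- sum(oracle_dominant_pass(cohort$genotypes, st,
                                       cfg_s$min_affected_carriers,
                                       cfg_s$max_unaffected_carriers))
    expect_equal(rep$summary$n_variants[s], oracle)
  }
  # gene counts >= unit counts and unit count <= variant count
  expect_true(all(rep$summary$n_genes <= rep$summary$n_haplotype_units))
  expect_true(all(rep$summary$n_haplotype_units <= rep$summary$n_variants))
})

test_that("cis collapsing merges identical carrier sets within a gene", {
  samples <- sprintf("S%02d", 1:10)
  v <- data.frame(chrom = "1", pos = c(100L, 112L, 300L, 400L),
                  id = paste0("v", 1:4), ref = "G", alt = "A",
                  gene = c("EPAS1", "EPAS1", "EPAS1", "PDPR"),
                  class = "nonsynonymous", annotation = "",
                  stringsAsFactors = FALSE)
  g <- matrix(0L, 4, 10)
  g[1, 1:4] <- 1L
  g[2, 1:4] <- 1L   # same carriers as v1: one cis unit
  g[3, 1:5] <- 1L   # same gene, one extra carrier: separate unit
  g[4, 2:3] <- 1L
  gm <- genotype_matrix(v, g, samples)
  units <- collapse_cis(gm)
  expect_equal(nrow(units$units), 3L)
  pair <- units$units[units$units$n_members == 2L, ]
  expect_equal(pair$gene, "EPAS1")
  expect_equal(pair$member_ids, "v1,v2")
  # idempotence
  again <- collapse_cis(units)
  expect_equal(again$units$member_ids, units$units$member_ids)
  expect_equal(again$units$n_members, units$units$n_members)
  expect_identical(again$carriers, units$carriers)
})

test_that("simulated causal pairs always collapse into one unit", {
  for (seed in c(41, 42, 43)) {
    cohort <- simulate_cohort(cohort_config(
      n_affected = 8, n_unaffected = 8, background_variants = 30,
      seed = seed))
    units <- collapse_cis(cohort$genotypes)
    causal <- units$units[grepl("causal", units$units$member_ids), ]
    expect_equal(nrow(causal), 1L)
    expect_equal(causal$n_members, 2L)
  }
})
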