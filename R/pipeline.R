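#' Run the HAPH analysis pipeline from one configuration
#'
#' Orchestrates the stages `simulate`, `diversity`, `filter`, `assoc`
#' and `enrich`. Each stage runs iff its section is present in the
#' configuration (and listed in `stages`); inputs come either from the
#' simulate stage or from file paths in the `inputs` section. Every
#' intermediate artifact is written in the package's standard formats
#' (VCF + TSV) and a single JSON run report aggregates the filter
#' report, association statistics and enrichment result. With a fixed
#' config and seed the report is byte-identical across runs (no
#' timestamps are embedded).
#'
#' Configuration layout (YAML file or nested list): top-level `seed`,
#' optional `inputs` (`vcf`, `phenotypes`, `microsatellites`,
#' `expression`, `gene_set` paths), and per-stage sections:
#' `simulate` ([cohort_config()] fields plus an `expression` subsection
#' for [simulate_expression()]), `diversity` (`k`, `group`),
#' `filter` (`stages` as list of `[min_affected, max_unaffected]`,
#' `missing_policy`), `assoc` (`tables` as named list of
#' `[a, b, c, d]` herd counts, or empty to derive carrier status from
#' the filter stage; `prevalence`), `enrich` ([enrichment_config()]
#' fields).
#'
#' @param config path to a YAML file or a nested list.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @param stages character vector restricting which configured stages
#'   run (default: all present).
#' @param quiet suppress per-stage log lines.
#' @return the run report (list), invisibly written to
#'   `<out_dir>/run_report.json`.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL,
                         stages = c("simulate", "diversity", "filter",
                                    "assoc", "enrich"),
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  fail <- function(stage, e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               marker)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  report <- list(version = "1",
                 seed = seed,
                 stages = intersect(names(config),
                                    intersect(stages,
                                              c("simulate", "diversity",
                                                "filter", "assoc",
                                                "enrich"))))

  genotypes <- NULL; phenotypes <- NULL; microsat <- NULL
  expr <- NULL; gene_set <- NULL; cohort <- NULL
  inp <- config$inputs
  if (!is.null(inp$vcf)) genotypes <- read_vcf(inp$vcf)
  if (!is.null(inp$phenotypes)) phenotypes <- read_phenotypes(inp$phenotypes)
  if (!is.null(inp$microsatellites))
    microsat <- read_microsatellites(inp$microsatellites)
  if (!is.null(inp$expression)) expr <- read_expression(inp$expression)
  if (!is.null(inp$gene_set)) gene_set <- read_gene_set(inp$gene_set)

  if ("simulate" %in% report$stages) {
    tryCatch({
      sim_cfg <- config$simulate
      expr_cfg <- sim_cfg$expression
      sim_cfg$expression <- NULL
      # root seed split per stage: simulate gets seed, expression seed+1
      cc <- do.call(cohort_config, c(sim_cfg, list(seed = seed)))
      cohort <- simulate_cohort(cc)
      genotypes <- cohort$genotypes
      phenotypes <- cohort$phenotypes
      microsat <- cohort$microsatellites
      write_vcf(genotypes, file.path(out_dir, "cohort.vcf"))
      write_phenotypes(phenotypes, file.path(out_dir, "phenotypes.tsv"))
      utils::write.table(microsat, file.path(out_dir, "microsatellites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(expr_cfg)) {
        gene_set <- gene_set %||% expr_cfg$gene_set %||%
          sprintf("HIF_TARGET_%03d", seq_len(27))
        expr_args <- expr_cfg[setdiff(names(expr_cfg), "gene_set")]
        expr <- do.call(simulate_expression,
                        c(list(cohort = cohort, gene_set = gene_set,
                               seed = seed + 1L), expr_args))
        write_expression(expr, file.path(out_dir, "expression.tsv"))
      }
      report$simulate <- list(
        n_affected = sum(phenotypes$status == "affected"),
        n_unaffected = sum(phenotypes$status == "unaffected"),
        n_variants = nrow(genotypes$geno),
        n_carriers = length(cohort$truth$carriers),
        causal_gene = cohort$truth$causal_gene)
      log_stage("simulate", "%d samples, %d variants, %d carriers",
                nrow(phenotypes), nrow(genotypes$geno),
                length(cohort$truth$carriers))
    }, error = function(e) fail("simulate", e))
  }

  status <- NULL
  if (!is.null(phenotypes)) {
    status <- stats::setNames(phenotypes$status, phenotypes$sample_id)
    if (anyNA(status) && !is.null(config$thresholds)) {
      th <- config$thresholds
      status <- stats::setNames(
        classify_status(phenotypes$mean_pap,
                        affected_min = th$affected_min %||% 50,
                        unaffected_max = th$unaffected_max %||% 39),
        phenotypes$sample_id)
    }
  }

  if ("diversity" %in% report$stages) {
    tryCatch({
      dcfg <- config$diversity
      dist <- pairwise_distance(microsat)
      utils::write.table(dist, file.path(out_dir, "distance_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      sel <- lapply(dcfg$groups %||% c("affected", "unaffected"),
                    function(g)
                      select_diverse_subset(dist, phenotypes,
                                            k = dcfg$k %||% 5L, group = g))
      names(sel) <- dcfg$groups %||% c("affected", "unaffected")
      for (g in names(sel))
        writeLines(sel[[g]], file.path(out_dir,
                                       sprintf("diverse_subset_%s.txt", g)))
      report$diversity <- lapply(sel, function(s)
        list(samples = as.character(s), method = attr(s, "method"),
             total_distance = attr(s, "total_distance")))
      log_stage("diversity", "selected %s",
                paste(vapply(sel, paste, character(1), collapse = ","),
                      collapse = " | "))
    }, error = function(e) fail("diversity", e))
  }

  filter_report <- NULL
  if ("filter" %in% report$stages) {
    tryCatch({
      fcfg <- config$filter
      stage_list <- fcfg$stages %||% list(c(5, 0), c(4, 1), c(4, 0))
      keep <- names(status)[status %in% c("affected", "unaffected")]
      gm <- subset_variants(genotypes, samples = intersect(genotypes$samples,
                                                           keep))
      filter_report <- run_cascade(
        gm, status, stages = lapply(stage_list, unlist),
        missing_policy = fcfg$missing_policy %||% "as_noncarrier")
      utils::write.table(filter_report$details,
                         file.path(out_dir, "filter_details.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$filter <- list(
        summary = filter_report$summary,
        genes = filter_report$genes)
      log_stage("filter", "stage gene counts: %s",
                paste(filter_report$summary$n_genes, collapse = "/"))
    }, error = function(e) fail("filter", e))
  }

  if ("assoc" %in% report$stages) {
    tryCatch({
      acfg <- config$assoc
      prev <- acfg$prevalence %||% 0.5
      tables <- list()
      if (!is.null(acfg$tables)) {
        tables <- lapply(acfg$tables, function(x) as_ctab(unlist(x)))
      } else {
        # derive carrier flags from the strictest-passing haplotype unit
        if (is.null(filter_report) || nrow(filter_report$details) == 0L)
          stopf("no assoc tables given and no passing filter variants")
        units <- filter_report$units[[length(filter_report$units)]]
        if (nrow(units$units) == 0L)
          units <- filter_report$units[[1L]]
        best <- which.max(units$units$n_members)
        carrier <- stats::setNames(units$carriers[best, ], units$samples)
        tables <- list(herd1 = tabulate_carriers(carrier, status))
        report$assoc_carrier_unit <- units$units$member_ids[best]
      }
      per_herd <- lapply(tables, function(t) {
        chi <- chi2_2x2(t)
        rr <- relative_risk(t)
        or <- odds_ratio(t)
        pv <- predictive_values(t$a / (t$a + t$b), t$d / (t$c + t$d), prev)
        list(table = c(a = t$a, b = t$b, c = t$c, d = t$d),
             chi2 = chi$statistic, p = chi$p.value,
             rr = rr$estimate, rr_ci = c(rr$conf_low, rr$conf_high),
             or = or$estimate, or_ci = c(or$conf_low, or$conf_high),
             ppv = pv$ppv, npv = pv$npv)
      })
      res <- list(prevalence = prev, herds = per_herd)
      if (length(tables) > 1L) {
        pooled <- pool_tables(tables)
        chi <- chi2_2x2(pooled)
        res$joint <- list(table = c(a = pooled$a, b = pooled$b,
                                    c = pooled$c, d = pooled$d),
                          chi2 = chi$statistic, p = chi$p.value)
      }
      if (!is.null(phenotypes) && is.null(acfg$tables) &&
          exists("carrier", inherits = FALSE)) {
        pap <- stats::setNames(phenotypes$mean_pap, phenotypes$sample_id)
        ids <- intersect(names(carrier), names(pap))
        rs <- rank_sum(pap[ids][carrier[ids]], pap[ids][!carrier[ids]])
        res$rank_sum_p <- rs$p.value
      }
      report$assoc <- res
      log_stage("assoc", "herd p-values: %s",
                paste(signif(vapply(per_herd, `[[`, numeric(1), "p"), 3),
                      collapse = ", "))
    }, error = function(e) fail("assoc", e))
  }

  if ("enrich" %in% report$stages) {
    tryCatch({
      ecfg <- config$enrich %||% list()
      cfg <- enrichment_config(
        expression_floor = ecfg$expression_floor %||% 7,
        p_threshold = ecfg$p_threshold %||% 0.05,
        fc_threshold = ecfg$fc_threshold %||% 1.25,
        expected_mode = ecfg$expected_mode %||% "rounded_counts")
      groups <- list(
        affected = phenotypes$sample_id[status[phenotypes$sample_id] ==
                                          "affected"],
        unaffected = phenotypes$sample_id[status[phenotypes$sample_id] ==
                                            "unaffected"])
      if (!is.null(cohort))
        groups$affected <- intersect(groups$affected, cohort$truth$carriers)
      enr <- run_enrichment(expr, gene_set, groups, cfg)
      calls_df <- data.frame(gene = names(enr$calls), call = enr$calls,
                             row.names = NULL)
      utils::write.table(calls_df, file.path(out_dir, "enrichment_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$enrich <- list(
        n_expressed = enr$n_expressed,
        observed = as.list(enr$observed), expected = as.list(enr$expected),
        chi2 = enr$statistic, df = enr$df, p = enr$p.value,
        rates = enr$rates[c("p_up", "p_down")])
      log_stage("enrich", "chi-square %.3g (p = %.3g)",
                enr$statistic, enr$p.value)
    }, error = function(e) fail("enrich", e))
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

#' Render report tables (stage counts, passing genes, statistics)
#'
#' Writes three TSVs from a pipeline run report: per-stage filter
#' counts, the passing-gene list, and a flat statistics table.
#'
#' @param report a run report from [run_pipeline()] (or the parsed
#'   `run_report.json`).
#' @param out_dir directory for the TSVs.
#' @return character vector of paths written, invisibly.
#' @export
emit_paper_tables <- function(report, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p1 <- file.path(out_dir, "stage_counts.tsv")
  summ <- as.data.frame(report$filter$summary %||%
                          data.frame(stage = integer(),
                                     min_affected = integer(),
                                     max_unaffected = integer(),
                                     n_variants = integer(),
                                     n_genes = integer()))
  utils::write.table(summ, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p1)

  p2 <- file.path(out_dir, "passing_genes.tsv")
  genes <- report$filter$genes %||% list()
  gene_df <- if (length(genes) == 0L)
    data.frame(stage = integer(), gene = character())
  else do.call(rbind, lapply(seq_along(genes), function(s) {
    g <- unlist(genes[[s]])
    if (length(g) == 0L) return(NULL)
    data.frame(stage = s, gene = g)
  })) %||% data.frame(stage = integer(), gene = character())
  utils::write.table(gene_df, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p2)

  p3 <- file.path(out_dir, "statistics.tsv")
  stats_rows <- list()
  for (h in names(report$assoc$herds %||% list())) {
    hh <- report$assoc$herds[[h]]
    stats_rows[[h]] <- data.frame(
      herd = h, chi2 = hh$chi2, p = hh$p, rr = hh$rr, or = hh$or,
      ppv = hh$ppv, npv = hh$npv)
  }
  if (!is.null(report$assoc$joint))
    stats_rows$joint <- data.frame(herd = "joint",
                                   chi2 = report$assoc$joint$chi2,
                                   p = report$assoc$joint$p,
                                   rr = NA, or = NA, ppv = NA, npv = NA)
  stat_df <- do.call(rbind, stats_rows) %||%
    data.frame(herd = character(), chi2 = numeric(), p = numeric())
  utils::write.table(stat_df, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p3)
  invisible(paths)
}

#' Validate a run report against the shipped JSON schema
#'
#' Performs the structural checks declared by the schema at
#' `inst/schema/run-report.schema.json`: required top-level keys exist
#' and have the declared JSON types.
#'
#' @param report run-report list (from [run_pipeline()] or parsed from
#'   JSON).
#' @param schema_path path to the schema (default: the shipped one).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_run_report <- function(report,
                                schema_path = system.file(
                                  "schema", "run-report.schema.json",
                                  package = "haphseg")) {
  schema <- jsonlite::read_json(schema_path)
  for (key in unlist(schema$required))
    if (is.null(report[[key]]))
      stopf("run report lacks required key '%s'", key)
  type_ok <- function(x, type) {
    switch(type,
           string = is.character(x) && length(x) == 1L,
           integer = is.numeric(x) && length(x) == 1L &&
             x == floor(x),
           number = is.numeric(x) && length(x) == 1L,
           array = is.vector(x) || is.list(x),
           object = is.list(x),
           TRUE)
  }
  for (key in names(schema$properties)) {
    if (is.null(report[[key]])) next
    type <- schema$properties[[key]]$type
    if (!is.null(type) && !type_ok(report[[key]], type))
      stopf("run report key '%s' is not of schema type '%s'", key, type)
  }
  invisible(TRUE)
}
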