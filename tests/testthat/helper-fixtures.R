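# fixture builders and independent oracles shared across test files

# write a small VCF from raw field rows; returns the path
write_vcf_text <- function(records, samples, path = tempfile(fileext = ".vcf"),
                           eol = "\n") {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  con <- file(path, "wb")
  writeLines(c(header, records), con, sep = eol)
  close(con)
  path
}

# random genotype matrix: copy counts 0/1/2 with optional missing rate
random_gm <- function(n_var, samples, p_carrier = 0.3, p_missing = 0,
                      gene_per_variant = TRUE) {
  g <- matrix(stats::rbinom(n_var * length(samples), 2L,
                            1 - sqrt(1 - p_carrier)),
              nrow = n_var)
  if (p_missing > 0) {
    drop <- stats::runif(length(g)) < p_missing
    g[drop] <- NA_integer_
  }
  variants <- data.frame(
    chrom = "1", pos = seq_len(n_var), id = sprintf("v%03d", seq_len(n_var)),
    ref = "A", alt = "T",
    gene = if (gene_per_variant) sprintf("G%03d", seq_len(n_var))
           else sample(sprintf("G%03d", seq_len(max(1, n_var %/% 2))),
                       n_var, replace = TRUE),
    class = "nonsynonymous", annotation = "", stringsAsFactors = FALSE)
  genotype_matrix(variants, g, samples)
}

# independent brute-force dominant-filter oracle: per-variant loops
oracle_dominant_pass <- function(gm, status, min_aff, max_un,
                                 missing_policy = "as_noncarrier") {
  status <- status[gm$samples]
  pass <- logical(nrow(gm$geno))
  for (v in seq_len(nrow(gm$geno))) {
    aff <- 0L; un <- 0L; n_missing <- 0L
    for (s in seq_along(gm$samples)) {
      g <- gm$geno[v, s]
      if (is.na(g)) {
        n_missing <- n_missing + 1L
        next
      }
      if (g >= 1L) {
        if (status[s] == "affected") aff <- aff + 1L else un <- un + 1L
      }
    }
    pass[v] <- aff >= min_aff && un <= max_un &&
      (missing_policy != "as_fail" || n_missing == 0L)
  }
  pass
}

# independent allele-sharing oracle using count tables (vs match-removal)
oracle_pair_distance <- function(x, y) {
  lv <- unique(c(x, y))
  tx <- table(factor(x, levels = lv))
  ty <- table(factor(y, levels = lv))
  2L - sum(pmin(tx, ty))
}

# random microsatellite profile table
random_profiles <- function(n_samples, n_markers, n_alleles = 4,
                            p_missing = 0) {
  ids <- sprintf("S%02d", seq_len(n_samples))
  cols <- list(sample_id = ids)
  for (m in seq_len(n_markers)) {
    for (slot in c("a", "b")) {
      al <- sample(100 + 2 * seq_len(n_alleles), n_samples, replace = TRUE)
      if (p_missing > 0) al[stats::runif(n_samples) < p_missing] <- NA
      cols[[sprintf("marker%d_%s", m, slot)]] <- al
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(df, "markers") <- sprintf("marker%d", seq_len(n_markers))
  df
}

herd1_table <- function() contingency_2x2(15, 5, 4, 17)
herd2_table <- function() contingency_2x2(11, 4, 4, 12)
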