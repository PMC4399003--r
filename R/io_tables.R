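#' Read a phenotype table
#'
#' Expects a TSV with a header row containing at least `sample_id` and
#' `mean_pap` (mean pulmonary artery pressure, mm Hg); `herd`,
#' `altitude_ft` and `status` are honoured when present. A `status`
#' column is kept verbatim (values `affected`, `unaffected`,
#' `indeterminate`); otherwise status is left unassigned (`NA`) for
#' [classify_status()] to fill.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id`, `herd`, `altitude_ft`,
#'   `mean_pap`, `status`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(text = read_lines_clean(path),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "mean_pap")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stopf("phenotype table %s lacks required column(s): %s",
          path, paste(miss, collapse = ", "))
  pap <- suppressWarnings(as.numeric(df$mean_pap))
  if (anyNA(pap))
    stopf("non-numeric mean_pap value(s) in %s (e.g. '%s')",
          path, df$mean_pap[which(is.na(pap))[1L]])
  if (any(pap <= 0))
    stopf("mean_pap must be positive in %s", path)
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample_id in %s: %s",
          path, df$sample_id[duplicated(df$sample_id)][1L])
  data.frame(
    sample_id = as.character(df$sample_id),
    herd = as.character(df$herd %||% NA_character_),
    altitude_ft = suppressWarnings(as.numeric(df$altitude_ft %||% NA_real_)),
    mean_pap = pap,
    status = as.character(df$status %||% NA_character_),
    stringsAsFactors = FALSE)
}

#' Write a phenotype table as TSV
#'
#' @param phenotypes data.frame as returned by [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read microsatellite genotype profiles
#'
#' Expects a TSV with a `sample_id` column and two columns per marker
#' named `<marker>_a` and `<marker>_b` (unordered allele pair). Missing
#' alleles may be empty or `NA`; they are kept as `NA` and flagged by
#' downstream distance computation.
#'
#' @param path path to the TSV file.
#' @return data.frame with `sample_id` and paired allele columns; the
#'   marker names are stored in `attr(, "markers")`.
#' @export
read_microsatellites <- function(path) {
  df <- utils::read.delim(text = read_lines_clean(path),
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stopf("microsatellite table %s lacks a sample_id column", path)
  acols <- grep("_a$", names(df), value = TRUE)
  markers <- sub("_a$", "", acols)
  bcols <- paste0(markers, "_b")
  missing_b <- setdiff(bcols, names(df))
  if (length(markers) == 0L || length(missing_b) > 0L)
    stopf("microsatellite table %s: every marker needs <marker>_a and %s",
          path, "<marker>_b columns")
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample_id in %s", path)
  out <- df[, c("sample_id", as.vector(rbind(acols, bcols)))]
  out$sample_id <- as.character(out$sample_id)
  attr(out, "markers") <- markers
  out
}

#' Read a log2 expression matrix
#'
#' Expects a TSV whose first column (`gene`) holds gene symbols and
#' remaining columns one sample each, values in log2 units. Duplicate
#' gene symbols are an error; non-finite values become `NA`.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(text = read_lines_clean(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stopf("expression table %s needs a gene column plus >=1 sample", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stopf("duplicated gene symbol in %s: %s",
          path, genes[duplicated(genes)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  m[!is.finite(m)] <- NA_real_
  rownames(m) <- genes
  m
}

#' Write a log2 expression matrix as TSV
#'
#' @param expr numeric matrix, genes in rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set from a plain-text list
#'
#' One symbol per line; blank lines and `#` comments are skipped;
#' duplicates are collapsed keeping first occurrence order.
#'
#' @param path path to the list file.
#' @return character vector of unique gene symbols (possibly empty,
#'   with a warning).
#' @export
read_gene_set <- function(path) {
  x <- read_lines_clean(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  x <- x[!duplicated(x)]
  if (length(x) == 0L) warnf("gene set %s is empty", path)
  x
}
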