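#' Genotype matrix with dominant carrier semantics
#'
#' Container for exome variants by samples. Genotypes are stored as the
#' number of copies of the (single) alternate allele: 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing
#' call. Multi-allelic input records are split on read so that every row
#' describes exactly one alternate allele; under the dominant model a
#' sample is a carrier of a variant iff its copy count is at least 1.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`, `gene`, `class`, `annotation`.
#' @param geno integer matrix, variants in rows, samples in columns.
#' @param samples character vector of sample ids (column order of `geno`).
#' @return An object of class `genotype_matrix`.
#' @seealso [read_vcf()], [write_vcf()], [dominant_filter()]
#' @export
genotype_matrix <- function(variants, geno, samples) {
  stopifnot(is.data.frame(variants), is.matrix(geno))
  need <- c("chrom", "pos", "id", "ref", "alt", "gene", "class", "annotation")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0L)
    stopf("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(variants) != nrow(geno))
    stopf("variant table (%d rows) and genotype matrix (%d rows) disagree",
          nrow(variants), nrow(geno))
  if (length(samples) != ncol(geno))
    stopf("%d samples but genotype matrix has %d columns",
          length(samples), ncol(geno))
  if (anyDuplicated(samples))
    stopf("duplicated sample id: %s", samples[duplicated(samples)][1L])
  if (any(variants$pos < 1L, na.rm = TRUE))
    stopf("variant positions must be 1-based (>= 1)")
  mode(geno) <- "integer"
  dimnames(geno) <- list(variants$id, samples)
  structure(list(variants = variants, geno = geno, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variant(s) x %d sample(s)\n",
              nrow(x$geno), ncol(x$geno)))
  cat(sprintf("  genes: %d distinct; missing calls: %d\n",
              length(unique(x$variants$gene[x$variants$gene != ""])),
              sum(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by variant index and/or sample id
#'
#' @param gm a [genotype_matrix()].
#' @param variants integer or logical index over variant rows.
#' @param samples character vector of sample ids to retain.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_variants <- function(gm, variants = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vi <- variants %||% seq_len(nrow(gm$geno))
  si <- gm$samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, gm$samples)
    if (length(missing) > 0L)
      stopf("sample(s) not in genotype matrix: %s",
            paste(missing, collapse = ", "))
    si <- samples
  }
  genotype_matrix(gm$variants[vi, , drop = FALSE],
                  gm$geno[vi, si, drop = FALSE], si)
}

# parse one GT token ("0/1", "0|1", "./.", ".") into copies of allele k
gt_copies <- function(gt, k) {
  alleles <- strsplit(gt, "[/|]", fixed = FALSE)
  vapply(alleles, function(a) {
    if (length(a) == 0L || any(a == ".")) return(NA_integer_)
    sum(a == as.character(k))
  }, integer(1))
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  if (length(m) == 0L) return("")
  sub(paste0("^;?", key, "="), "", m)
}

#' Read a minimal-dialect VCF v4.2 file into a genotype matrix
#'
#' Supports the subset of VCF needed for co-segregation analysis:
#' CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT columns with a GT entry
#' in FORMAT. Multi-allelic records are split into one biallelic record
#' per alternate allele; a sample's copy count for allele *k* is the
#' number of times allele index *k* appears in its GT (phase separators
#' `/` and `|` are equivalent, and `./.` is parsed as missing, never as
#' homozygous reference). The INFO keys `GENE`, `CLASS` and `ANN` carry
#' the gene symbol, consequence class and free-text annotation.
#'
#' @param path path to a VCF file (plain text; CRLF tolerated).
#' @param sample_subset optional character vector restricting (and
#'   ordering) the samples returned; an absent id is an error.
#' @return A [genotype_matrix()] with records in file order (split
#'   alleles adjacent, in ALT order).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  lines <- read_lines_clean(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    stopf("malformed VCF %s: expected exactly one #CHROM header line", path)
  hfields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(hfields) < 10L || hfields[9L] != "FORMAT")
    stopf("malformed VCF header at line %d: need FORMAT and >=1 sample", hdr)
  samples <- hfields[-(1:9)]

  rec_lines <- which(seq_along(lines) > hdr & nzchar(lines) &
                       !startsWith(lines, "#"))
  vlist <- vector("list", length(rec_lines))
  glist <- vector("list", length(rec_lines))
  for (i in seq_along(rec_lines)) {
    ln <- rec_lines[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + length(samples))
      stopf("malformed VCF record at line %d: %d fields, expected %d",
            ln, length(f), 9L + length(samples))
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx))
      stopf("malformed VCF record at line %d: no GT in FORMAT", ln)
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L)
      stopf("malformed VCF record at line %d: bad POS '%s'", ln, f[2L])
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE),
                  function(x) x[gt_idx], character(1))
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1]]
    gene <- parse_info_field(f[8L], "GENE")
    cls <- parse_info_field(f[8L], "CLASS")
    ann <- parse_info_field(f[8L], "ANN")
    vlist[[i]] <- data.frame(
      chrom = f[1L], pos = pos,
      id = if (f[3L] == "." && length(alts) > 1L)
        paste0(f[1L], ":", pos, "_", seq_along(alts))
      else if (length(alts) > 1L) paste0(f[3L], "_", seq_along(alts))
      else if (f[3L] == ".") paste0(f[1L], ":", pos) else f[3L],
      ref = f[4L], alt = alts, gene = gene, class = cls,
      annotation = ann, stringsAsFactors = FALSE)
    glist[[i]] <- t(vapply(seq_along(alts),
                           function(k) gt_copies(gts, k),
                           integer(length(samples))))
  }
  variants <- do.call(rbind, vlist) %||%
    data.frame(chrom = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), gene = character(),
               class = character(), annotation = character())
  geno <- do.call(rbind, glist) %||%
    matrix(integer(), nrow = 0, ncol = length(samples))
  gm <- genotype_matrix(variants, geno, samples)
  if (!is.null(sample_subset)) gm <- subset_variants(gm, samples = sample_subset)
  gm
}

#' Write a genotype matrix as a minimal VCF v4.2 file
#'
#' Emits one biallelic record per variant row with GT-only FORMAT and
#' the INFO keys `GENE`, `CLASS` and `ANN`. Copy counts map back to
#' unphased GT strings (0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' `NA` -> `./.`), so `read_vcf(write_vcf(gm))` reproduces CHROM, POS,
#' REF, ALT and GT exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  info <- sprintf("GENE=%s;CLASS=%s;ANN=%s", v$gene, v$class, v$annotation)
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$geno), ncol = ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_map[gm$geno[ok] + 1L]
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
                sep = "\t")
  if (ncol(gm$geno) > 0L && nrow(gm$geno) > 0L)
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
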