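#' Read a VCF file into a variant table and genotype matrix
#'
#' Parses a VCF v4.x file (only the GT format field is required) with
#' [vcfR::read.vcfR()] and recodes genotypes as alternate-allele counts.
#' Multi-allelic records are decomposed so that every output row is biallelic:
#' a record with k ALT alleles becomes k rows, and each sample's count for
#' row k is the number of its alleles equal to ALT k. Missing calls (`./.`)
#' are preserved as `NA`. Annotation is taken from the INFO keys `GENE`,
#' `REGION`, `CSQ` and `PCHANGE` when present (as written by [write_vcf()]).
#'
#' @param path path to a VCF (plain text or gzipped).
#' @return a list with elements `variants` (a [variant_table()]) and
#'   `genotypes` (integer matrix, variants x samples, values 0/1/2/`NA`, with
#'   a `"haplotypes"` attribute holding the two per-sample allele matrices
#'   when every call is phased).
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  prescan_vcf(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt
  samples <- colnames(gt_raw)[-1]
  # GT is the leading (or only) field of each genotype column
  gt <- sub(":.*$", "", gt_raw[, -1, drop = FALSE])
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|]([^/|]*)$", "\\1", gt)
  a1[a1 == "." | a1 == ""] <- NA
  a2[a2 == "." | a2 == ""] <- NA
  a1 <- matrix(suppressWarnings(as.integer(a1)), nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(a2)), nrow = nrow(gt))
  phased <- all(grepl("\\|", gt) | is.na(a1))

  info_field <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene_i <- info_field("GENE")
  region_i <- info_field("REGION")
  csq_i <- info_field("CSQ")
  pch_i <- info_field("PCHANGE")
  region_i[is.na(region_i)] <- "other"

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))
  alt_vec <- unlist(alt_list)

  geno <- matrix(NA_integer_, nrow = length(row_idx), ncol = length(samples))
  hapA <- hapB <- matrix(NA_integer_, nrow = length(row_idx), ncol = length(samples))
  for (j in seq_along(row_idx)) {
    i <- row_idx[j]; k <- alt_idx[j]
    g1 <- as.integer(a1[i, ] == k); g2 <- as.integer(a2[i, ] == k)
    geno[j, ] <- g1 + g2
    hapA[j, ] <- g1; hapB[j, ] <- g2
  }

  variants <- variant_table(
    chrom = fix[row_idx, "CHROM"], pos = as.integer(fix[row_idx, "POS"]),
    ref = fix[row_idx, "REF"], alt = alt_vec,
    rsid = ifelse(fix[row_idx, "ID"] == ".", NA_character_, fix[row_idx, "ID"]),
    genes = gene_i[row_idx], region = region_i[row_idx],
    consequence = csq_i[row_idx], protein_change = pch_i[row_idx]
  )
  dimnames(geno) <- list(variants$key, samples)
  if (phased) {
    dimnames(hapA) <- dimnames(hapB) <- dimnames(geno)
    attr(geno, "haplotypes") <- list(hapA, hapB)
  }
  list(variants = variants, genotypes = geno)
}

# Cheap structural validation so malformed files fail with a line number
# (vcfR is permissive and reports neither).
prescan_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) {
    stop("malformed VCF header: no #CHROM line in ", path)
  }
  nfield <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- seq_along(lines) > hdr[1]
  counts <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  bad <- which(counts != nfield & nzchar(lines[body]))
  if (length(bad)) {
    stop(sprintf("malformed VCF record at line %d: expected %d fields, found %d",
                 hdr[1] + bad[1], nfield, counts[bad[1]]))
  }
  invisible(TRUE)
}

#' Write a variant table and genotype matrix as VCF v4.2
#'
#' Emits one biallelic record per variant row with annotation in the INFO
#' keys `GENE`, `REGION`, `CSQ` and `PCHANGE`, so [read_vcf()] round-trips
#' the in-memory records exactly. Genotypes are written phased (`a|b`) when
#' the matrix carries a `"haplotypes"` attribute and unphased otherwise.
#'
#' @param variants a [variant_table()].
#' @param genotypes integer matrix (variants x samples) as from [read_vcf()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == nrow(genotypes))
  haps <- attr(genotypes, "haplotypes")
  samples <- colnames(genotypes)
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (!is.na(variants$genes[i])) parts <- c(parts, paste0("GENE=", variants$genes[i]))
    parts <- c(parts, paste0("REGION=", variants$region[i]))
    if (!is.na(variants$consequence[i])) parts <- c(parts, paste0("CSQ=", variants$consequence[i]))
    if (!is.na(variants$protein_change[i])) parts <- c(parts, paste0("PCHANGE=", variants$protein_change[i]))
    paste(parts, collapse = ";")
  }, "")
  if (is.null(haps)) {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix(code[as.character(genotypes)], nrow = nrow(genotypes))
    gt[is.na(genotypes)] <- "./."
  } else {
    gt <- matrix(paste0(haps[[1]], "|", haps[[2]]), nrow = nrow(genotypes))
    gt[is.na(haps[[1]]) | is.na(haps[[2]])] <- ".|."
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=.,Type=String,Description=\"Overlapping gene symbols\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Functional region\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Exonic consequence\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- cbind(variants$chrom, variants$pos,
                ifelse(is.na(variants$rsid), ".", variants$rsid),
                variants$ref, variants$alt, ".", "PASS", info, "GT", gt)
  writeLines(c(hdr, apply(rows, 1, paste, collapse = "\t")), path)
  invisible(path)
}
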