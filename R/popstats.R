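#' Minor allele frequency
#'
#' `MAF = min(p, 1 - p)` for alternate-allele frequency `p`; always in
#' `[0, 0.5]`.
#'
#' @param af alternate-allele frequency (vectorised), each in `[0, 1]`.
#' @return numeric vector of minor-allele frequencies.
#' @export
compute_maf <- function(af) {
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop("allele frequencies must be in [0, 1]")
  }
  pmin(af, 1 - af)
}

#' The six standard MAF bins
#'
#' Edges of the spectrum bins 0-0.05, >0.05-0.1, >0.1-0.2, >0.2-0.3,
#' >0.3-0.4, >0.4-0.5: the first bin is closed on both ends, the rest are
#' half-open `(a, b]` (so a MAF of exactly 0.05 falls in the first bin).
#'
#' @return numeric vector of 7 edges.
#' @export
maf_bin_edges <- function() c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Bin minor-allele frequencies into the six-band spectrum
#'
#' @param mafs numeric vector of MAFs in `[0, 0.5]`.
#' @return named numeric vector of 6 proportions summing to 1 (all zero
#'   with attribute `undefined = TRUE` for empty input).
#' @export
bin_maf <- function(mafs) {
  if (any(mafs < 0 | mafs > 0.5, na.rm = TRUE)) {
    stop("MAF values must be in [0, 0.5]")
  }
  mafs <- mafs[!is.na(mafs)]
  edges <- maf_bin_edges()
  labels <- paste0(c("0", paste0(">", edges[2:6])), "-", edges[-1])
  if (!length(mafs)) {
    out <- setNames(rep(0, 6), labels)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  counts <- table(cut(mafs, breaks = edges, include.lowest = TRUE,
                      right = TRUE))
  setNames(as.numeric(counts) / length(mafs), labels)
}

#' Per-gene pathogenic SNP fraction
#'
#' The fraction of reported-pathogenic SNPs among all SNPs assigned to a
#' gene: `count(pathogenic) / count(total)`. Undefined (`NA`, not 0) when no
#' SNP is assigned.
#'
#' @param pathogenic logical vector of per-SNP pathogenic flags (flags are
#'   taken from annotation input, e.g. ClinVar/ANNOVAR reports — they are
#'   never recomputed here).
#' @return a single fraction in `[0, 1]`, or `NA` for empty input.
#' @export
pathogenic_fraction <- function(pathogenic) {
  if (!length(pathogenic)) return(NA_real_)
  mean(pathogenic)
}

#' Gene-level aggregated SNP frequency
#'
#' Aggregates the MAFs of the SNPs assigned to a gene region (the gene span
#' plus a flank on each side). The default aggregation is the SUM of
#' per-SNP MAFs — unbounded above, so burdened genes can score above 1 —
#' with `mean` available as an alternative. Undefined (`NA`) when no SNP
#' falls in the region.
#'
#' @param mafs MAFs of the SNPs assigned to the gene region.
#' @param aggregation `"sum"` (default) or `"mean"`.
#' @return a single number, or `NA` for empty input.
#' @export
gene_snp_frequency <- function(mafs, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  mafs <- mafs[!is.na(mafs)]
  if (!length(mafs)) return(NA_real_)
  if (aggregation == "sum") sum(mafs) else mean(mafs)
}

# SNP -> gene assignment: variant indices falling in [start - flank,
# end + flank] on the gene's chromosome.
assign_snps_to_gene <- function(variants, gene, flank_bp = 2000L) {
  which(variants$chrom == gene$chrom &
          variants$pos >= gene$start_bp - flank_bp &
          variants$pos <= gene$end_bp + flank_bp)
}

#' Cross-population per-gene burden table and MAF spectra
#'
#' For every (gene, population) pair computes the pathogenic SNP fraction
#' and the gene-level aggregated SNP frequency over the SNPs assigned to
#' the gene region (span plus flank), and for every population the
#' six-bin MAF spectrum over all its SNPs. Population columns may include
#' family-derived frequency columns, so families can be compared against
#' reference populations on the same footing.
#'
#' @param variants a [variant_table()] (positions used for assignment).
#' @param panel allele-frequency matrix (variant keys x populations).
#' @param pathogenic named logical vector of per-variant pathogenic flags
#'   (missing keys count as not pathogenic).
#' @param genes a `gene_models` table.
#' @param flank_bp up/downstream flank for SNP assignment (default 2000).
#' @param aggregation passed to [gene_snp_frequency()].
#' @return list with `burden` (long data.frame: `gene`, `population`,
#'   `n_snps`, `pathogenic_fraction`, `gene_snp_frequency`, deterministic
#'   (gene, population) ordering; undefined entries are `NA`) and `spectra`
#'   (data.frame: `population`, `bin`, `proportion`). The `aggregation` and
#'   `flank_bp` used are attached as attributes of `burden`.
#' @export
population_comparison_table <- function(variants, panel, pathogenic, genes,
                                        flank_bp = 2000L,
                                        aggregation = "sum") {
  pops <- colnames(panel)
  flags <- setNames(rep(FALSE, nrow(variants)), variants$key)
  flags[intersect(names(pathogenic), names(flags))] <-
    pathogenic[intersect(names(pathogenic), names(flags))]
  af <- matrix(NA_real_, nrow = nrow(variants), ncol = length(pops),
               dimnames = list(variants$key, pops))
  present <- variants$key %in% rownames(panel)
  af[present, ] <- panel[variants$key[present], , drop = FALSE]
  maf <- compute_maf(af)              # pmin keeps the matrix shape

  rows <- list()
  for (gi in seq_len(nrow(genes))) {
    snps <- assign_snps_to_gene(variants, genes[gi, ], flank_bp)
    for (pop in pops) {
      m <- maf[snps, pop]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$symbol[gi], population = pop,
        n_snps = sum(!is.na(m)),
        pathogenic_fraction = pathogenic_fraction(flags[snps][!is.na(m)]),
        gene_snp_frequency = gene_snp_frequency(m, aggregation),
        stringsAsFactors = FALSE)
    }
  }
  burden <- do.call(rbind, rows)
  burden <- burden[order(burden$gene, burden$population), , drop = FALSE]
  rownames(burden) <- NULL
  attr(burden, "aggregation") <- aggregation
  attr(burden, "flank_bp") <- flank_bp

  spectra <- do.call(rbind, lapply(pops, function(pop) {
    sp <- bin_maf(maf[!is.na(maf[, pop]), pop])
    data.frame(population = pop, bin = names(sp), proportion = as.numeric(sp),
               stringsAsFactors = FALSE)
  }))
  list(burden = burden, spectra = spectra)
}

#' Read / write a per-population allele-frequency table
#'
#' TSV with a `key` column (variant key) and one numeric column per
#' population; frequencies must lie in `[0, 1]`.
#'
#' @param path path to the TSV.
#' @return numeric matrix (keys x populations).
#' @export
read_frequency_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"key" %in% names(tab)) stop("frequency table needs a 'key' column")
  mat <- as.matrix(tab[setdiff(names(tab), "key")])
  rownames(mat) <- tab$key
  if (any(mat < 0 | mat > 1, na.rm = TRUE)) {
    stop("allele frequencies outside [0, 1] in ", path)
  }
  mat
}

#' @rdname read_frequency_table
#' @param panel frequency matrix to write.
#' @return (`write_frequency_table`) `path`, invisibly.
#' @export
write_frequency_table <- function(panel, path) {
  out <- data.frame(key = rownames(panel), panel, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
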