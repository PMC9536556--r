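# shared fixture builders (everything generated in code at test time)

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal VCF with explicit genotype strings
tiny_vcf <- function(records, samples = c("S1", "S2", "S3")) {
  write_tmp_lines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), ext = ".vcf")
}

vcf_record <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# one nuclear family: two founders + kids (optionally one MZ pair)
nuclear_pedigree <- function(n_kids = 2, mz = FALSE, family = "Fam",
                             affected_kids = rep(TRUE, n_kids)) {
  kid_ids <- paste0(family, "_kid", seq_len(n_kids))
  ped <- data.frame(
    id = c(paste0(family, "_dad"), paste0(family, "_mum"), kid_ids),
    family_id = family,
    father_id = c("0", "0", rep(paste0(family, "_dad"), n_kids)),
    mother_id = c("0", "0", rep(paste0(family, "_mum"), n_kids)),
    sex = c("male", "female", rep("male", n_kids)),
    affected = c(FALSE, FALSE, affected_kids),
    mz_group = c(NA, NA,
                 if (mz && n_kids >= 2) c("MZ", "MZ", rep(NA, n_kids - 2))
                 else rep(NA, n_kids)),
    stringsAsFactors = FALSE)
  ped$founder <- ped$father_id == "0"
  ped
}

empty_plan <- function() {
  data.frame(gene = character(0), n_variants = integer(0),
             families = character(0), pattern = character(0))
}

# small complete synthetic study, cached once per test run
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(seed = 42))
    }
    cache
  }
})

split_genes_test <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

# brute-force interval-overlap oracle (quadratic)
oracle_overlap_genes <- function(segment, genes, containment = FALSE) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    if (genes$chrom[i] != segment$chrom) return(FALSE)
    if (containment) {
      genes$start_bp[i] >= segment$start_bp && genes$end_bp[i] <= segment$end_bp
    } else {
      genes$start_bp[i] <= segment$end_bp && genes$end_bp[i] >= segment$start_bp
    }
  }, TRUE)
  idx <- which(hit)
  idx <- idx[order(genes$start_bp[idx], genes$symbol[idx])]
  genes$symbol[idx]
}
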