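#' Variant keys
#'
#' Variants are identified throughout the package by the string
#' `chrom:pos:ref:alt`. Genotype matrices, prediction profiles and frequency
#' panels are all keyed this way so tables from different sources join
#' unambiguously after multi-allelic decomposition.
#'
#' @param chrom,pos,ref,alt vectors of chromosome, 1-based position,
#'   reference and alternate allele.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a variant table
#'
#' The package-wide representation of variants is a plain data frame with one
#' row per biallelic (chrom, pos, ref, alt) record. `genes` is a
#' comma-separated list of overlapped gene symbols (a variant may support
#' several genes). `consequence` must be present exactly for exonic variants.
#'
#' @param chrom,pos,ref,alt per-variant fields; `pos` is 1-based.
#' @param rsid optional identifiers (`NA` allowed).
#' @param genes comma-separated gene symbols (`NA` if none).
#' @param region functional region, one of [variant_regions()].
#' @param consequence exonic consequence, one of [variant_consequences()] or
#'   `NA` for non-exonic variants.
#' @param protein_change optional protein-level change strings.
#' @return data.frame of class `variant_table` with a `key` column.
#' @export
variant_table <- function(chrom, pos, ref, alt, rsid = NA_character_,
                          genes = NA_character_, region = "other",
                          consequence = NA_character_,
                          protein_change = NA_character_) {
  n <- length(chrom)
  pos <- as.integer(pos)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (any(pos < 1L)) stop("variant positions must be >= 1 (1-based)")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  region <- rep_len(as.character(region), n)
  consequence <- rep_len(as.character(consequence), n)
  bad_region <- setdiff(unique(region), variant_regions())
  if (length(bad_region)) {
    stop("unknown region value(s): ", paste(bad_region, collapse = ", "))
  }
  bad_csq <- setdiff(unique(consequence[!is.na(consequence)]),
                     variant_consequences())
  if (length(bad_csq)) {
    stop("unknown consequence value(s): ", paste(bad_csq, collapse = ", "))
  }
  if (any(region == "exonic" & is.na(consequence))) {
    stop("exonic variants must carry a consequence")
  }
  if (any(region != "exonic" & !is.na(consequence))) {
    stop("consequence is only defined for exonic variants")
  }
  out <- data.frame(
    key = variant_key(chrom, pos, ref, alt),
    chrom = as.character(chrom), pos = pos,
    ref = as.character(ref), alt = as.character(alt),
    rsid = rep_len(as.character(rsid), n),
    genes = rep_len(as.character(genes), n),
    region = region, consequence = consequence,
    protein_change = rep_len(as.character(protein_change), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Controlled vocabularies for variant annotation
#'
#' @return character vector of allowed region / consequence labels.
#' @export
variant_regions <- function() {
  c("exonic", "splicing", "ncRNA_exonic", "UTR5", "UTR3", "intronic",
    "upstream", "downstream", "intergenic", "other")
}

#' @rdname variant_regions
#' @export
variant_consequences <- function() {
  c("nonsynonymous", "synonymous", "stopgain", "stoploss",
    "frameshift_insertion", "frameshift_deletion",
    "nonframeshift_insertion", "nonframeshift_deletion", "unknown")
}

# Split a comma-separated gene field into a character vector (empty for NA).
split_genes <- function(genes) {
  if (length(genes) == 1L) {
    if (is.na(genes) || genes == "") return(character(0))
    return(strsplit(genes, ",", fixed = TRUE)[[1]])
  }
  lapply(genes, split_genes)
}
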