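#' Worked-example data: a two-family ACL rupture study design
#'
#' Small bundled datasets mirroring the published record of a two-family
#' anterior cruciate ligament (ACL) rupture whole-genome study: the
#' two-family pedigree (each family with a monozygotic twin pair), the 11
#' pairwise shared IBD segment records with their LOD scores and genetic
#' lengths, gene models for the genes listed on those segments, and the
#' African/European population frequencies of the six shared candidate
#' variants. Only the LINC01250 gene span is a real coordinate; every
#' other gene placement, and all candidate variant positions, are
#' synthetic placements inside their printed segments (the files carry
#' `synthetic` in their names). The original sequence data are not public;
#' these tables exercise the intersection, annotation and counting
#' operations on the printed record.
#'
#' The record pairing the twin pair jointly against their brother is
#' encoded as the pair (twin 1, brother): monozygotic twins are
#' genetically identical, so the pairwise record carries the same content.
#'
#' Known internal inconsistencies of the printed record are preserved, not
#' reconciled: gene counts in the prose ("17 genes", "8 genes", "29
#' genes") exceed the listed entries (11, 6, 27); the same ~3 Mb
#' chromosome 2 locus is labelled both 2p25.3 and 2q25.3 (coordinates are
#' trusted, band labels are not); and `LILRP1` is listed twice (kept as
#' two models; counting follows entries as listed).
#'
#' @return `acl_example_pedigree()`: a `pedigree_table`;
#'   `acl_example_segments()`: an `ibd_segments` table (11 records);
#'   `acl_example_genes()`: a `gene_models` table;
#'   `acl_example_candidates()`: a list with `variants` (a
#'   [variant_table()] of the six shared candidate variants) and `panel`
#'   (AFR/EUR allele-frequency matrix).
#' @name acl_examples
NULL

acl_extdata <- function(f) {
  system.file("extdata", f, package = "famshare", mustWork = TRUE)
}

#' @rdname acl_examples
#' @export
acl_example_pedigree <- function() {
  read_pedigree(acl_extdata("acl_pedigree.ped"))
}

#' @rdname acl_examples
#' @export
acl_example_segments <- function() {
  read_ibd_file(acl_extdata("acl_ibd_segments.tsv"), dialect = "simple_tsv")
}

#' @rdname acl_examples
#' @export
acl_example_genes <- function() {
  read_gene_bed(acl_extdata("acl_region_genes.synthetic.bed"))
}

#' @rdname acl_examples
#' @export
acl_example_candidates <- function() {
  tab <- read.delim(acl_extdata("acl_candidate_frequencies.synthetic.tsv"),
                    stringsAsFactors = FALSE)
  variants <- variant_table(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                            alt = tab$alt, rsid = tab$rsid, genes = tab$gene,
                            region = "exonic", consequence = "nonsynonymous")
  panel <- as.matrix(tab[, c("AFR", "EUR")])
  rownames(panel) <- variants$key
  list(variants = variants, panel = panel)
}
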