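#' Plant pathogenic variants into a simulated study
#'
#' For each planned variant the carrier pattern is imposed as a
#' Mendelian-consistent genotype configuration on the listed families:
#' affected members are set homozygous alternate (`pattern = "hom"`, the
#' default, matching the shared-candidate pattern of two-family studies) or
#' heterozygous (`"het"`); unaffected members are set heterozygous by
#' default (`unaffected = "het"`) or homozygous reference
#' (`unaffected = "ref"`). The assignment overwrites the gene-dropped
#' haplotypes at the planted sites; a pattern that is Mendelian-impossible
#' (e.g. a homozygous-alternate child of two reference-homozygous parents)
#' is an error, never a silent adjustment. Planted variant keys are added
#' to the truth set.
#'
#' @param genotypes genotype matrix from [gene_drop()] (haplotype attribute
#'   updated in place).
#' @param truth ground-truth list from [gene_drop()].
#' @param variants the study [variant_table()]; planted sites are forced to
#'   exonic nonsynonymous consequence.
#' @param genes `gene_models` table; every planned gene must exist and
#'   contain at least one site.
#' @param pedigree the study pedigree.
#' @param plan data.frame with columns `gene`, `n_variants`, `families`
#'   (comma-separated family ids or `"all"`), `pattern`; an optional
#'   `site_key` column pins each planned variant to a specific site
#'   (as chosen up front by [simulate_study()] so the panel can make the
#'   site rare before founder haplotypes are drawn).
#' @param seed integer seed for site selection within genes.
#' @param unaffected `"het"` or `"ref"` — genotype assigned to unaffected
#'   members of the listed families.
#' @return list with updated `genotypes`, `truth` (with `true_deleterious`
#'   and a `planted` data.frame of gene/key/families) and `variants`.
#' @export
plant_pathogenic_variants <- function(genotypes, truth, variants, genes,
                                      pedigree, plan, seed = 1L,
                                      unaffected = c("het", "ref")) {
  unaffected <- match.arg(unaffected)
  if (is.null(plan) || !nrow(plan)) {
    truth$planted <- data.frame(gene = character(0), key = character(0),
                                families = character(0))
    return(list(genotypes = genotypes, truth = truth, variants = variants))
  }
  set.seed(seed)
  haps <- attr(genotypes, "haplotypes")
  planted <- list()
  used_sites <- integer(0)
  for (r in seq_len(nrow(plan))) {
    gene <- plan$gene[r]
    gi <- which(genes$symbol == gene)
    if (!length(gi)) stop("planned gene not in the gene model: ", gene)
    fams <- if (plan$families[r] == "all") unique(pedigree$family_id) else
      strsplit(plan$families[r], ",", fixed = TRUE)[[1]]
    members <- pedigree[pedigree$family_id %in% fams, ]
    g_aff <- if (plan$pattern[r] == "hom") 2L else 1L
    g_un <- if (unaffected == "het") 1L else 0L
    assigned <- setNames(ifelse(members$affected, g_aff, g_un), members$id)
    check_mendelian_pattern(assigned, members, gene)
    if (!is.null(plan$site_key)) {
      pick <- match(plan$site_key[r], variants$key)
      if (is.na(pick)) stop("planned site_key not in variants: ", plan$site_key[r])
    } else {
      sites <- setdiff(assign_snps_to_gene(variants, genes[gi[1], ], 0L),
                       used_sites)
      if (length(sites) < plan$n_variants[r]) {
        stop("gene ", gene, " has too few free sites for the plan")
      }
      pick <- sites[sample.int(length(sites), plan$n_variants[r])]
    }
    used_sites <- c(used_sites, pick)
    for (s in pick) {
      cols <- match(members$id, colnames(genotypes))
      known <- !is.na(cols)
      genotypes[s, cols[known]] <- assigned[members$id[known]]
      haps[[1]][s, cols[known]] <- as.integer(assigned[members$id[known]] >= 1L)
      haps[[2]][s, cols[known]] <- as.integer(assigned[members$id[known]] == 2L)
      variants$region[s] <- "exonic"
      variants$consequence[s] <- "nonsynonymous"
      planted[[length(planted) + 1L]] <- data.frame(
        gene = gene, key = variants$key[s],
        families = paste(fams, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  attr(genotypes, "haplotypes") <- haps
  planted <- do.call(rbind, planted)
  truth$true_deleterious <- unique(c(truth$true_deleterious, planted$key))
  truth$planted <- planted
  list(genotypes = genotypes, truth = truth, variants = variants)
}

# Genotype-level Mendelian consistency of an assigned pattern: every child
# with both parents assigned must be able to receive its alleles.
check_mendelian_pattern <- function(assigned, members, gene) {
  for (i in seq_len(nrow(members))) {
    fa <- members$father_id[i]; mo <- members$mother_id[i]
    if (!(fa %in% names(assigned)) || !(mo %in% names(assigned))) next
    gc <- assigned[[members$id[i]]]
    gf <- assigned[[fa]]; gm <- assigned[[mo]]
    ok <- switch(as.character(gc),
                 `2` = gf >= 1 && gm >= 1,
                 `1` = (gf >= 1 && gm <= 1) || (gm >= 1 && gf <= 1),
                 `0` = gf <= 1 && gm <= 1)
    if (!ok) {
      stop("carrier pattern for gene ", gene, " is Mendelian-impossible: ",
           members$id[i], " (genotype ", gc, ") with parents ", fa,
           " (", gf, ") and ", mo, " (", gm, ")")
    }
  }
  invisible(TRUE)
}
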