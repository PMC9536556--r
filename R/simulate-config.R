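#' Simulation configuration
#'
#' Collects every tunable of the synthetic two-family study generator. The
#' defaults define the reference study conditions: a ~390 Mb four-chromosome
#' genome at a uniform 1 cM/Mb map, 4000 variant sites, a 20-population
#' allele-frequency panel with a 30% rare share, 12 genes per chromosome,
#' the two-family pedigree of [acl_study_pedigree()], a pathogenic plan
#' planting candidate variants in 29 Family A genes and 18 Family B genes of
#' which 3 are common to both, and error-free predictors (sensitivity and
#' specificity 1; predictor noise is a dial for recovery experiments, not
#' part of the default fixture).
#'
#' @param seed integer master seed; every stage derives a named substream
#'   from it, so identical configs give byte-identical outputs.
#' @param chrom_lengths_bp named vector of chromosome lengths.
#' @param cm_per_mb uniform recombination rate (centimorgan per megabase).
#' @param n_variants total variant sites (each gene is guaranteed >= 1).
#' @param n_populations number of panel populations.
#' @param pop_labels population labels (first two default to AFR/EUR-style
#'   names; the first population is the designated rare population).
#' @param rare_fraction fraction of variants made rare (MAF <= `rare_max`)
#'   in the designated population.
#' @param rare_max MAF bound defining "rare" for the panel (default 0.05).
#' @param pop_sd between-population frequency jitter (s.d. around the base
#'   frequency).
#' @param divergence_prob probability that a population's frequency is
#'   redrawn independently (creates rs970547-style AFR/EUR divergence).
#' @param n_genes_per_chrom gene models laid down per chromosome.
#' @param gene_length_bp two-vector range of gene lengths.
#' @param pedigree pedigree table (default [acl_study_pedigree()]).
#' @param founder_pops named vector family id -> panel population whose
#'   frequencies founder haplotypes are drawn from; default: the second
#'   population (EUR-like) for every family.
#' @param pathogenic_plan data.frame with columns `gene`, `n_variants`,
#'   `families` (comma-separated family ids), `pattern` (`"hom"` or
#'   `"het"`); `NULL` for the default 29/18/3 plan over the simulated gene
#'   symbols.
#' @param predictor_sensitivity,predictor_specificity per-tool
#'   probabilities in `[0, 1]`, recycled to the tool count.
#' @param tools ordered predictor names (default [default_tools()]).
#' @param a_tools subset of tools that emit `A`
#'   (disease_causing_automatic-style) instead of `D` when calling a true
#'   variant damaging.
#' @param genotype_error symmetric allele-flip rate for stress tests
#'   (default 0, off).
#' @param drop_samples sample ids simulated but excluded from the written
#'   VCF (default `"B_father"`, the unrecruited Family B father).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths_bp = c(chr1 = 120e6, chr2 = 100e6,
                                            chr3 = 90e6, chr4 = 80e6),
                       cm_per_mb = 1.0,
                       n_variants = 4000L,
                       n_populations = 20L,
                       pop_labels = NULL,
                       rare_fraction = 0.3,
                       rare_max = 0.05,
                       pop_sd = 0.05,
                       divergence_prob = 0.05,
                       n_genes_per_chrom = 12L,
                       gene_length_bp = c(2e4, 2e5),
                       pedigree = acl_study_pedigree(),
                       founder_pops = NULL,
                       pathogenic_plan = NULL,
                       predictor_sensitivity = 1.0,
                       predictor_specificity = 1.0,
                       tools = default_tools(),
                       a_tools = "MutationTaster",
                       genotype_error = 0,
                       drop_samples = "B_father") {
  # YAML-archived configs deserialize vectors as lists and data frames as
  # column lists; coerce back so archived runs reproduce exactly
  chrom_lengths_bp <- unlist(chrom_lengths_bp)
  if (!is.null(founder_pops)) founder_pops <- unlist(founder_pops)
  if (!is.null(pathogenic_plan) && !is.data.frame(pathogenic_plan)) {
    pathogenic_plan <- as.data.frame(lapply(pathogenic_plan, unlist),
                                     stringsAsFactors = FALSE)
  }
  if (n_populations < 1) stop("need at least one population")
  if (is.null(pop_labels)) {
    pop_labels <- c("AFR", "EUR", sprintf("POP%02d", seq_len(max(n_populations - 2, 0)) + 2))
    pop_labels <- pop_labels[seq_len(n_populations)]
  }
  stopifnot(length(pop_labels) == n_populations)
  probs <- c(rare_fraction, divergence_prob, predictor_sensitivity,
             predictor_specificity, genotype_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (is.null(founder_pops)) {
    fams <- unique(pedigree$family_id)
    founder_pops <- setNames(rep(pop_labels[min(2, n_populations)],
                                 length(fams)), fams)
  }
  cfg <- list(seed = as.integer(seed), chrom_lengths_bp = chrom_lengths_bp,
              cm_per_mb = cm_per_mb, n_variants = as.integer(n_variants),
              n_populations = as.integer(n_populations),
              pop_labels = pop_labels, rare_fraction = rare_fraction,
              rare_max = rare_max, pop_sd = pop_sd,
              divergence_prob = divergence_prob,
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              gene_length_bp = gene_length_bp, pedigree = pedigree,
              founder_pops = founder_pops,
              pathogenic_plan = pathogenic_plan,
              predictor_sensitivity = rep_len(predictor_sensitivity,
                                              length(tools)),
              predictor_specificity = rep_len(predictor_specificity,
                                              length(tools)),
              tools = tools, a_tools = a_tools,
              genotype_error = genotype_error,
              drop_samples = drop_samples)
  class(cfg) <- "sim_config"
  cfg
}

# Named substream so toggling one stage never shifts another's randomness.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + sum(utf8ToInt(stage)) * 31) %% 2147483647)
}

#' The default two-family study pedigree
#'
#' Mirrors the structure of a two-family ACL rupture study: Family A has a
#' father, a mother, a monozygotic twin pair and a brother, with the
#' father, twins and brother affected; Family B has a father (deceased at
#' recruitment — simulated for transmission but dropped from the written
#' genotype set), a mother, a monozygotic twin pair (affected) and a
#' sister. Six affected individuals in total.
#'
#' @return a `pedigree_table`.
#' @export
acl_study_pedigree <- function() {
  ped <- data.frame(
    id = c("A_father", "A_mother", "A_twin1", "A_twin2", "A_brother",
           "B_father", "B_mother", "B_twin3", "B_twin4", "B_sister"),
    family_id = rep(c("FamilyA", "FamilyB"), each = 5),
    father_id = c("0", "0", "A_father", "A_father", "A_father",
                  "0", "0", "B_father", "B_father", "B_father"),
    mother_id = c("0", "0", "A_mother", "A_mother", "A_mother",
                  "0", "0", "B_mother", "B_mother", "B_mother"),
    sex = c("male", "female", "male", "male", "male",
            "male", "female", "male", "male", "female"),
    affected = c(TRUE, FALSE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, TRUE, TRUE, FALSE),
    mz_group = c(NA, NA, "MZ_A", "MZ_A", NA,
                 NA, NA, "MZ_B", "MZ_B", NA),
    stringsAsFactors = FALSE
  )
  ped$founder <- ped$father_id == "0"
  validate_pedigree(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Simulate gene models
#'
#' Lays down `n_genes_per_chrom` non-overlapping gene intervals per
#' chromosome (uniform start within equal-width slots, length uniform in
#' `gene_length_bp`), symbols `GENE001`, `GENE002`, ...
#'
#' @param config a [sim_config()].
#' @return a `gene_models` table.
#' @export
simulate_gene_models <- function(config) {
  set.seed(stage_seed(config$seed, "genes"))
  rows <- list()
  k <- 0L
  for (chrom in names(config$chrom_lengths_bp)) {
    L <- config$chrom_lengths_bp[[chrom]]
    n <- config$n_genes_per_chrom
    slot <- floor(L / n)
    for (i in seq_len(n)) {
      k <- k + 1L
      len <- round(runif(1, config$gene_length_bp[1],
                         min(config$gene_length_bp[2], slot - 1)))
      start <- (i - 1L) * slot + 1L + floor(runif(1, 0, slot - len))
      rows[[k]] <- data.frame(symbol = sprintf("GENE%03d", k), chrom = chrom,
                              start_bp = start, end_bp = start + len - 1L,
                              stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, rows)
  gene_models(g$symbol, g$chrom, g$start_bp, g$end_bp)
}

#' Simulate variant sites
#'
#' Places variant sites uniformly at random along each chromosome
#' (proportional to length) after guaranteeing at least one site inside
#' every gene model. Sites inside a gene are exonic with a sampled
#' consequence; all other sites are intergenic.
#'
#' @param config a [sim_config()].
#' @param genes a `gene_models` table (default: simulated from `config`).
#' @return a [variant_table()] sorted by (chrom, pos).
#' @export
simulate_variant_sites <- function(config, genes = simulate_gene_models(config)) {
  force(genes)   # evaluate before seeding: the default draws its own substream
  set.seed(stage_seed(config$seed, "variants"))
  chroms <- names(config$chrom_lengths_bp)
  lens <- as.numeric(config$chrom_lengths_bp)
  pos <- integer(0); chrom <- character(0)
  # one guaranteed site per gene
  gpos <- floor(runif(nrow(genes), genes$start_bp, genes$end_bp + 1))
  chrom <- genes$chrom; pos <- as.integer(gpos)
  n_rest <- max(config$n_variants - nrow(genes), 0L)
  ci <- sample.int(length(chroms), n_rest, replace = TRUE, prob = lens)
  rpos <- as.integer(floor(runif(n_rest, 1, lens[ci] + 1)))
  chrom <- c(chrom, chroms[ci]); pos <- c(pos, rpos)
  dup <- duplicated(paste(chrom, pos))
  chrom <- chrom[!dup]; pos <- pos[!dup]
  ord <- order(match(chrom, chroms), pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  gr_v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(gr_v, genes_as_granges(genes))
  gene_of <- tapply(genes$symbol[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    paste, collapse = ",")
  genes_field <- rep(NA_character_, length(pos))
  genes_field[as.integer(names(gene_of))] <- unname(gene_of)
  in_gene <- !is.na(genes_field)
  region <- ifelse(in_gene, "exonic", "intergenic")
  csq <- rep(NA_character_, length(pos))
  csq[in_gene] <- sample(c("nonsynonymous", "synonymous", "stopgain",
                           "stoploss"),
                         sum(in_gene), replace = TRUE,
                         prob = c(0.55, 0.35, 0.05, 0.05))
  variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                rsid = sprintf("snp%06d", seq_along(pos)),
                genes = genes_field, region = region, consequence = csq)
}

#' Default pathogenic plan over simulated gene symbols
#'
#' Plants one homozygous-in-all-affected candidate variant in 29 Family A
#' genes and 18 Family B genes, 3 of which are common to both families —
#' the discovery scale of the two-family study the generator emulates.
#'
#' @param genes a `gene_models` table with >= 44 distinct symbols.
#' @return data.frame with columns `gene`, `n_variants`, `families`,
#'   `pattern`.
#' @export
default_pathogenic_plan <- function(genes) {
  syms <- unique(genes$symbol)
  if (length(syms) < 44) stop("default plan needs >= 44 gene symbols")
  shared <- syms[1:3]
  a_only <- syms[4:29]          # 26 genes -> 29 total for Family A
  b_only <- syms[30:44]         # 15 genes -> 18 total for Family B
  data.frame(
    gene = c(shared, a_only, b_only),
    n_variants = 1L,
    families = c(rep("FamilyA,FamilyB", length(shared)),
                 rep("FamilyA", length(a_only)),
                 rep("FamilyB", length(b_only))),
    pattern = "hom", stringsAsFactors = FALSE)
}
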