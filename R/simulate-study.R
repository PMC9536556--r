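#' Simulate a complete two-family study with ground truth
#'
#' Orchestrates the generator end to end: gene models, variant sites, the
#' multi-population frequency panel, the pedigree gene drop, pathogenic
#' planting (the default plan plants 29 Family A / 18 Family B candidate
#' genes with 3 in common), the predictor status matrix — and optionally
#' writes the full fixture bundle (VCF, PED, prediction TSV, frequency TSV,
#' gene BED, truth JSON) to a directory. Planted variant sites are forced
#' rare (frequency below 0.005) in the designated rare population, the
#' panel's stand-in for the novel-rare character of true family candidate
#' variants. Identical configs produce byte-identical bundles.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory for the fixture bundle.
#' @return list with `config`, `pedigree`, `genes`, `variants`, `panel`,
#'   `genotypes`, `profiles`, `truth` and (when written) `paths`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  genes <- simulate_gene_models(config)
  variants <- simulate_variant_sites(config, genes)
  panel <- simulate_frequency_panel(config, variants)
  ped <- config$pedigree
  plan <- config$pathogenic_plan
  if (is.null(plan)) plan <- default_pathogenic_plan(genes)
  # pin one site per planned variant and make it rare in every population
  # BEFORE founder haplotypes are drawn, so only the planted carrier
  # pattern — never a chance founder allele — carries the variant
  if (nrow(plan) && is.null(plan$site_key)) {
    set.seed(stage_seed(config$seed, "plant_sites"))
    plan <- plan[rep(seq_len(nrow(plan)), plan$n_variants), , drop = FALSE]
    plan$n_variants <- 1L
    used <- integer(0)
    plan$site_key <- vapply(seq_len(nrow(plan)), function(r) {
      gi <- which(genes$symbol == plan$gene[r])[1]
      if (is.na(gi)) stop("planned gene not in the gene model: ", plan$gene[r])
      sites <- setdiff(assign_snps_to_gene(variants, genes[gi, ], 0L), used)
      if (!length(sites)) stop("gene ", plan$gene[r], " has no free site")
      s <- sites[sample.int(length(sites), 1)]
      used <<- c(used, s)
      variants$key[s]
    }, "")
    panel[plan$site_key, ] <- matrix(
      runif(nrow(plan) * ncol(panel), 0, 0.005), nrow = nrow(plan))
  }
  gd <- gene_drop(ped, panel, config, variants)
  pl <- plant_pathogenic_variants(gd$genotypes, gd$truth, variants, genes,
                                  ped, plan,
                                  seed = stage_seed(config$seed, "plant"))
  profiles <- simulate_predictions(pl$variants, pl$truth, config)

  out <- list(config = config, pedigree = ped, genes = genes,
              variants = pl$variants, panel = panel,
              genotypes = pl$genotypes, profiles = profiles,
              truth = pl$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    keep <- setdiff(colnames(pl$genotypes), config$drop_samples)
    geno_out <- pl$genotypes[, keep, drop = FALSE]
    haps <- attr(pl$genotypes, "haplotypes")
    attr(geno_out, "haplotypes") <- lapply(haps, function(h)
      h[, keep, drop = FALSE])
    write_vcf(pl$variants, geno_out, p("study.vcf"))
    write_pedigree(ped, p("study.ped"))
    write_prediction_table(profiles, p("predictions.tsv"))
    write_frequency_table(panel, p("frequencies.tsv"))
    write_gene_bed(genes, p("genes.bed"))
    jsonlite::write_json(
      list(true_deleterious = pl$truth$true_deleterious,
           planted = pl$truth$planted,
           true_ibd = pl$truth$true_ibd),
      p("truth.json"), dataframe = "columns", digits = NA)
    out$paths <- c(vcf = p("study.vcf"), ped = p("study.ped"),
                   predictions = p("predictions.tsv"),
                   frequencies = p("frequencies.tsv"),
                   genes = p("genes.bed"), truth = p("truth.json"))
  }
  out
}
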