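test_that("frequency panel respects the rare fraction by construction", {
  cfg <- sim_config(seed = 5, n_variants = 500, n_genes_per_chrom = 2,
                    rare_fraction = 1.0, pathogenic_plan = empty_plan())
  v <- simulate_variant_sites(cfg)
  panel <- simulate_frequency_panel(cfg, v)
  maf_first <- pmin(panel[, 1], 1 - panel[, 1])
  expect_true(all(maf_first <= 0.05))
  expect_error(sim_config(n_populations = 0), "population")
})

test_that("frequency panel is deterministic under the seed", {
  cfg <- sim_config(seed = 9, n_variants = 300, n_genes_per_chrom = 2,
                    n_populations = 2, pathogenic_plan = empty_plan())
  v <- simulate_variant_sites(cfg)
  expect_identical(simulate_frequency_panel(cfg, v),
                   simulate_frequency_panel(cfg, v))
})

test_that("observed rare share matches the binomial sampling oracle", {
  cfg <- sim_config(seed = 17, n_variants = 10000, n_genes_per_chrom = 2,
                    rare_fraction = 0.3, pathogenic_plan = empty_plan())
  v <- simulate_variant_sites(cfg)
  panel <- simulate_frequency_panel(cfg, v)
  n <- nrow(panel)
  observed <- mean(attr(panel, "rare"))
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(observed - 0.3), 3 * se)
  # and the designated population really is rare at those variants
  rare <- attr(panel, "rare")
  expect_true(all(pmin(panel[rare, 1], 1 - panel[rare, 1]) <= 0.05))
})

test_that("monozygotic twins get identical genomes and full-length true IBD", {
  st <- default_study()
  g <- st$genotypes
  expect_identical(g[, "A_twin1"], setNames(g[, "A_twin2"],
                                            rownames(g)))
  tw <- st$truth$true_ibd
  tw <- tw[tw$id1 == "A_twin1" & tw$id2 == "A_twin2", ]
  lens <- st$config$chrom_lengths_bp
  expect_setequal(tw$chrom, names(lens))
  expect_true(all(tw$start_bp == 1L))
  expect_equal(tw$end_bp, unname(as.integer(lens[tw$chrom])))
})

test_that("children are Mendelian-consistent with both parents", {
  st <- default_study()
  g <- st$genotypes
  ped <- st$pedigree
  kids <- ped[ped$father_id != "0", ]
  for (i in seq_len(nrow(kids))) {
    gc <- g[, kids$id[i]]
    gf <- g[, kids$father_id[i]]
    gm <- g[, kids$mother_id[i]]
    # a child shares >= 1 allele with each parent at every site
    expect_false(any((gc == 2 & (gf == 0 | gm == 0)) |
                       (gc == 0 & (gf == 2 | gm == 2)), na.rm = TRUE),
                 info = kids$id[i])
  }
})

test_that("sib-pair IBD>=1 genome fraction matches the analytic 0.75", {
  # 35 chromosome-Morgans; fraction measured on the ground-truth tracks
  ped <- nuclear_pedigree(2)
  lens <- setNames(rep(350e6, 10), paste0("c", 1:10))
  fr <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = i, chrom_lengths_bp = lens, n_variants = 30,
                      n_genes_per_chrom = 1, n_populations = 2,
                      pedigree = ped, pathogenic_plan = empty_plan())
    v <- simulate_variant_sites(cfg)
    p <- simulate_frequency_panel(cfg, v)
    gd <- gene_drop(ped, p, cfg, v)
    ti <- gd$truth$true_ibd
    ti <- ti[ti$id1 == "Fam_kid1" & ti$id2 == "Fam_kid2", ]
    sum(ti$end_bp - ti$start_bp + 1) / sum(lens)
  }, 0)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.75), 3 * se)
})

test_that("alleles are conserved: sites in true IBD segments share state", {
  st <- default_study()
  g <- st$genotypes
  v <- st$variants
  ti <- st$truth$true_ibd
  set.seed(1)
  for (k in sample.int(nrow(ti), 25)) {
    sel <- v$chrom == ti$chrom[k] & v$pos >= ti$start_bp[k] &
      v$pos <= ti$end_bp[k]
    g1 <- g[sel, ti$id1[k]]
    g2 <- g[sel, ti$id2[k]]
    # IBD1+ implies >= 1 allele identical by state: never opposite homozygotes
    expect_false(any((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)))
  }
})

test_that("founder allele frequencies track the panel", {
  # many founders: observed founder AF ~ panel AF
  n_f <- 60
  ped <- data.frame(id = paste0("f", 1:n_f), family_id = "F",
                    father_id = "0", mother_id = "0", sex = "male",
                    affected = FALSE, mz_group = NA_character_,
                    founder = TRUE, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 3, chrom_lengths_bp = c(c1 = 10e6),
                    n_variants = 400, n_genes_per_chrom = 1,
                    n_populations = 2, pedigree = ped,
                    pathogenic_plan = empty_plan())
  v <- simulate_variant_sites(cfg)
  p <- simulate_frequency_panel(cfg, v)
  gd <- gene_drop(ped, p, cfg, v)
  obs <- rowMeans(gd$genotypes) / 2
  exp_af <- p[rownames(gd$genotypes), "EUR"]
  # binomial error over 2 * n_f draws per site, averaged across sites
  expect_lt(mean(abs(obs - exp_af)), 3 * mean(sqrt(exp_af * (1 - exp_af) /
                                                     (2 * n_f))))
})

test_that("one known parent is rejected", {
  ped <- nuclear_pedigree(1)
  ped$mother_id[3] <- "0"
  cfg <- sim_config(seed = 1, chrom_lengths_bp = c(c1 = 1e6),
                    n_variants = 20, n_genes_per_chrom = 1,
                    n_populations = 2, pedigree = ped,
                    pathogenic_plan = empty_plan())
  v <- simulate_variant_sites(cfg)
  p <- simulate_frequency_panel(cfg, v)
  expect_error(gene_drop(ped, p, cfg, v), "exactly one known parent")
})

test_that("planting 3 genes yields truth of size 3, affected homozygous", {
  st <- default_study()
  shared <- st$truth$planted[st$truth$planted$families == "FamilyA,FamilyB", ]
  expect_equal(nrow(shared), 3L)
  aff <- st$pedigree$id[st$pedigree$affected]
  for (k in shared$key) {
    expect_true(all(st$genotypes[k, aff] == 2L))
  }
  # unaffected members stay het-or-ref
  unaff <- st$pedigree$id[!st$pedigree$affected]
  expect_true(all(st$genotypes[shared$key, unaff] <= 1L))
})

test_that("empty plan changes nothing and yields empty truth", {
  cfg <- sim_config(seed = 2, chrom_lengths_bp = c(c1 = 5e6),
                    n_variants = 100, n_genes_per_chrom = 2,
                    n_populations = 2, pathogenic_plan = empty_plan())
  st <- simulate_study(cfg)
  expect_length(st$truth$true_deleterious, 0L)
  cfg2 <- sim_config(seed = 2, chrom_lengths_bp = c(c1 = 5e6),
                     n_variants = 100, n_genes_per_chrom = 2,
                     n_populations = 2, pathogenic_plan = empty_plan())
  v <- simulate_variant_sites(cfg2)
  p <- simulate_frequency_panel(cfg2, v)
  gd <- gene_drop(cfg2$pedigree, p, cfg2, v)
  expect_identical(unclass(st$genotypes)[, ], unclass(gd$genotypes)[, ])
})

test_that("Mendelian-impossible carrier patterns error, never adjust", {
  st <- default_study()
  genes <- st$genes
  plan <- data.frame(gene = genes$symbol[1], n_variants = 1L,
                     families = "FamilyB", pattern = "hom",
                     stringsAsFactors = FALSE)
  # both Family B parents are unaffected; forcing them to 0/0 makes the
  # twins' homozygous-alt genotype impossible
  expect_error(
    plant_pathogenic_variants(st$genotypes, st$truth, st$variants, genes,
                              st$pedigree, plan, unaffected = "ref"),
    "Mendelian-impossible")
})

test_that("perfect predictors vote 21-0; noisy retention matches the binomial tail", {
  st <- default_study()
  votes <- rowSums(st$profiles %in% c("D", "A") |>
                     matrix(nrow = nrow(st$profiles)))
  is_true <- rownames(st$profiles) %in% st$truth$true_deleterious
  expect_true(all(votes[is_true] == 21))
  expect_true(all(votes[!is_true] == 0))

  # sensitivity 0.9: retention of true variants ~ P(Bin(21, 0.9) >= 17)
  n_true <- 4000
  cfg <- sim_config(seed = 31, predictor_sensitivity = 0.9,
                    predictor_specificity = 0.95)
  v <- variant_table(chrom = rep("c1", n_true + 2000),
                     pos = seq_len(n_true + 2000),
                     ref = rep("A", n_true + 2000),
                     alt = rep("G", n_true + 2000), region = "intergenic")
  truth <- list(true_deleterious = v$key[seq_len(n_true)])
  prof <- simulate_predictions(v, truth, cfg)
  keep <- casting_vote(prof)
  p_tail <- 1 - pbinom(16, 21, 0.9)
  se <- sqrt(p_tail * (1 - p_tail) / n_true)
  expect_lt(abs(mean(keep[seq_len(n_true)]) - p_tail), 3 * se)

  # specificity 0.95: false retention ~ P(Bin(21, 0.05) >= 17) ~ 0
  p_false <- 1 - pbinom(16, 21, 0.05)
  n_null <- 2000
  se_f <- sqrt(max(p_false * (1 - p_false) / n_null, 1e-12))
  expect_lte(abs(mean(keep[n_true + seq_len(n_null)]) - p_false),
             max(3 * se_f, 1 / n_null))
})

test_that("identical configs give byte-identical fixture bundles", {
  cfg <- function() sim_config(seed = 8, chrom_lengths_bp = c(c1 = 5e6),
                               n_variants = 150, n_genes_per_chrom = 2,
                               n_populations = 3,
                               pathogenic_plan = empty_plan())
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  simulate_study(cfg(), out_dir = d1)
  simulate_study(cfg(), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})
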