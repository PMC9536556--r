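test_that("LOD filtering keeps all 11 worked-example records at 3.0", {
  seg <- acl_example_segments()
  expect_equal(nrow(seg), 11L)
  expect_equal(min(seg$lod), 3.31)
  expect_equal(nrow(filter_segments(seg, min_lod = 3.0)), 11L)
  expect_equal(nrow(filter_segments(seg, min_lod = Inf)), 0L)
  # closed bound: a segment at exactly the threshold is retained
  expect_equal(nrow(filter_segments(seg, min_lod = 3.31)), 11L)
  expect_equal(nrow(filter_segments(seg, min_lod = 3.32)), 10L)
  # missing genetic length passes the length test
  seg$length_cm[1] <- NA
  expect_equal(nrow(filter_segments(seg, min_cm = 1.0)), 11L)
})

test_that("segment-gene annotation matches the printed LINC01250 overlap", {
  genes <- acl_example_genes()
  seg <- acl_example_segments()
  twinA <- seg[seg$chrom == "chr2" & seg$id1 == "A_twin1" &
                 seg$id2 == "A_twin2", ]
  expect_equal(annotate_segment_genes(twinA, genes), "LINC01250")
  # no genes on the segment's chromosome -> empty
  none <- ibd_segments("x", "y", "chr22", 1, 1000, 5)
  expect_length(annotate_segment_genes(none, genes), 0L)
})

test_that("annotation equals the brute-force interval oracle", {
  set.seed(7)
  genes <- gene_models(symbol = sprintf("G%03d", 1:80),
                       chrom = sample(c("c1", "c2", "c3"), 80, replace = TRUE),
                       start_bp = s <- sample.int(1e6, 80),
                       end_bp = s + sample.int(5e4, 80))
  for (i in 1:40) {
    st <- sample.int(1e6, 1)
    seg <- ibd_segments("a", "b", sample(c("c1", "c2", "c3"), 1),
                        st, st + sample.int(2e5, 1), 4)
    expect_equal(annotate_segment_genes(seg, genes),
                 oracle_overlap_genes(seg, genes))
    expect_equal(annotate_segment_genes(seg, genes, rule = "full_containment"),
                 oracle_overlap_genes(seg, genes, containment = TRUE))
  }
})

test_that("sharing table reproduces the 20-gene mother-brother record", {
  tab <- pairwise_sharing_table(acl_example_segments(),
                                acl_example_pedigree(),
                                acl_example_genes())
  mb <- tab[tab$id1 == "A_mother" & tab$id2 == "A_brother", ]
  expect_equal(nrow(mb), 1L)
  expect_false(mb$affected1)
  expect_true(mb$affected2)
  expect_equal(mb$n_genes, 20L)
  expect_setequal(
    split_genes_test(mb$genes),
    c("CDC42EP5", "KIR3DX1", "LAIR1", "LAIR2", "LENG8", "LENG8-AS1",
      "LENG9", "LILRA4", "LILRA5", "LILRA6", "LILRB2", "LILRB3", "LILRB5",
      "MBOAT7", "MIR4752", "RNU6-1307P", "RPS9", "TSEN34", "TTYH1",
      "VN1R104P"))
  # deterministic (family, chrom, start) ordering
  expect_false(is.unsorted(order(tab$family, tab$chrom, tab$start_bp)))
  # gene counts equal the brute-force oracle for every record
  genes <- acl_example_genes()
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n_genes[i],
                 length(oracle_overlap_genes(
                   list(chrom = tab$chrom[i], start_bp = tab$start_bp[i],
                        end_bp = tab$end_bp[i]), genes)))
  }
})

test_that("empty segment input gives an empty table; unknown ids error", {
  seg0 <- acl_example_segments()[0, ]
  expect_equal(nrow(pairwise_sharing_table(seg0, acl_example_pedigree(),
                                           acl_example_genes())), 0L)
  seg <- acl_example_segments()
  seg$id1[1] <- "nobody"
  expect_error(pairwise_sharing_table(seg, acl_example_pedigree(),
                                      acl_example_genes()), "nobody")
})

test_that("cross-family commons match the printed twin-pair overlaps", {
  tab <- pairwise_sharing_table(acl_example_segments(),
                                acl_example_pedigree(),
                                acl_example_genes())
  res <- cross_family_common(tab, affected_only = TRUE)
  chr2 <- res$intervals[res$intervals$chrom == "chr2", ]
  # Family A twin segment x Family B twin segment: the narrower B interval
  expect_true(any(chr2$start_bp == 3009692 & chr2$end_bp == 3047881 &
                    chr2$genes == "LINC01250"))
  chr15 <- res$intervals[res$intervals$chrom == "chr15", ]
  expect_equal(nrow(chr15), 1L)
  expect_setequal(split_genes_test(chr15$genes),
                  c("GOLGA6L22", "GOLGA8EP", "HERC2P2", "HERC2P7",
                    "RN7SL545P", "SPATA31E3P"))
  expect_equal(chr15$n_genes, 6L)
  expect_true(all(c("LINC01250", "GOLGA6L22") %in% res$genes))
  # the unaffected-mother KIR3DX1 sharing only appears without the
  # affected-only restriction
  expect_false("KIR3DX1" %in% res$genes)
  res_all <- cross_family_common(tab, affected_only = FALSE)
  kir <- res_all$intervals[res_all$intervals$genes == "KIR3DX1", ]
  expect_gte(nrow(kir), 1L)
})

test_that("cross-family intersections obey interval algebra", {
  tab <- pairwise_sharing_table(acl_example_segments(),
                                acl_example_pedigree(),
                                acl_example_genes())
  res <- cross_family_common(tab, affected_only = FALSE)
  for (i in seq_len(nrow(res$intervals))) {
    iv <- res$intervals[i, ]
    parents <- tab[tab$chrom == iv$chrom &
                     tab$start_bp <= iv$start_bp & tab$end_bp >= iv$end_bp, ]
    # contained in >= 2 records from different families
    expect_gte(length(unique(parents$family)), 2L)
  }
  # swapping the pair labels changes nothing
  seg <- acl_example_segments()
  swapped <- seg
  swapped$id1 <- seg$id2
  swapped$id2 <- seg$id1
  tab2 <- pairwise_sharing_table(swapped, acl_example_pedigree(),
                                 acl_example_genes())
  res2 <- cross_family_common(tab2, affected_only = FALSE)
  expect_setequal(res2$genes, res$genes)
  expect_equal(res2$intervals[c("chrom", "start_bp", "end_bp")],
               res$intervals[c("chrom", "start_bp", "end_bp")])
})

test_that("families on disjoint chromosomes share nothing", {
  seg <- ibd_segments(c("A_twin1", "B_twin3"), c("A_twin2", "B_twin4"),
                      c("chr1", "chr3"), c(100, 100), c(2000, 2000),
                      c(5, 5))
  tab <- pairwise_sharing_table(seg, acl_example_pedigree(),
                                acl_example_genes())
  res <- cross_family_common(tab)
  expect_equal(nrow(res$intervals), 0L)
  expect_length(res$genes, 0L)
})

test_that("detector covers MZ twin genomes and respects max_ibs0 soundness", {
  cfg <- sim_config(seed = 21, chrom_lengths_bp = c(c1 = 40e6, c2 = 40e6),
                    n_variants = 3000, n_genes_per_chrom = 2,
                    pathogenic_plan = empty_plan())
  st <- simulate_study(cfg)
  det <- detect_ibd_segments(st$variants, st$genotypes, st$panel,
                             population = "EUR")
  mz <- det[det$id1 == "A_twin1" & det$id2 == "A_twin2", ]
  expect_gte(sum(mz$end_bp - mz$start_bp + 1) / 80e6, 0.99)
  # soundness: no detected segment contains > max_ibs0 opposite homozygotes
  for (i in seq_len(nrow(det))) {
    sel <- st$variants$chrom == det$chrom[i] &
      st$variants$pos >= det$start_bp[i] & st$variants$pos <= det$end_bp[i]
    g1 <- st$genotypes[sel, det$id1[i]]
    g2 <- st$genotypes[sel, det$id2[i]]
    expect_lte(sum((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)), 0L)
  }
  # symmetry: results do not depend on sample order
  det_rev <- detect_ibd_segments(st$variants,
                                 st$genotypes[, rev(colnames(st$genotypes))],
                                 st$panel, population = "EUR")
  key <- function(d) sort(paste(pmin(d$id1, d$id2), pmax(d$id1, d$id2),
                                d$chrom, d$start_bp, d$end_bp))
  expect_equal(key(det_rev), key(det))
})

test_that("all-missing sample pairs are skipped with a warning", {
  cfg <- sim_config(seed = 22, chrom_lengths_bp = c(c1 = 5e6),
                    n_variants = 100, n_genes_per_chrom = 1,
                    n_populations = 2, pathogenic_plan = empty_plan())
  st <- simulate_study(cfg)
  g <- st$genotypes[, c("A_twin1", "A_brother")]
  g[, "A_brother"] <- NA_integer_
  expect_warning(
    detect_ibd_segments(st$variants, g, st$panel, population = "EUR"),
    "skipped")
})
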