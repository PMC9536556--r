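test_that("casting vote retains at >= 17 qualifying statuses of 21", {
  expect_true(casting_vote(rep("D", 21)))
  # 16 qualifying votes miss the 17 threshold
  expect_false(casting_vote(c(rep("D", 16), rep("T", 5))))
  expect_true(casting_vote(c(rep("D", 16), "A", rep("T", 4))))
  # U never qualifies and the denominator stays at the tool count
  expect_false(casting_vote(c(rep("D", 16), rep("U", 5))))
  expect_error(casting_vote(rep("D", 10), min_votes = 17), "tool count")
})

test_that("casting vote equals a brute-force count oracle on random profiles", {
  set.seed(123)
  statuses <- c("D", "A", "T", "U")
  profiles <- matrix(sample(statuses, 2000 * 21, replace = TRUE,
                            prob = c(0.5, 0.1, 0.3, 0.1)),
                     nrow = 2000)
  got <- casting_vote(profiles)
  oracle <- apply(profiles, 1, function(p) {
    n <- 0L
    for (s in p) if (s == "D" || s == "A") n <- n + 1L
    n >= 17L
  })
  expect_equal(unname(got), oracle)
})

test_that("vote is monotone in statuses and in the threshold", {
  set.seed(99)
  for (rep in 1:50) {
    prof <- sample(c("D", "A", "T", "U"), 21, replace = TRUE)
    i <- which(!prof %in% c("D", "A"))
    if (length(i)) {
      upgraded <- prof
      upgraded[i[1]] <- "D"
      # adding a qualifying status never flips retained -> dropped
      expect_gte(casting_vote(upgraded) - casting_vote(prof), 0)
    }
    # raising min_votes never grows the retained set
    kept <- vapply(0:21, function(m) casting_vote(prof, min_votes = m), TRUE)
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("rarity filter reproduces the candidate-variant frequency logic", {
  ex <- acl_example_candidates()
  key <- ex$variants$key[ex$variants$rsid == "rs970547"]
  # AFR 0.0026 / EUR 0.73: rare in AFR alone
  expect_true(filter_rare(key, ex$panel, max_af = 0.01, scope = "AFR",
                          scope_mode = "all")[[1]])
  expect_false(filter_rare(key, ex$panel, max_af = 0.01,
                           scope = c("AFR", "EUR"),
                           scope_mode = "all")[[1]])
  expect_true(filter_rare(key, ex$panel, max_af = 0.01,
                          scope = c("AFR", "EUR"),
                          scope_mode = "any")[[1]])
  # max_af 1 passes everything
  expect_true(all(filter_rare(ex$variants$key, ex$panel, max_af = 1)))
  # absent variants count as rare with a tally
  res <- filter_rare("chrX:1:A:G", ex$panel, max_af = 0.01)
  expect_true(res[[1]])
  expect_equal(attr(res, "n_absent"), 1L)
  expect_error(filter_rare(key, ex$panel, scope = "MARS"), "MARS")
})

test_that("consequence filter keeps protein-altering exonic classes only", {
  v <- variant_table(chrom = c("c1", "c1", "c1", "c1"), pos = 1:4,
                     ref = c("A", "A", "A", "A"), alt = c("G", "G", "G", "G"),
                     region = c("exonic", "intronic", "exonic", "exonic"),
                     consequence = c("nonsynonymous", NA, "synonymous",
                                     "stopgain"))
  expect_equal(unname(filter_consequence(v)), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("carrier filter enforces the affected genotype pattern strictly", {
  ped <- nuclear_pedigree(3, affected_kids = c(TRUE, TRUE, FALSE))
  g <- matrix(c(2L, 2L, 0L,   # v1: both affected hom
                2L, 1L, 0L,   # v2: one affected het
                1L, 1L, 2L,   # v3: affected carry, unaffected hom
                2L, NA, 0L),  # v4: missing genotype fails
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("v", 1:4),
                              c("Fam_kid1", "Fam_kid2", "Fam_kid3")))
  hom <- family_carrier_filter(g, ped, "Fam", "all_affected_homozygous")
  expect_equal(unname(hom), c(TRUE, FALSE, FALSE, FALSE))
  carry <- family_carrier_filter(g, ped, "Fam", "all_affected_carry")
  expect_equal(unname(carry), c(TRUE, TRUE, TRUE, FALSE))
  ped0 <- ped
  ped0$affected <- FALSE
  expect_error(family_carrier_filter(g, ped0, "Fam"), "no genotyped affected")
})

test_that("family prioritization recovers exactly the planted truth", {
  st <- default_study()
  repA <- prioritize_family("FamilyA", st$variants, st$genotypes,
                            st$profiles, st$panel, st$pedigree,
                            carrier_mode = "all_affected_homozygous")
  truthA <- st$truth$planted[grepl("FamilyA", st$truth$planted$families), ]
  expect_setequal(repA$variants$key, truthA$key)
  expect_setequal(repA$genes, unique(truthA$gene))
  expect_equal(length(repA$genes), 29L)
  expect_true(all(repA$variants$qualifying_votes == 21L))
  # genes ordered by chromosome then first supporting position
  first_pos <- vapply(repA$gene_support, function(k) {
    i <- match(k[1], st$variants$key)
    st$variants$pos[i] + 1e9 * match(st$variants$chrom[i],
                                     names(st$config$chrom_lengths_bp))
  }, 0)
  expect_false(is.unsorted(first_pos))
})

test_that("no qualifying variants yields a valid empty report", {
  st <- default_study()
  rep0 <- prioritize_family("FamilyA", st$variants, st$genotypes,
                            st$profiles, st$panel, st$pedigree,
                            min_votes = 21L, max_af = 1e-9)
  expect_equal(nrow(rep0$variants), 0L)
  expect_length(rep0$genes, 0L)
})

test_that("lowering the vote threshold only grows the retained set", {
  st <- default_study()
  prev <- character(0)
  for (m in c(21L, 19L, 17L, 10L, 0L)) {
    r <- prioritize_family("FamilyA", st$variants, st$genotypes,
                           st$profiles, st$panel, st$pedigree,
                           min_votes = m,
                           carrier_mode = "all_affected_homozygous")
    expect_true(all(prev %in% r$variants$key), info = paste("min_votes", m))
    prev <- r$variants$key
  }
})

test_that("per-variant predicates commute", {
  st <- default_study()
  keys <- st$variants$key
  prof <- st$profiles[keys, ]
  a <- filter_rare(keys, st$panel)
  b <- filter_consequence(st$variants)
  c_ <- casting_vote(prof)
  d <- family_carrier_filter(st$genotypes, st$pedigree, "FamilyA",
                             "all_affected_homozygous")[keys]
  orders <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))
  preds <- list(a, b, c_, d)
  ref <- Reduce(`&`, preds)
  for (o in orders) {
    expect_equal(unname(Reduce(`&`, preds[o])), unname(ref))
  }
})

test_that("cross-family intersection finds the genes common to all reports", {
  # printed-scale worked example: 29- and 18-gene lists sharing 3 genes
  shared <- c("COL12A1", "CATSPER2", "KCNJ12")
  listA <- c(shared, "COL11A1", sprintf("A%02d", 1:25))
  listB <- c(shared, sprintf("B%02d", 1:15))
  mk <- function(fam, genes) {
    structure(list(family = fam, variants = NULL, genes = genes,
                   gene_support = setNames(as.list(genes), genes)),
              class = "candidate_report")
  }
  res <- intersect_families(list(mk("FamilyA", listA), mk("FamilyB", listB)))
  expect_setequal(res$shared, shared)
  res_rev <- intersect_families(list(mk("FamilyB", listB), mk("FamilyA", listA)))
  expect_setequal(res_rev$shared, shared)
  expect_equal(nrow(res$union), length(union(listA, listB)))
  expect_equal(sum(res$union$FamilyA & res$union$FamilyB), 3L)

  expect_equal(intersect_families(list(mk("A", listA), mk("B", listA)))$shared,
               listA)
  expect_length(intersect_families(list(mk("A", c("X")), mk("B", c("Y"))))$shared,
                0L)
  expect_error(intersect_families(list(mk("A", listA))), "at least 2")
})
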