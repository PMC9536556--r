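#' Casting-vote deleteriousness consensus
#'
#' The consensus rule retains a variant only if at least `min_votes` of the
#' configured predictors call it damaging: statuses `D` (deleterious /
#' probably damaging / disease_causing) or `A` (disease_causing_automatic)
#' qualify; `T` and `U` never do, and the denominator is always the
#' configured tool count (missing predictors weaken, never shrink, the
#' vote). Defaults follow the 17-of-21 rule.
#'
#' @param profile character vector of statuses in `D`/`A`/`T`/`U`, one per
#'   configured tool, or a `prediction_profiles` matrix (one row per
#'   variant).
#' @param min_votes minimum number of qualifying statuses (default 17).
#' @param qualifying set of qualifying statuses (default `c("D", "A")`).
#' @return logical: `TRUE` when the variant is retained. For a matrix input,
#'   a named logical vector over variants.
#' @export
casting_vote <- function(profile, min_votes = 17L, qualifying = c("D", "A")) {
  if (is.matrix(profile)) {
    if (min_votes > ncol(profile)) {
      stop("min_votes (", min_votes, ") exceeds the tool count (",
           ncol(profile), ")")
    }
    return(rowSums(matrix(profile %in% qualifying, nrow = nrow(profile),
                          dimnames = dimnames(profile))) >= min_votes)
  }
  if (min_votes > length(profile)) {
    stop("min_votes (", min_votes, ") exceeds the tool count (",
         length(profile), ")")
  }
  sum(profile %in% qualifying) >= min_votes
}

#' Population-rarity filter
#'
#' A variant passes when its alternate-allele frequency is at most `max_af`
#' in the populations of `scope`: under `scope_mode = "any"` (default) one
#' qualifying population suffices; under `"all"` every scoped population
#' must qualify. Variants absent from the panel are treated as frequency 0
#' (novel variants are exactly the interesting case); the number of such
#' variants is attached as attribute `"n_absent"` and logged.
#'
#' @param keys character vector of variant keys.
#' @param panel numeric matrix of alternate-allele frequencies
#'   (variant keys x population labels), as from
#'   [simulate_frequency_panel()] or [read_frequency_table()].
#' @param max_af maximum qualifying frequency (default 0.01).
#' @param scope populations considered (default: all panel columns).
#' @param scope_mode `"any"` or `"all"`.
#' @return named logical vector over `keys` with attribute `"n_absent"`.
#' @export
filter_rare <- function(keys, panel, max_af = 0.01,
                        scope = colnames(panel),
                        scope_mode = c("any", "all")) {
  scope_mode <- match.arg(scope_mode)
  if (!all(scope %in% colnames(panel))) {
    stop("scope population(s) not in panel: ",
         paste(setdiff(scope, colnames(panel)), collapse = ", "))
  }
  af <- matrix(0, nrow = length(keys), ncol = length(scope),
               dimnames = list(keys, scope))
  present <- keys %in% rownames(panel)
  af[present, ] <- panel[keys[present], scope, drop = FALSE]
  ok <- if (scope_mode == "any") {
    rowSums(af <= max_af) >= 1
  } else {
    rowSums(af <= max_af) == length(scope)
  }
  if (any(!present)) {
    .log_msg(sum(!present), " variant(s) absent from the frequency panel; ",
             "treated as frequency 0")
  }
  names(ok) <- keys
  attr(ok, "n_absent") <- sum(!present)
  ok
}

#' Consequence filter
#'
#' Retains exonic variants whose consequence is in the allowed set; by
#' default protein-altering point classes (nonsynonymous, stopgain,
#' stoploss). Everything non-exonic fails.
#'
#' @param variants a [variant_table()].
#' @param allowed allowed consequence values.
#' @return named logical vector over variant keys.
#' @export
filter_consequence <- function(variants,
                               allowed = c("nonsynonymous", "stopgain",
                                           "stoploss")) {
  ok <- variants$region == "exonic" &
    !is.na(variants$consequence) & variants$consequence %in% allowed
  setNames(ok, variants$key)
}

#' Affected-carrier filter within a family
#'
#' Retains variants whose genotype pattern among the family's affected,
#' genotyped members satisfies the carrier mode: `all_affected_carry`
#' (every affected carries >= 1 alternate allele) or
#' `all_affected_homozygous` (every affected is homozygous alternate, the
#' pattern of the shared candidate variants in two-family ACL studies).
#' Missing genotypes fail the test (strict).
#'
#' @param genotypes integer genotype matrix (variant keys x sample ids).
#' @param pedigree a pedigree table; only rows of `family` are used.
#' @param family family id to evaluate.
#' @param mode carrier mode (see above).
#' @return named logical vector over variant keys.
#' @export
family_carrier_filter <- function(genotypes, pedigree, family,
                                  mode = c("all_affected_carry",
                                           "all_affected_homozygous")) {
  mode <- match.arg(mode)
  fam <- pedigree[pedigree$family_id == family, ]
  aff <- intersect(fam$id[fam$affected], colnames(genotypes))
  if (!length(aff)) stop("family ", family, " has no genotyped affected member")
  g <- genotypes[, aff, drop = FALSE]
  thr <- if (mode == "all_affected_carry") 1L else 2L
  ok <- rowSums(!is.na(g) & g >= thr) == length(aff)
  setNames(ok, rownames(genotypes))
}

#' Prioritize candidate variants and genes for one family
#'
#' Applies, in order, the rarity filter, the consequence filter, the
#' casting-vote consensus and the affected-carrier filter (all are
#' per-variant predicates, so the order does not change the result), then
#' reports the genes supported by the retained variants, deduplicated and
#' ordered by chromosome and position of the first supporting variant.
#'
#' @param family family id.
#' @param variants a [variant_table()].
#' @param genotypes genotype matrix over the same variant keys.
#' @param profiles `prediction_profiles` matrix over the same keys.
#' @param panel allele-frequency matrix (keys x populations).
#' @param pedigree pedigree table containing `family`.
#' @param max_af,scope,scope_mode rarity settings (see [filter_rare()]).
#' @param allowed_consequences consequence whitelist
#'   (see [filter_consequence()]).
#' @param min_votes,qualifying vote settings (see [casting_vote()]).
#' @param carrier_mode carrier pattern (see [family_carrier_filter()]).
#' @return object of class `candidate_report`: list with `family`,
#'   `variants` (retained rows of `variants` plus a `qualifying_votes`
#'   column), `genes` (ordered character vector) and `gene_support` (named
#'   list gene -> supporting variant keys).
#' @export
prioritize_family <- function(family, variants, genotypes, profiles, panel,
                              pedigree,
                              max_af = 0.01, scope = colnames(panel),
                              scope_mode = "any",
                              allowed_consequences = c("nonsynonymous",
                                                       "stopgain", "stoploss"),
                              min_votes = 17L, qualifying = c("D", "A"),
                              carrier_mode = "all_affected_carry") {
  keys <- variants$key
  prof <- matrix("U", nrow = length(keys), ncol = ncol(profiles),
                 dimnames = list(keys, colnames(profiles)))
  have <- keys %in% rownames(profiles)
  prof[have, ] <- profiles[keys[have], , drop = FALSE]
  keep <- filter_rare(keys, panel, max_af, scope, scope_mode) &
    filter_consequence(variants, allowed_consequences) &
    casting_vote(prof, min_votes, qualifying) &
    family_carrier_filter(genotypes, pedigree, family, carrier_mode)[keys]
  retained <- variants[keep, , drop = FALSE]
  retained$qualifying_votes <-
    rowSums(matrix(prof[keep, , drop = FALSE] %in% qualifying,
                   nrow = sum(keep)))
  # gene list ordered by (chrom, pos) of first supporting variant
  support <- list()
  ord <- order(retained$chrom, retained$pos)
  for (i in ord) {
    for (g in split_genes(retained$genes[i])) {
      support[[g]] <- c(support[[g]], retained$key[i])
    }
  }
  structure(list(family = family, variants = retained,
                 genes = names(support), gene_support = support),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate gene report for family ", x$family, "\n", sep = "")
  cat("  retained variants: ", nrow(x$variants), "\n", sep = "")
  cat("  genes (", length(x$genes), "): ",
      paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Intersect per-family candidate gene reports
#'
#' Computes the genes present in every family's report (order-insensitive)
#' together with, for each shared gene, the supporting variant keys per
#' family, and a union table flagging per-family membership.
#'
#' @param reports list of two or more `candidate_report` objects.
#' @return list with `shared` (character vector of genes common to all
#'   reports), `support` (named list gene -> named list family ->
#'   supporting keys) and `union` (data.frame gene x per-family logical
#'   membership flags).
#' @export
intersect_families <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 family reports to intersect")
  gene_lists <- lapply(reports, `[[`, "genes")
  fams <- vapply(reports, `[[`, "", "family")
  shared <- Reduce(intersect, gene_lists)
  support <- lapply(setNames(shared, shared), function(g) {
    lapply(setNames(reports, fams), function(r) r$gene_support[[g]])
  })
  all_genes <- unique(unlist(gene_lists))
  membership <- vapply(gene_lists, function(gl) all_genes %in% gl,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(NULL, fams))
  union_tab <- data.frame(gene = all_genes, membership,
                          check.names = FALSE, stringsAsFactors = FALSE)
  list(shared = shared, support = support, union = union_tab)
}
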