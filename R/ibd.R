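#' Filter IBD segments on support and length
#'
#' Keeps segments with `lod >= min_lod` (closed bound: a segment whose LOD
#' equals the threshold is retained) and `length_cm >= min_cm`; a missing
#' genetic length passes the length test. The default `min_lod = 3` sits
#' below the weakest segment typically reported by haplotype-based
#' detectors.
#'
#' @param segments an `ibd_segments` table.
#' @param min_lod minimum LOD score (default 3).
#' @param min_cm minimum genetic length in cM (default 0).
#' @return the retained rows, same class.
#' @export
filter_segments <- function(segments, min_lod = 3.0, min_cm = 0.0) {
  keep <- segments$lod >= min_lod &
    (is.na(segments$length_cm) | segments$length_cm >= min_cm)
  segments[keep, , drop = FALSE]
}

#' Genes overlapping an IBD segment
#'
#' Annotates a segment with the gene models it overlaps, in stable order of
#' gene start. Under `any_overlap` (default) a single shared base pair of
#' the 1-based closed intervals suffices; under `full_containment` the gene
#' must lie entirely inside the segment. Duplicate symbols (two models with
#' the same name) are kept as listed unless `dedup = TRUE`.
#'
#' @param segment one-row `ibd_segments` table (or list with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param genes a `gene_models` table.
#' @param rule `"any_overlap"` or `"full_containment"`.
#' @param dedup collapse duplicate symbols?
#' @return character vector of gene symbols (possibly empty).
#' @export
annotate_segment_genes <- function(segment, genes,
                                   rule = c("any_overlap", "full_containment"),
                                   dedup = FALSE) {
  rule <- match.arg(rule)
  seg_gr <- GenomicRanges::GRanges(
    segment$chrom,
    IRanges::IRanges(segment$start_bp, segment$end_bp))
  # disjoint seqlevels (a segment on a gene-free chromosome) is a valid
  # query, not a condition worth warning about
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    genes_as_granges(genes), seg_gr,
    type = if (rule == "any_overlap") "any" else "within"))
  idx <- S4Vectors::queryHits(hits)
  idx <- idx[order(genes$start_bp[idx], genes$symbol[idx])]
  out <- genes$symbol[idx]
  if (dedup) out <- unique(out)
  out
}

#' Within-family IBD sharing table
#'
#' Builds one record per segment: the sample pair with affected flags from
#' the pedigree, the interval, its LOD and genetic length, and the ordered
#' overlapping gene symbols. Records are sorted by (family, chrom, start).
#'
#' @param segments an `ibd_segments` table (filter first with
#'   [filter_segments()] if desired).
#' @param pedigree pedigree table resolving every sample id.
#' @param genes a `gene_models` table.
#' @param rule,dedup gene-overlap settings (see [annotate_segment_genes()]).
#' @return data.frame of class `sharing_table` with columns `family`, `id1`,
#'   `affected1`, `id2`, `affected2`, `chrom`, `start_bp`, `end_bp`, `lod`,
#'   `length_cm`, `genes` (comma-separated, as listed), `n_genes`.
#' @export
pairwise_sharing_table <- function(segments, pedigree, genes,
                                   rule = "any_overlap", dedup = FALSE) {
  ids <- unique(c(segments$id1, segments$id2))
  unknown <- setdiff(ids, pedigree$id)
  if (length(unknown)) {
    stop("sample id(s) not in pedigree: ", paste(unknown, collapse = ", "))
  }
  lookup <- function(id, col) pedigree[[col]][match(id, pedigree$id)]
  fam1 <- lookup(segments$id1, "family_id")
  fam2 <- lookup(segments$id2, "family_id")
  fam <- ifelse(fam1 == fam2, fam1, paste(pmin(fam1, fam2), pmax(fam1, fam2),
                                          sep = "+"))
  gene_lists <- vapply(seq_len(nrow(segments)), function(i) {
    paste(annotate_segment_genes(segments[i, ], genes, rule, dedup),
          collapse = ",")
  }, "")
  out <- data.frame(
    family = fam,
    id1 = segments$id1, affected1 = lookup(segments$id1, "affected"),
    id2 = segments$id2, affected2 = lookup(segments$id2, "affected"),
    chrom = segments$chrom, start_bp = segments$start_bp,
    end_bp = segments$end_bp, lod = segments$lod,
    length_cm = segments$length_cm,
    genes = gene_lists,
    n_genes = lengths(strsplit(gene_lists, ",", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  out$n_genes[out$genes == ""] <- 0L
  out <- out[order(out$family, out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sharing_table", "data.frame")
  out
}

#' Cross-family common IBD regions and genes
#'
#' For every pair of sharing records from different families on the same
#' chromosome, emits the interval intersection when non-empty together with
#' the gene symbols present in both records' gene lists. With
#' `affected_only = TRUE` (default) only pairs of records in which all four
#' samples are affected contribute. The gene-level summary collects every
#' gene appearing in at least one cross-family intersection.
#'
#' @param records a `sharing_table` covering two or more families.
#' @param affected_only restrict to all-affected record pairs?
#' @return list with `intervals` (data.frame: `family1`, `family2`, `chrom`,
#'   `start_bp`, `end_bp`, `genes`, `n_genes`) and `genes` (character
#'   vector, deduplicated).
#' @export
cross_family_common <- function(records, affected_only = TRUE) {
  res <- list()
  n <- nrow(records)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ri <- records[i, ]; rj <- records[j, ]
      if (ri$family == rj$family || ri$chrom != rj$chrom) next
      if (affected_only &&
          !(ri$affected1 && ri$affected2 && rj$affected1 && rj$affected2)) next
      s <- max(ri$start_bp, rj$start_bp)
      e <- min(ri$end_bp, rj$end_bp)
      if (s > e) next
      common <- intersect(split_genes(ri$genes), split_genes(rj$genes))
      res[[length(res) + 1L]] <- data.frame(
        family1 = min(ri$family, rj$family),
        family2 = max(ri$family, rj$family),
        chrom = ri$chrom, start_bp = s, end_bp = e,
        genes = paste(common, collapse = ","),
        n_genes = length(common), stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    intervals <- data.frame(family1 = character(0), family2 = character(0),
                            chrom = character(0), start_bp = integer(0),
                            end_bp = integer(0), genes = character(0),
                            n_genes = integer(0), stringsAsFactors = FALSE)
    return(list(intervals = intervals, genes = character(0)))
  }
  intervals <- do.call(rbind, res)
  intervals <- intervals[order(intervals$chrom, intervals$start_bp), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  genes <- unique(unlist(lapply(intervals$genes, split_genes)))
  list(intervals = intervals, genes = genes)
}
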