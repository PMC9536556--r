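#' Simple genotype-based IBD segment detector
#'
#' A deliberately simple detector for error-free synthetic genotypes, so
#' that simulated studies can be run end to end without an external
#' haplotype-based tool. It is NOT a replacement for haplotype-HMM
#' detectors (Refined IBD and kin): it works on unphased genotypes, ignores
#' linkage disequilibrium and models no genotyping error beyond a small
#' mixture weight.
#'
#' For each sample pair and chromosome the detector finds maximal runs of
#' consecutive (non-missing) markers containing at most `max_ibs0`
#' opposite-homozygote sites, scores each run
#' `LOD = sum_sites log10 P(g1, g2 | IBD1) / P(g1, g2 | IBD0)` under
#' Hardy-Weinberg with panel allele frequencies, and emits runs with at
#' least `min_markers` markers and `LOD >= min_lod`. No emitted run
#' contains more than `max_ibs0` opposite-homozygote sites by construction.
#'
#' Because runs are by construction free of opposite-homozygote sites, a
#' raw within-run LOD is selection-biased upward (the terminating evidence
#' is never counted). The run score therefore also includes the two
#' flanking opposite-homozygote sites where they exist (each contributes
#' about `log10(err)` under the error mixture), which restores conservative
#' behaviour for unrelated pairs while leaving long true segments, whose
#' interior LOD dominates, essentially untouched. Frequencies should come
#' from the population the samples derive from (`population`); a mismatched
#' frequency model inflates the LOD.
#'
#' @param variants a [variant_table()] giving marker chromosome/position.
#' @param genotypes integer genotype matrix (variant keys x samples).
#' @param panel allele-frequency matrix (keys x populations).
#' @param population panel column used for frequencies; default the
#'   row-wise mean over all populations.
#' @param min_markers minimum markers per emitted run (default 20).
#' @param min_lod minimum LOD (default 3).
#' @param max_ibs0 opposite-homozygote tolerance per run (default 0).
#' @param cm_per_mb uniform genetic map used to attach `length_cm`.
#' @param err small genotype-error mixture weight keeping the IBD1
#'   likelihood finite at opposite-homozygote sites (only reachable when
#'   `max_ibs0 > 0`).
#' @return an `ibd_segments` table.
#' @export
detect_ibd_segments <- function(variants, genotypes, panel,
                                population = NULL,
                                min_markers = 20L, min_lod = 3.0,
                                max_ibs0 = 0L, cm_per_mb = 1.0,
                                err = 1e-3) {
  stopifnot(nrow(variants) == nrow(genotypes))
  freqs <- if (is.null(population)) {
    rowMeans(panel)
  } else {
    panel[, population]
  }
  p <- rep(0.5, nrow(variants))
  have <- variants$key %in% names(freqs)
  p[have] <- freqs[variants$key[have]]
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  q <- 1 - p

  # per-site genotype log-likelihood ratio tables, columns = genotype 0/1/2
  l0 <- cbind(q^2, 2 * p * q, p^2)                  # IBD0: HWE product terms
  fA <- cbind(0, q, p)                              # P(g | shared alt allele)
  fR <- cbind(q, p, 0)                              # P(g | shared ref allele)

  samples <- colnames(genotypes)
  out <- list()
  for (chrom in unique(variants$chrom)) {
    on_chr <- which(variants$chrom == chrom)
    on_chr <- on_chr[order(variants$pos[on_chr])]
    pos <- variants$pos[on_chr]
    for (i in seq_along(samples)) {
      for (j in seq_along(samples)) {
        if (j <= i) next
        g1 <- genotypes[on_chr, i]
        g2 <- genotypes[on_chr, j]
        ok <- !is.na(g1) & !is.na(g2)
        if (!any(ok)) {
          warning("pair ", samples[i], "/", samples[j],
                  " has no jointly called genotypes on ", chrom, "; skipped")
          next
        }
        idx <- which(ok)
        s1 <- g1[idx] + 1L; s2 <- g2[idx] + 1L
        site <- on_chr[idx]                    # rows into the per-site tables
        lik1 <- p[site] * fA[cbind(site, s1)] * fA[cbind(site, s2)] +
          q[site] * fR[cbind(site, s1)] * fR[cbind(site, s2)]
        lik0 <- l0[cbind(site, s1)] * l0[cbind(site, s2)]
        lik1 <- (1 - err) * lik1 + err * lik0
        site_lod <- log10(lik1 / lik0)
        ibs0 <- (g1[idx] == 0L & g2[idx] == 2L) | (g1[idx] == 2L & g2[idx] == 0L)
        runs <- runs_with_tolerance(ibs0, max_ibs0)
        for (r in runs) {
          nm <- r[2] - r[1] + 1L
          if (nm < min_markers) next
          lod <- sum(site_lod[r[1]:r[2]])
          # boundary correction: count the flanking IBS0 sites' evidence
          if (r[1] > 1L) lod <- lod + site_lod[r[1] - 1L]
          if (r[2] < length(site_lod)) lod <- lod + site_lod[r[2] + 1L]
          if (!is.finite(lod) || lod < min_lod) next
          sbp <- pos[idx[r[1]]]; ebp <- pos[idx[r[2]]]
          if (sbp >= ebp) next
          out[[length(out) + 1L]] <- data.frame(
            id1 = samples[i], id2 = samples[j], chrom = chrom,
            start_bp = sbp, end_bp = ebp, lod = lod,
            length_cm = (ebp - sbp + 1) / 1e6 * cm_per_mb,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(ibd_segments(character(0), character(0), character(0),
                        integer(0), integer(0), numeric(0), numeric(0)))
  }
  seg <- do.call(rbind, out)
  ibd_segments(seg$id1, seg$id2, seg$chrom, seg$start_bp, seg$end_bp,
               seg$lod, seg$length_cm)
}

# Maximal runs (as list of c(first, last) indices) of a logical violation
# vector containing at most k TRUE values. For k = 0 these are the stretches
# between violations; for k > 0 each window bounded by the (i)th and
# (i+k+1)th violation is maximal.
runs_with_tolerance <- function(viol, k = 0L) {
  n <- length(viol)
  if (n == 0L) return(list())
  v <- c(0L, which(viol), n + 1L)
  m <- length(v) - 2L                 # number of violations
  if (m <= k) return(list(c(1L, n)))
  runs <- list()
  for (i in 0:(m - k)) {
    lo <- v[i + 1L] + 1L
    hi <- v[i + k + 2L] - 1L
    if (hi >= lo) runs[[length(runs) + 1L]] <- c(lo, hi)
  }
  runs
}
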