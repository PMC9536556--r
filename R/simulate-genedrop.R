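#' Gene-drop simulation down a pedigree
#'
#' Simulates genotype transmission from founder haplotypes through modeled
#' meioses. Founder haplotype alleles are drawn per site from the panel
#' frequencies of the family's assigned population; each meiosis places
#' crossovers as a Poisson process (no interference) at the uniform
#' `cm_per_mb` map; monozygotic twins receive copies of the SAME meiosis
#' products. Every haplotype carries a founder-origin track, from which the
#' ground-truth pairwise IBD segments (maximal intervals where a pair
#' shares a founder haplotype id on at least one haplotype combination) are
#' computed for all within-family pairs.
#'
#' @param pedigree a `pedigree_table`; every non-founder must have both
#'   parents in the pedigree (exactly one known parent is an error).
#' @param panel allele-frequency matrix (variant keys x populations).
#' @param config a [sim_config()] (map, seed, founder populations).
#' @param variants a [variant_table()] giving the sites; default simulated
#'   from `config`.
#' @return list with:
#'   * `genotypes` — integer matrix (keys x sample ids) with a
#'     `"haplotypes"` attribute (two 0/1 allele matrices);
#'   * `truth` — list with `true_deleterious` (empty; filled by
#'     [plant_pathogenic_variants()]), `true_ibd` (data.frame `id1`, `id2`,
#'     `chrom`, `start_bp`, `end_bp`) and `founder_origin` (per sample, per
#'     haplotype, per chromosome interval -> founder haplotype id tracks).
#' @export
gene_drop <- function(pedigree, panel, config, variants = NULL) {
  if (is.null(variants)) variants <- simulate_variant_sites(config)
  validate_pedigree(pedigree)
  single <- xor(pedigree$father_id == "0", pedigree$mother_id == "0")
  if (any(single)) {
    stop("individual(s) with exactly one known parent: ",
         paste(pedigree$id[single], collapse = ", "),
         " (pedigree must be complete per nuclear family)")
  }
  set.seed(stage_seed(config$seed, "genedrop"))
  chroms <- names(config$chrom_lengths_bp)
  site_idx <- lapply(setNames(chroms, chroms),
                     function(ch) which(variants$chrom == ch))

  # topological order (parents before children)
  ids <- pedigree$id
  placed <- character(0)
  order_ids <- character(0)
  while (length(order_ids) < length(ids)) {
    ready <- vapply(seq_along(ids), function(i) {
      !(ids[i] %in% order_ids) &&
        (pedigree$father_id[i] == "0" ||
           (pedigree$father_id[i] %in% order_ids &&
              pedigree$mother_id[i] %in% order_ids))
    }, TRUE)
    if (!any(ready)) stop("pedigree contains a cycle or unresolved parents")
    order_ids <- c(order_ids, ids[ready])
  }

  next_founder_hap <- 0L
  haps <- list()   # haps[[id]][[chrom]] = list(h1 = list(allele, track), h2)

  draw_founder <- function(id) {
    fam <- pedigree$family_id[match(id, pedigree$id)]
    pop <- config$founder_pops[[fam]]
    out <- list()
    for (ch in chroms) {
      L <- config$chrom_lengths_bp[[ch]]
      keys <- variants$key[site_idx[[ch]]]
      af <- rep(0.5, length(keys))
      have <- keys %in% rownames(panel)
      af[have] <- panel[keys[have], pop]
      hs <- lapply(1:2, function(k) {
        next_founder_hap <<- next_founder_hap + 1L
        list(allele = rbinom(length(af), 1L, af),
             track = data.frame(start = 1L, end = as.integer(L),
                                hap = next_founder_hap))
      })
      out[[ch]] <- list(h1 = hs[[1]], h2 = hs[[2]])
    }
    out
  }

  meiosis_chrom <- function(parent_ch, L, pos, cm_per_mb) {
    morgans <- L * cm_per_mb / 1e6 / 100
    nx <- rpois(1, morgans)
    xpos <- sort(as.integer(floor(runif(nx, 1, L))))
    start <- sample.int(2, 1)
    seg_of_site <- findInterval(pos, xpos + 0.5) + 1L
    hap_of_seg <- function(k) ((start - 1L + k - 1L) %% 2L) + 1L
    hap_sites <- hap_of_seg(seg_of_site)
    allele <- ifelse(hap_sites == 1L, parent_ch$h1$allele, parent_ch$h2$allele)
    bounds <- c(1L, xpos + 1L)
    ends <- c(xpos, as.integer(L))
    tracks <- lapply(seq_along(bounds), function(k) {
      src <- if (hap_of_seg(k) == 1L) parent_ch$h1$track else parent_ch$h2$track
      clip_track(src, bounds[k], ends[k])
    })
    list(allele = as.integer(allele), track = merge_track(do.call(rbind, tracks)))
  }

  gamete <- function(parent_id) {
    out <- list()
    for (ch in chroms) {
      out[[ch]] <- meiosis_chrom(haps[[parent_id]][[ch]],
                                 config$chrom_lengths_bp[[ch]],
                                 variants$pos[site_idx[[ch]]],
                                 config$cm_per_mb)
    }
    out
  }

  for (id in order_ids) {
    i <- match(id, pedigree$id)
    if (pedigree$father_id[i] == "0") {
      haps[[id]] <- draw_founder(id)
      next
    }
    grp <- pedigree$mz_group[i]
    if (!is.na(grp)) {
      done <- intersect(pedigree$id[!is.na(pedigree$mz_group) &
                                      pedigree$mz_group == grp],
                        names(haps))
      if (length(done)) {      # identical twin: copy the same meioses
        haps[[id]] <- haps[[done[1]]]
        next
      }
    }
    pat <- gamete(pedigree$father_id[i])
    mat <- gamete(pedigree$mother_id[i])
    haps[[id]] <- lapply(setNames(chroms, chroms), function(ch) {
      list(h1 = pat[[ch]], h2 = mat[[ch]])
    })
  }

  # assemble matrices in variant order
  n <- nrow(variants)
  hapA <- hapB <- matrix(NA_integer_, n, length(ids),
                         dimnames = list(variants$key, ids))
  for (id in ids) {
    for (ch in chroms) {
      hapA[site_idx[[ch]], id] <- haps[[id]][[ch]]$h1$allele
      hapB[site_idx[[ch]], id] <- haps[[id]][[ch]]$h2$allele
    }
  }
  if (config$genotype_error > 0) {
    flipA <- matrix(runif(length(hapA)) < config$genotype_error, nrow = n)
    flipB <- matrix(runif(length(hapB)) < config$genotype_error, nrow = n)
    hapA[flipA] <- 1L - hapA[flipA]
    hapB[flipB] <- 1L - hapB[flipB]
  }
  genotypes <- hapA + hapB
  attr(genotypes, "haplotypes") <- list(hapA, hapB)

  # ground-truth pairwise IBD within each family
  ibd_rows <- list()
  for (fam in unique(pedigree$family_id)) {
    members <- pedigree$id[pedigree$family_id == fam]
    if (length(members) < 2) next
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (b <= a) next
        for (ch in chroms) {
          segs <- pair_ibd_from_tracks(
            haps[[members[a]]][[ch]]$h1$track, haps[[members[a]]][[ch]]$h2$track,
            haps[[members[b]]][[ch]]$h1$track, haps[[members[b]]][[ch]]$h2$track,
            config$chrom_lengths_bp[[ch]])
          if (nrow(segs)) {
            ibd_rows[[length(ibd_rows) + 1L]] <- data.frame(
              id1 = members[a], id2 = members[b], chrom = ch,
              start_bp = segs$start, end_bp = segs$end,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  true_ibd <- if (length(ibd_rows)) do.call(rbind, ibd_rows) else
    data.frame(id1 = character(0), id2 = character(0), chrom = character(0),
               start_bp = integer(0), end_bp = integer(0))
  origin <- lapply(haps, function(h)
    lapply(h, function(ch) list(h1 = ch$h1$track, h2 = ch$h2$track)))
  list(genotypes = genotypes,
       truth = list(true_deleterious = character(0), true_ibd = true_ibd,
                    founder_origin = origin))
}

clip_track <- function(track, s, e) {
  sel <- track$end >= s & track$start <= e
  t <- track[sel, , drop = FALSE]
  t$start <- pmax(t$start, as.integer(s))
  t$end <- pmin(t$end, as.integer(e))
  t
}

merge_track <- function(track) {
  if (nrow(track) <= 1) return(track)
  keep <- which(c(TRUE, track$hap[-1] != track$hap[-nrow(track)]))
  data.frame(start = track$start[keep],
             end = track$end[c(keep[-1] - 1L, nrow(track))],
             hap = track$hap[keep], row.names = NULL)
}

# Maximal intervals on [1, L] where the two individuals share a founder
# haplotype id on >= 1 of the four haplotype pairings (IBD >= 1).
pair_ibd_from_tracks <- function(t1a, t1b, t2a, t2b, L) {
  pts <- sort(unique(c(1L, t1a$start, t1b$start, t2a$start, t2b$start,
                       t1a$end + 1L, t1b$end + 1L, t2a$end + 1L, t2b$end + 1L)))
  pts <- pts[pts <= L]
  id_at <- function(track, q) track$hap[findInterval(q, track$start)]
  i1 <- cbind(id_at(t1a, pts), id_at(t1b, pts))
  i2 <- cbind(id_at(t2a, pts), id_at(t2b, pts))
  shared <- i1[, 1] == i2[, 1] | i1[, 1] == i2[, 2] |
    i1[, 2] == i2[, 1] | i1[, 2] == i2[, 2]
  ends <- c(pts[-1] - 1L, as.integer(L))
  r <- rle(shared)
  stops <- cumsum(r$lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  sel <- which(r$values)
  data.frame(start = pts[starts[sel]], end = ends[stops[sel]])
}
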