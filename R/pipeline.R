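#' Build a pipeline run configuration
#'
#' Gathers every stage toggle, threshold and input/output path of a full
#' run. The configuration is serialized verbatim (YAML) into the run
#' directory, and re-running an archived configuration reproduces the run's
#' outputs byte-identically.
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed; each stage draws a named substream, so toggling
#'   one stage does not shift another's randomness.
#' @param stages named logical toggles: `simulate`, `prioritize`, `ibd`,
#'   `popstats`.
#' @param sim list of [sim_config()] overrides for the simulate stage.
#' @param inputs named paths (`vcf`, `ped`, `predictions`, `frequencies`,
#'   `genes`, optionally `segments`) used when `simulate` is off.
#' @param max_af,scope_mode,min_votes,carrier_mode,min_lod,flank_bp,aggregation
#'   stage thresholds (see the stage functions for semantics and defaults).
#' @param ibd_dialect dialect of the `segments` input file.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c(simulate = TRUE, prioritize = TRUE,
                                  ibd = TRUE, popstats = TRUE),
                       sim = list(), inputs = list(),
                       max_af = 0.01, scope_mode = "any",
                       min_votes = 17L, carrier_mode = "all_affected_carry",
                       min_lod = 3.0, flank_bp = 2000L, aggregation = "sum",
                       ibd_dialect = "simple_tsv") {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = as.list(stages), sim = sim, inputs = inputs,
                 max_af = max_af, scope_mode = scope_mode,
                 min_votes = as.integer(min_votes),
                 carrier_mode = carrier_mode, min_lod = min_lod,
                 flank_bp = as.integer(flank_bp), aggregation = aggregation,
                 ibd_dialect = ibd_dialect),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> prioritize -> ibd -> popstats under one
#' configuration. Stage outputs are written as TSV into the run directory
#' together with the archived configuration (`config.yaml`) and a
#' `summary.json` holding per-family candidate gene counts, the shared
#' genes, the cross-family IBD genes and the top burden genes. A stage
#' failure aborts the run with the failing stage named; partial outputs are
#' retained next to a `FAILED` marker file.
#'
#' @param config a [run_config()], a list coercible to one, or the path of
#'   a YAML file holding one.
#' @return the run directory path, invisibly; the summary is also returned
#'   as attribute `"summary"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "run_config")) {
    config <- do.call(run_config, config)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  archive <- config
  archive$stages <- lapply(archive$stages, isTRUE)
  # named atomic vectors must become YAML maps or their names are lost
  archive$sim <- lapply(archive$sim, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(unclass(archive), file.path(out_dir, "config.yaml"))
  summary <- list(seed = config$seed)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage ", stage, " failed: ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  any_ran <- FALSE
  tryCatch({
    data <- NULL
    if (isTRUE(config$stages$simulate)) {
      any_ran <- TRUE
      stage <- "simulate"
      sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      data <- simulate_study(sim_cfg, out_dir = file.path(out_dir, "sim"))
    } else if (length(config$inputs)) {
      stage <- "load"
      vcf <- read_vcf(config$inputs$vcf)
      data <- list(
        variants = vcf$variants, genotypes = vcf$genotypes,
        pedigree = read_pedigree(config$inputs$ped),
        profiles = read_prediction_table(config$inputs$predictions),
        panel = read_frequency_table(config$inputs$frequencies),
        genes = read_gene_bed(config$inputs$genes),
        truth = NULL)
    }

    if (isTRUE(config$stages$prioritize)) {
      stage <- "prioritize"
      any_ran <- TRUE
      fams <- unique(data$pedigree$family_id)
      reports <- lapply(fams, function(f)
        prioritize_family(f, data$variants, data$genotypes, data$profiles,
                          data$panel, data$pedigree,
                          max_af = config$max_af,
                          scope_mode = config$scope_mode,
                          min_votes = config$min_votes,
                          carrier_mode = config$carrier_mode))
      names(reports) <- fams
      write_candidate_reports(reports, data$profiles,
                              file.path(out_dir, "candidates.tsv"))
      inter <- intersect_families(reports)
      summary$family_gene_counts <- lapply(reports,
                                           function(r) length(r$genes))
      summary$shared_genes <- inter$shared
    }

    if (isTRUE(config$stages$ibd)) {
      stage <- "ibd"
      any_ran <- TRUE
      segments <- if (!is.null(config$inputs$segments)) {
        read_ibd_file(config$inputs$segments, config$ibd_dialect)
      } else {
        detect_ibd_segments(data$variants, data$genotypes, data$panel,
                            min_lod = config$min_lod)
      }
      segments <- filter_segments(segments, min_lod = config$min_lod)
      sharing <- pairwise_sharing_table(segments, data$pedigree, data$genes)
      cross <- cross_family_common(sharing)
      write.table(sharing, file.path(out_dir, "ibd_sharing.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(cross$intervals, file.path(out_dir, "ibd_cross_family.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$cross_family_ibd_genes <- cross$genes
    }

    if (isTRUE(config$stages$popstats)) {
      stage <- "popstats"
      any_ran <- TRUE
      pathogenic <- setNames(
        data$variants$key %in% data$truth$true_deleterious,
        data$variants$key)
      stats <- population_comparison_table(data$variants, data$panel,
                                           pathogenic, data$genes,
                                           flank_bp = config$flank_bp,
                                           aggregation = config$aggregation)
      write.table(stats$burden, file.path(out_dir, "gene_burden.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(stats$spectra, file.path(out_dir, "maf_spectra.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      top <- stats$burden[!is.na(stats$burden$gene_snp_frequency), ]
      top <- top[order(-top$gene_snp_frequency), ]
      summary$top_burden_genes <- unique(top$gene)[seq_len(min(5, nrow(top)))]
    }
  }, error = on_fail)
  if (any_ran) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(structure(out_dir, summary = summary))
}

# Flat TSV across families: one row per (family, retained variant), sorted
# (family, chrom, pos) for diff-stability.
write_candidate_reports <- function(reports, profiles, path) {
  rows <- lapply(reports, function(r) {
    v <- r$variants
    if (!nrow(v)) return(NULL)
    statuses <- apply(profiles[v$key, , drop = FALSE], 1, paste, collapse = "")
    data.frame(family = r$family, gene = v$genes, chrom = v$chrom,
               pos = v$pos, ref = v$ref, alt = v$alt, rsid = v$rsid,
               qualifying_votes = v$qualifying_votes, statuses = statuses,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(family = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      rsid = character(0), qualifying_votes = integer(0),
                      statuses = character(0))
  } else {
    out <- out[order(out$family, out$chrom, out$pos), , drop = FALSE]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
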