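#' Simulate a multi-population allele-frequency panel
#'
#' Draws, for each variant, a base alternate-allele frequency and then one
#' frequency per population: a Gaussian jitter (`pop_sd`) around the base,
#' with probability `divergence_prob` replaced by an independent uniform
#' draw (creating strongly divergent population pairs of the kind seen
#' between African and European reference panels). A `rare_fraction` share
#' of variants is made rare (frequency uniform in `[0, rare_max]`) in the
#' designated first population, so the spectrum populates both the rare bin
#' and the five common bins. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param variants optional [variant_table()] supplying the row keys;
#'   default: simulated from `config`.
#' @return numeric matrix (variant keys x population labels) with
#'   attribute `"rare"` (logical: designated-rare variants).
#' @export
simulate_frequency_panel <- function(config,
                                     variants = simulate_variant_sites(config)) {
  force(variants)   # evaluate before seeding: the default draws its own substream
  set.seed(stage_seed(config$seed, "panel"))
  n <- nrow(variants)
  pops <- config$pop_labels
  base <- runif(n, config$rare_max + 0.005, 1 - config$rare_max - 0.005)
  rare <- runif(n) < config$rare_fraction
  base[rare] <- runif(sum(rare), 0, config$rare_max)
  panel <- matrix(NA_real_, n, length(pops),
                  dimnames = list(variants$key, pops))
  for (j in seq_along(pops)) {
    af <- base + rnorm(n, 0, config$pop_sd)
    div <- runif(n) < config$divergence_prob
    af[div] <- runif(sum(div))
    panel[, j] <- pmin(pmax(af, 0), 1)
  }
  # the designated rare population keeps its rare variants rare
  panel[rare, 1] <- pmin(panel[rare, 1], runif(sum(rare), 0, config$rare_max))
  attr(panel, "rare") <- setNames(rare, variants$key)
  panel
}
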