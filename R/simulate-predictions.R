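#' Simulate a multi-predictor status matrix
#'
#' Each configured tool calls each variant independently: a true
#' deleterious variant (key in `truth$true_deleterious`) receives a
#' qualifying status with the tool's sensitivity (`A` for tools in
#' `config$a_tools`, `D` otherwise) and `T` when missed; any other variant
#' receives `D` with probability `1 - specificity` and `T` otherwise.
#' Deterministic under the config seed.
#'
#' @param variants a [variant_table()].
#' @param truth ground-truth list carrying `true_deleterious`.
#' @param config a [sim_config()].
#' @return `prediction_profiles` character matrix (keys x tools).
#' @export
simulate_predictions <- function(variants, truth, config) {
  set.seed(stage_seed(config$seed, "predictions"))
  n <- nrow(variants)
  tools <- config$tools
  is_true <- variants$key %in% truth$true_deleterious
  profiles <- matrix("T", n, length(tools),
                     dimnames = list(variants$key, tools))
  for (j in seq_along(tools)) {
    hit <- rep(FALSE, n)
    hit[is_true] <- runif(sum(is_true)) < config$predictor_sensitivity[j]
    hit[!is_true] <- runif(sum(!is_true)) < (1 - config$predictor_specificity[j])
    status <- if (tools[j] %in% config$a_tools) "A" else "D"
    profiles[hit & is_true, j] <- status
    profiles[hit & !is_true, j] <- "D"
  }
  class(profiles) <- c("prediction_profiles", class(profiles))
  profiles
}
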