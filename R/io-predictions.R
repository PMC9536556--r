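#' Default deleteriousness-predictor configuration
#'
#' The consensus vote runs over a configurable, ordered set of in silico
#' predictors; the default set is the 21 ANNOVAR-style functional scores
#' commonly distributed with whole-genome annotation (SIFT, PolyPhen-2
#' HDIV/HVAR, LRT, MutationTaster, MutationAssessor, FATHMM, fathmm-MKL,
#' RadialSVM, LR, PROVEAN, MetaSVM, MetaLR, CADD, GERP++, DANN, M-CAP,
#' Eigen, GenoCanyon, PhyloP, SiPhy). Raw column values are mapped onto the
#' four internal statuses:
#' * `D` — deleterious / probably damaging / disease_causing,
#' * `A` — disease_causing_automatic,
#' * `T` — tolerated / benign / neutral,
#' * `U` — unknown or missing (never a qualifying vote).
#'
#' Predictors that emit numeric scores only (CADD, GERP++, PhyloP, SiPhy
#' and similar) carry no categorical call; their columns are thresholded at
#' `numeric_threshold` (default 20, the conventional CADD "likely
#' deleterious" band): score >= threshold maps to `D`, below to `T`. The
#' threshold is a stated assumption of the run and is logged.
#'
#' @param tools ordered character vector of predictor (column) names.
#' @param mapping named character vector mapping raw categorical values to
#'   statuses in `D`/`A`/`T`/`U`.
#' @param numeric_threshold numeric cutoff for score-only columns.
#' @return a list of class `tool_config`.
#' @export
tool_config <- function(tools = default_tools(),
                        mapping = default_status_mapping(),
                        numeric_threshold = 20) {
  stopifnot(length(tools) >= 1, all(mapping %in% c("D", "A", "T", "U")))
  structure(list(tools = tools, mapping = mapping,
                 numeric_threshold = numeric_threshold),
            class = "tool_config")
}

#' @rdname tool_config
#' @export
default_tools <- function() {
  c("SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT", "MutationTaster",
    "MutationAssessor", "FATHMM", "fathmm_MKL", "RadialSVM", "LR",
    "PROVEAN", "MetaSVM", "MetaLR", "CADD", "GERP", "DANN", "M_CAP",
    "Eigen", "GenoCanyon", "PhyloP", "SiPhy")
}

#' @rdname tool_config
#' @export
default_status_mapping <- function() {
  c(D = "D", deleterious = "D", Deleterious = "D",
    `probably damaging` = "D", probably_damaging = "D", P = "D",
    disease_causing = "D", disease_causing_automatic = "A", A = "A",
    T = "T", tolerated = "T", Tolerated = "T", benign = "T", B = "T",
    neutral = "T", N = "T",
    U = "U", unknown = "U", `.` = "U")
}

#' Read a per-variant multi-predictor status table
#'
#' Reads a tab-delimited, ANNOVAR-multianno-style table with one row per
#' variant and one column per configured predictor, and maps every raw value
#' through the configured status mapping. Predictor columns absent from the
#' file yield status `U` for all variants. Numeric columns are thresholded
#' (see [tool_config()]). An unmapped raw value is an error naming the value
#' and the column — values are never silently dropped.
#'
#' Variant keys are taken from a `key` column if present, otherwise built
#' from `chrom`/`pos`/`ref`/`alt` columns.
#'
#' @param path path to the TSV (header line required).
#' @param config a [tool_config()].
#' @return character matrix of class `prediction_profiles`
#'   (variants x tools) with values in `D`/`A`/`T`/`U`, row names the
#'   variant keys, column names the configured tools.
#' @export
read_prediction_table <- function(path, config = tool_config()) {
  # colClasses: a status column of all "T" must not become logical TRUE
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if ("key" %in% names(tab)) {
    keys <- tab$key
  } else if (all(c("chrom", "pos", "ref", "alt") %in% names(tab))) {
    keys <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  } else {
    stop("prediction table needs a 'key' column or chrom/pos/ref/alt columns")
  }
  profiles <- matrix("U", nrow = nrow(tab), ncol = length(config$tools),
                     dimnames = list(keys, config$tools))
  n_absent <- 0L
  for (tool in config$tools) {
    if (!tool %in% names(tab)) {
      n_absent <- n_absent + 1L
      next
    }
    raw <- as.character(tab[[tool]])
    raw[is.na(raw) | raw == ""] <- "."
    num <- suppressWarnings(as.numeric(raw))
    is_num <- !is.na(num)
    status <- rep(NA_character_, length(raw))
    status[is_num] <- ifelse(num[is_num] >= config$numeric_threshold, "D", "T")
    known <- !is_num & raw %in% names(config$mapping)
    status[known] <- unname(config$mapping[raw[known]])
    bad <- which(is.na(status))
    if (length(bad)) {
      stop("unmapped predictor value '", raw[bad[1]], "' in column '", tool,
           "' (row ", bad[1], ")")
    }
    profiles[, tool] <- status
  }
  if (n_absent > 0) {
    .log_msg(n_absent, " configured predictor column(s) absent; statuses set to U")
  }
  class(profiles) <- c("prediction_profiles", class(profiles))
  profiles
}

#' Write a prediction-profile matrix as TSV
#'
#' Inverse of [read_prediction_table()] under a mapping that is the identity
#' on `D`/`A`/`T`/`U` (the default mapping is).
#'
#' @param profiles matrix as returned by [read_prediction_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(profiles, path) {
  out <- data.frame(key = rownames(profiles), unclass(profiles),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
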