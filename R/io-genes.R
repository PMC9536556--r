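#' Read gene models from BED
#'
#' Reads BED3+name via [rtracklayer::import()] and converts to the package's
#' 1-based inclusive coordinate convention (`start_bp = BED start + 1`, so a
#' BED interval of length L satisfies `end_bp - start_bp + 1 == L`).
#' Zero-length intervals and negative coordinates are parse errors. Two gene
#' models sharing a symbol (e.g. on different chromosomes) are both retained
#' as distinct records.
#'
#' @param path path to a BED file with at least 4 columns (chrom, start,
#'   end, name).
#' @return data.frame of class `gene_models` with columns `symbol`, `chrom`,
#'   `start_bp`, `end_bp`, `strand`.
#' @export
read_gene_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) && any(GenomicRanges::width(gr) < 1)) {
    stop("zero-length BED interval in ", path)
  }
  name <- gr$name
  if (is.null(name) || anyNA(name) || any(name == "")) {
    stop("BED file must carry a non-empty name (gene symbol) column")
  }
  # rtracklayer already shifts BED's 0-based half-open starts to 1-based
  gene_models(symbol = name,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start_bp = GenomicRanges::start(gr),
              end_bp = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)))
}

#' Construct a gene-model table
#'
#' @param symbol gene symbols (non-empty).
#' @param chrom chromosome names.
#' @param start_bp,end_bp 1-based inclusive span, `start_bp <= end_bp`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return data.frame of class `gene_models`.
#' @export
gene_models <- function(symbol, chrom, start_bp, end_bp, strand = "*") {
  stopifnot(all(nzchar(symbol)))
  g <- data.frame(symbol = as.character(symbol), chrom = as.character(chrom),
                  start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                  strand = rep_len(as.character(strand), length(symbol)),
                  stringsAsFactors = FALSE)
  if (any(g$start_bp < 1)) stop("gene coordinates must be positive (1-based)")
  if (any(g$start_bp > g$end_bp)) stop("gene model with start_bp > end_bp")
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Write gene models as BED3+name
#'
#' Converts back to BED's 0-based half-open convention; [read_gene_bed()]
#' round-trips the records.
#'
#' @param genes a `gene_models` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  out <- cbind(genes$chrom, genes$start_bp - 1L, genes$end_bp, genes$symbol)
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}

# GRanges view of a gene_models table (1-based inclusive already)
genes_as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start_bp, end = genes$end_bp),
    symbol = genes$symbol
  )
}
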