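#' Read pairwise IBD segments
#'
#' Two tab-delimited dialects are supported:
#' * `refined_ibd` — the output layout of the Refined IBD detector:
#'   `id1, hap1, id2, hap2, chrom, start, end, lod` (no header). The
#'   haplotype indices are discarded; this reader consumes the format, it
#'   does not reimplement the detector.
#' * `simple_tsv` — `id1, id2, chrom, start, end, lod, cm` with a header
#'   line; `cm` (genetic length in centimorgans) may be `NA`.
#'
#' Coordinates are 1-based inclusive. Records with `start >= end` are
#' rejected with a warning and tallied in the `"rejects"` attribute;
#' multiple segments on the same pair/chromosome are preserved as separate
#' records.
#'
#' @param path path to the segment file.
#' @param dialect `"refined_ibd"` (default) or `"simple_tsv"`.
#' @return data.frame of class `ibd_segments` with columns `id1`, `id2`,
#'   `chrom`, `start_bp`, `end_bp`, `lod`, `length_cm`; attribute
#'   `"rejects"` counts dropped records.
#' @export
read_ibd_file <- function(path, dialect = c("refined_ibd", "simple_tsv")) {
  dialect <- match.arg(dialect)
  empty <- ibd_segments(character(0), character(0), character(0),
                        integer(0), integer(0), numeric(0), numeric(0))
  if (file.size(path) == 0) {
    attr(empty, "rejects") <- 0L
    return(empty)
  }
  if (dialect == "refined_ibd") {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 8) stop("refined_ibd dialect expects >= 8 columns")
    seg <- data.frame(id1 = as.character(raw[[1]]), id2 = as.character(raw[[3]]),
                      chrom = as.character(raw[[5]]),
                      start_bp = as.integer(raw[[6]]), end_bp = as.integer(raw[[7]]),
                      lod = as.numeric(raw[[8]]),
                      length_cm = if (ncol(raw) >= 9) as.numeric(raw[[9]]) else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("id1", "id2", "chrom", "start", "end", "lod")
    if (!all(need %in% names(raw))) {
      stop("simple_tsv dialect needs columns: ", paste(need, collapse = ", "))
    }
    seg <- data.frame(id1 = as.character(raw$id1), id2 = as.character(raw$id2),
                      chrom = as.character(raw$chrom),
                      start_bp = as.integer(raw$start), end_bp = as.integer(raw$end),
                      lod = as.numeric(raw$lod),
                      length_cm = if ("cm" %in% names(raw)) as.numeric(raw$cm) else NA_real_,
                      stringsAsFactors = FALSE)
  }
  bad <- seg$start_bp >= seg$end_bp
  if (any(bad)) {
    warning(sum(bad), " IBD record(s) with start >= end rejected")
    seg <- seg[!bad, , drop = FALSE]
  }
  if (any(!is.finite(seg$lod))) stop("non-finite LOD score in ", path)
  class(seg) <- c("ibd_segments", "data.frame")
  attr(seg, "rejects") <- sum(bad)
  seg
}

#' Construct an IBD segment table in memory
#'
#' @param id1,id2 sample identifiers of the (unordered) pair.
#' @param chrom chromosome name.
#' @param start_bp,end_bp 1-based inclusive interval; `start_bp < end_bp`.
#' @param lod log10 odds supporting IBD over non-IBD for the segment.
#' @param length_cm optional genetic length in centimorgans.
#' @return data.frame of class `ibd_segments`.
#' @export
ibd_segments <- function(id1, id2, chrom, start_bp, end_bp, lod,
                         length_cm = NA_real_) {
  seg <- data.frame(id1 = as.character(id1), id2 = as.character(id2),
                    chrom = as.character(chrom),
                    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                    lod = as.numeric(lod),
                    length_cm = rep_len(as.numeric(length_cm), length(id1)),
                    stringsAsFactors = FALSE)
  if (any(seg$start_bp >= seg$end_bp)) stop("IBD segment with start >= end")
  if (any(!is.finite(seg$lod))) stop("IBD segment with non-finite LOD")
  class(seg) <- c("ibd_segments", "data.frame")
  seg
}

#' Write IBD segments in the simple_tsv dialect
#'
#' @param segments an `ibd_segments` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ibd_file <- function(segments, path) {
  out <- data.frame(id1 = segments$id1, id2 = segments$id2,
                    chrom = segments$chrom, start = segments$start_bp,
                    end = segments$end_bp, lod = segments$lod,
                    cm = segments$length_cm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
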