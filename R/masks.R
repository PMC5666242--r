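#' Interval mask set
#'
#' A set of genomic intervals to be removed from analysis, in the BED
#' convention: half-open, 0-based `[start, end)`. Intervals are normalized
#' on construction (sorted, merged, non-overlapping) via IRanges.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(intervals = data.frame(chrom = character(),
                                            start = integer(),
                                            end = integer())) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]
  if (any(intervals$start < 0)) stop("mask intervals must have start >= 0")
  if (nrow(intervals)) {
    parts <- lapply(split(intervals, intervals$chrom), function(d) {
      # to 1-based closed for IRanges, reduce, back to 0-based half-open
      r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      data.frame(chrom = d$chrom[1],
                 start = IRanges::start(r) - 1L,
                 end = IRanges::end(r))
    })
    intervals <- do.call(rbind, parts)
    intervals <- intervals[order(intervals$chrom, intervals$start), ]
    rownames(intervals) <- NULL
  }
  structure(list(intervals = intervals), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("mask_set: %d intervals, %s bp on %d chromosome(s)\n",
              nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start), big.mark = ","),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Read a BED file as a mask set
#'
#' Reads the first three columns (chrom, start, end) of a BED file; BED is
#' already 0-based half-open so coordinates pass straight through.
#' @param path BED file path.
#' @export
read_bed_mask <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          rep("NULL", max(0, .bed_ncol(path) - 3))))
  names(bed)[1:3] <- c("chrom", "start", "end")
  mask_set(bed[, 1:3])
}

.bed_ncol <- function(path) {
  first <- readLines(path, n = 1)
  length(strsplit(first, "\t")[[1]])
}

#' Write a mask set as BED
#' @param mask a `mask_set`.
#' @param path output path.
#' @export
write_bed_mask <- function(mask, path) {
  utils::write.table(mask$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union of mask sets
#' @param ... `mask_set` objects.
#' @export
merge_masks <- function(...) {
  ms <- list(...)
  stopifnot(all(vapply(ms, inherits, logical(1), "mask_set")))
  mask_set(do.call(rbind, lapply(ms, `[[`, "intervals")))
}

# Logical vector: is each 1-based position covered by the mask?
mask_covers <- function(mask, chrom, pos) {
  hit <- logical(length(pos))
  iv <- mask$intervals
  for (ch in unique(iv$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    q <- IRanges::IRanges(pos[sel], width = 1L)
    s <- IRanges::IRanges(ivc$start + 1L, ivc$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

# Build a mask from 1-based single-position footprints extended by a buffer.
positions_to_mask <- function(chrom, pos, buffer = 0L, ref_len = 1L) {
  if (!length(pos)) return(mask_set())
  mask_set(data.frame(chrom = chrom,
                      start = pmax(0L, pos - 1L - buffer),
                      end = pos + ref_len - 1L + buffer))
}
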