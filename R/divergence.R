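#' Pairwise nucleotide divergence between two individuals
#'
#' Average per-site percent nucleotide difference between the alleles
#' carried by two individuals. At each site where both are called, the
#' mismatch fraction is the mean over all ordered allele pairs (4 for
#' diploid vs diploid, 2 for diploid vs haploid, 1 for haploid vs
#' haploid); divergence is 100 times the mean mismatch fraction over
#' compared sites. Uncorrected by default; `correction = TRUE` applies the
#' Jukes–Cantor multiple-hit correction
#' `d = -(3/4) log(1 - (4/3) p)` to the raw proportion.
#'
#' Either sample may be `"reference"`, in which case its allele at every
#' site is the REF base (useful for ingroup–outgroup distances when the
#' outgroup is the reference assembly).
#'
#' @param table a `genotype_table` (already filtered).
#' @param sample_a,sample_b sample names (or `"reference"`); comparing a
#'   sample with itself is rejected unless `allow_self = TRUE`.
#' @param chrom optionally restrict to one chromosome.
#' @param correction apply Jukes–Cantor correction.
#' @param allow_self permit a self-comparison (its "divergence" is the
#'   individual's per-site heterozygous mismatch).
#' @return list of class `divergence_result`: `pair`, `n_sites`,
#'   `divergence` (percent), `corrected`.
#' @export
pairwise_divergence <- function(table, sample_a, sample_b, chrom = NULL,
                                correction = FALSE, allow_self = FALSE) {
  if (identical(sample_a, sample_b) && !allow_self)
    stop("self-comparison requested; set allow_self = TRUE if intended")
  idx <- if (is.null(chrom)) seq_len(n_sites(table))
         else which(table$sites$chrom == chrom)
  mf <- .mismatch_fraction(table, sample_a, sample_b, idx)
  ok <- !is.na(mf)
  if (!any(ok)) stop("no comparable sites for ", sample_a, " vs ", sample_b)
  p <- mean(mf[ok])
  d <- if (correction) .jukes_cantor(p) else p
  structure(list(pair = c(sample_a, sample_b), n_sites = sum(ok),
                 divergence = 100 * d, corrected = isTRUE(correction)),
            class = "divergence_result")
}

.jukes_cantor <- function(p) {
  if (p >= 0.75) stop("raw mismatch proportion >= 0.75: JC correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

# per-site mismatch fraction for the selected rows; NA where either
# sample is missing. Haploid calls are duplicated into both allele slots
# so the 4-pair mean is correct for every ploidy combination.
.mismatch_fraction <- function(table, sample_a, sample_b, idx) {
  get2 <- function(s) {
    if (identical(s, "reference")) {
      r <- table$sites$ref[idx]
      list(x = r, y = r)
    } else {
      stopifnot(s %in% table$samples)
      x <- table$a1[idx, s]
      y <- table$a2[idx, s]
      list(x = x, y = ifelse(is.na(y), x, y))
    }
  }
  a <- get2(sample_a)
  b <- get2(sample_b)
  ((a$x != b$x) + (a$x != b$y) + (a$y != b$x) + (a$y != b$y)) / 4
}

#' Per-window pairwise divergence
#'
#' Divergence on the same non-overlapping window tiling used by the
#' pattern statistics, so the result joins a `window_stats` table
#' directly.
#'
#' @inheritParams pairwise_divergence
#' @param window_bp window size in bp (default 5,000,000).
#' @return data.frame with `chrom`, `start`, `end`, `n_sites`,
#'   `divergence` (raw percent) and, when `correction` is set, `jc_divergence`.
#' @export
window_divergence <- function(table, sample_a, sample_b, window_bp = 5e6,
                              correction = FALSE) {
  if (identical(sample_a, sample_b))
    stop("self-comparison requested; use pairwise_divergence(allow_self = TRUE)")
  idx <- seq_len(n_sites(table))
  mf <- .mismatch_fraction(table, sample_a, sample_b, idx)
  ok <- !is.na(mf)
  start <- window_start(table$sites$pos, as.integer(window_bp))
  key <- paste(table$sites$chrom, start, sep = ":")[ok]
  agg <- rowsum(cbind(mf = mf[ok], n = 1), key, reorder = FALSE)
  first <- which(ok)[!duplicated(key)]
  out <- data.frame(chrom = table$sites$chrom[first],
                    start = start[first],
                    end = start[first] + as.integer(window_bp) - 1L,
                    n_sites = as.integer(agg[, "n"]),
                    divergence = 100 * agg[, "mf"] / agg[, "n"],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (correction)
    out$jc_divergence <- 100 * vapply(out$divergence / 100, .jukes_cantor,
                                      numeric(1))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
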