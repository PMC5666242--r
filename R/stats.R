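#' Patterson's D statistic
#'
#' `D = (sum(ABBA) - sum(BABA)) / (sum(ABBA) + sum(BABA))`. Positive D
#' indicates an excess of derived alleles shared by H2 and H3 (over H1 and
#' H3), the signature of H2–H3 gene flow; under incomplete lineage sorting
#' alone the expectation is zero. Swapping H1 and H2 negates D exactly.
#'
#' @param abba either the ABBA sum, or a `pattern_counts` window table
#'   whose `w_abba`/`w_baba` columns are summed.
#' @param baba the BABA sum when `abba` is numeric.
#' @return list of class `d_result` with `D`, `abba`, `baba`, `n_windows`.
#' @export
patterson_D <- function(abba, baba = NULL) {
  if (inherits(abba, "pattern_counts") ||
      (is.data.frame(abba) && all(c("w_abba", "w_baba") %in% names(abba)))) {
    nw <- nrow(abba)
    baba <- sum(abba$w_baba)
    abba <- sum(abba$w_abba)
  } else {
    stopifnot(is.numeric(abba), is.numeric(baba))
    nw <- NA_integer_
    abba <- sum(abba)
    baba <- sum(baba)
  }
  denom <- abba + baba
  D <- if (denom > 0) (abba - baba) / denom else NA_real_
  if (denom <= 0) warning("ABBA + BABA is zero: D undefined")
  structure(list(D = D, abba = abba, baba = baba, n_windows = nw),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f  (ABBA = %g, BABA = %g)\n",
              x$D, x$abba, x$baba))
  invisible(x)
}

# f_dM numerator and the two sign-branch denominators from per-site
# derived-allele frequencies. The statistic is S / S_D where S_D replaces
# the donor pair with pD = max(p2, p3) when S >= 0; for S < 0 the roles of
# H1 and H2 are exchanged and the sign flipped, which keeps the statistic
# on [-1, 1] and antisymmetric under the H1<->H2 swap.
fdm_components <- function(p1, p2, p3) {
  S <- sum((1 - p1) * p2 * p3 - p1 * (1 - p2) * p3)
  pD <- pmax(p2, p3)
  SDp <- sum((1 - p1) * pD * pD - p1 * (1 - pD) * pD)
  pDn <- pmax(p1, p3)
  SDn <- sum((1 - p2) * pDn * pDn - p2 * (1 - pDn) * pDn)
  c(S = S, SDp = SDp, SDn = SDn)
}

# evaluate f_dM from its components; sign branch chosen by S unless forced
fdm_value <- function(S, SDp, SDn, sign_branch = NULL) {
  pos <- if (is.null(sign_branch)) S >= 0 else sign_branch >= 0
  den <- if (pos) SDp else SDn
  if (is.na(den) || den == 0) return(NA_real_)
  f <- S / den
  if (!is.na(f) && abs(f) > 1) {
    warning("f_dM outside [-1, 1] (", format(f), "); clamped")
    f <- max(-1, min(1, f))
  }
  f
}

#' Windowed f_dM and D statistics
#'
#' Computes, per non-overlapping genomic window, the f_dM admixture
#' statistic, the window D, and the jackknife weight (the window's
#' ABBA + BABA sum).
#'
#' Two f_dM modes are provided. `"frequency"` is the dynamic-donor
#' formulation from allele frequencies (see [fdm_components()] internals):
#' bounded on \[-1, 1\], positive for an H2–H3 derived-allele excess and
#' negative for H1–H3. `"haploid"` reports the window D itself, which is
#' the statistic's value when every individual contributes a single
#' nucleotide per site. `"auto"` (default) selects `"haploid"` when all
#' frequencies are 0/1 and `"frequency"` otherwise.
#'
#' @param pol a `polarized_sites` data.frame.
#' @param window_bp window size in bp (default 5,000,000).
#' @param mode `"auto"`, `"haploid"` or `"frequency"`.
#' @return data.frame of class `window_stats`: `chrom`, `start`, `end`,
#'   `n_sites`, `w_bbaa`, `w_abba`, `w_baba`, `S`, `SDp`, `SDn`, `fdm`,
#'   `D`, `weight`. Windows with zero ABBA+BABA weight have `fdm = NA`.
#' @export
window_stats <- function(pol, window_bp = 5e6,
                         mode = c("auto", "haploid", "frequency")) {
  mode <- match.arg(mode)
  use <- pol[pol$usable, , drop = FALSE]
  if (mode == "auto") {
    haploid <- all(use$p1 %in% c(0, 1) & use$p2 %in% c(0, 1) &
                     use$p3 %in% c(0, 1))
    mode <- if (haploid) "haploid" else "frequency"
  }
  win <- tally_windows(pol, window_bp = window_bp, mode = "frequency")
  window_bp <- attr(win, "window_bp")
  start <- window_start(use$pos, window_bp)
  key <- paste(use$chrom, start, sep = ":")
  comp <- t(vapply(split(seq_len(nrow(use)), key)[unique(key)],
                   function(i) fdm_components(use$p1[i], use$p2[i], use$p3[i]),
                   numeric(3)))
  ord <- match(paste(win$chrom, win$start, sep = ":"), unique(key))
  comp <- comp[ord, , drop = FALSE]
  win$S <- comp[, "S"]
  win$SDp <- comp[, "SDp"]
  win$SDn <- comp[, "SDn"]
  win$weight <- win$w_abba + win$w_baba
  win$D <- ifelse(win$weight > 0,
                  (win$w_abba - win$w_baba) / win$weight, NA_real_)
  if (mode == "haploid") {
    win$fdm <- win$D
  } else {
    win$fdm <- vapply(seq_len(nrow(win)), function(i)
      fdm_value(win$S[i], win$SDp[i], win$SDn[i]), numeric(1))
    win$fdm[win$weight == 0] <- NA_real_
  }
  class(win) <- c("window_stats", class(win))
  attr(win, "fdm_mode") <- mode
  win
}

# genome-wide f_dM from pooled window components (ratio of sums); the
# sign branch is fixed by the pooled numerator
genome_fdm <- function(win) {
  if (identical(attr(win, "fdm_mode"), "haploid")) {
    return(patterson_D(win)$D)
  }
  fdm_value(sum(win$S), sum(win$SDp), sum(win$SDn))
}

#' Weighted block jackknife for a ratio-of-sums statistic
#'
#' Significance for genome-wide D or f_dM from delete-one-block
#' resampling over contiguous genomic blocks. The estimate is the ratio
#' of sums `sum(num)/sum(den)` recomputed after deleting each block; the
#' standard error uses the weighted delete-m_j jackknife variance of
#' Busing et al. (1999): with n blocks of weight w_j summing to W and
#' h_j = W / w_j,
#' `theta_J = n*theta - sum_j (1 - w_j/W) theta_{-j}` and
#' `Var = (1/n) sum_j (h_j*theta - (h_j - 1)*theta_{-j} - theta_J)^2 / (h_j - 1)`.
#' The 95% CI is `theta +/- 1.96 SE` and `Z = theta / SE`.
#'
#' Blocks with zero weight carry no information and are dropped (with a
#' message). Unequal weights reflect unequal numbers of informative sites
#' per block; with equal weights the variance reduces to the ordinary
#' delete-one block jackknife.
#'
#' @param num per-block numerator contributions.
#' @param den per-block denominator contributions.
#' @param weights per-block jackknife weights; defaults to `den` (for D,
#'   the block's ABBA + BABA sum).
#' @return list of class `jackknife_result`: `estimate`, `se`, `ci`
#'   (95%, normal), `z`, `p_value` (two-sided normal), `n_blocks`.
#' @export
weighted_block_jackknife <- function(num, den, weights = den) {
  stopifnot(length(num) == length(den), length(weights) == length(num))
  keep <- !is.na(weights) & weights > 0
  if (any(!keep)) message(sum(!keep), " zero-weight block(s) dropped")
  num <- num[keep]; den <- den[keep]; w <- weights[keep]
  n <- length(num)
  if (n < 2) stop("weighted block jackknife needs at least 2 usable blocks")
  theta <- sum(num) / sum(den)
  theta_mj <- (sum(num) - num) / (sum(den) - den)
  W <- sum(w)
  h <- W / w
  theta_J <- n * theta - sum((1 - w / W) * theta_mj)
  var_j <- sum((h * theta - (h - 1) * theta_mj - theta_J)^2 / (h - 1)) / n
  se <- sqrt(var_j)
  z <- if (se > 0) theta / se else NA_real_
  structure(list(estimate = theta, se = se,
                 ci = c(lo = theta - 1.96 * se, hi = theta + 1.96 * se),
                 z = z,
                 p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                 n_blocks = n),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("estimate %.4f  SE %.4f  95%% CI [%.4f, %.4f]  Z = %.2f  (%d blocks)\n",
              x$estimate, x$se, x$ci[1], x$ci[2], x$z, x$n_blocks))
  invisible(x)
}

#' Jackknife significance of genome-wide D
#'
#' @param win a `window_stats` (or `pattern_counts`) table; each window is
#'   a jackknife block, weighted by its ABBA + BABA sum.
#' @export
jackknife_D <- function(win) {
  weighted_block_jackknife(win$w_abba - win$w_baba, win$w_abba + win$w_baba)
}

#' Jackknife significance of genome-wide f_dM
#'
#' In haploid mode this is identical to [jackknife_D()]. In frequency mode
#' the pooled numerator and sign-matched denominator sums are jackknifed,
#' with the ABBA+BABA window weights.
#' @param win a `window_stats` table.
#' @export
jackknife_fdm <- function(win) {
  if (identical(attr(win, "fdm_mode"), "haploid")) return(jackknife_D(win))
  den <- if (sum(win$S) >= 0) win$SDp else win$SDn
  weighted_block_jackknife(win$S, den, weights = win$w_abba + win$w_baba)
}

#' Attach conditional divergence to windows
#'
#' For each window the "conditional" genetic distance to H3 is the
#' divergence to whichever ingroup taxon shares the derived-allele excess:
#' d(H2, H3) when the window's f_dM is positive, d(H1, H3) when negative.
#' Windows with f_dM exactly zero (or undefined) are flagged ambiguous and
#' get `NA`. Under introgression, windows with strong positive f_dM are
#' expected to show reduced H2–H3 divergence.
#'
#' @param win a `window_stats` table.
#' @param d13,d23 per-window percent divergences aligned with `win` rows
#'   (H1 vs H3, H2 vs H3).
#' @return `win` with columns `cond_div` and `cond_pair` added.
#' @export
conditional_divergence <- function(win, d13, d23) {
  stopifnot(length(d13) == nrow(win), length(d23) == nrow(win))
  pos <- !is.na(win$fdm) & win$fdm > 0
  neg <- !is.na(win$fdm) & win$fdm < 0
  win$cond_div <- ifelse(pos, d23, ifelse(neg, d13, NA_real_))
  win$cond_pair <- ifelse(pos, "H2-H3", ifelse(neg, "H1-H3", "ambiguous"))
  win
}

#' Lineage rate-asymmetry report from tri-allelic counts
#'
#' On a BBBA background (derived allele shared by H1, H2 and H3), a later
#' mutation in the H1 lineage yields a CBBA site and one in the H2 lineage
#' a BCBA site. If H1 and H2 evolve at the same rate the two counts have
#' equal expectation, so their ratio should be near 1 and an exact
#' two-sided binomial test of BCBA successes out of BCBA + CBBA trials at
#' p = 0.5 should be non-significant. A significant excess in one class
#' would indicate a lineage-specific rate difference capable of mimicking
#' gene flow in D.
#'
#' @param counts a `triallelic_counts` row (or anything with `cbba`,
#'   `bcba` and optionally `ccba`, `bbba` fields).
#' @return list of class `rate_asymmetry` with the counts, `ratio`
#'   (BCBA/CBBA), and `p_value` (`NA` with a message when CBBA + BCBA = 0).
#' @export
rate_asymmetry_report <- function(counts) {
  cbba <- as.numeric(counts$cbba)
  bcba <- as.numeric(counts$bcba)
  n <- cbba + bcba
  if (n == 0) {
    message("no CBBA or BCBA sites: rate-asymmetry test skipped")
    p <- NA_real_
  } else {
    p <- stats::binom.test(round(bcba), round(n), p = 0.5)$p.value
  }
  structure(list(cbba = cbba, bcba = bcba,
                 ccba = if (!is.null(counts$ccba)) as.numeric(counts$ccba) else NA_real_,
                 bbba = if (!is.null(counts$bbba)) as.numeric(counts$bbba) else NA_real_,
                 ratio = if (cbba > 0) bcba / cbba else NA_real_,
                 p_value = p),
            class = "rate_asymmetry")
}

#' @export
print.rate_asymmetry <- function(x, ...) {
  cat(sprintf("CBBA = %g, BCBA = %g  (BCBA/CBBA = %.2f), exact binomial p = %.3g\n",
              x$cbba, x$bcba, x$ratio, x$p_value))
  invisible(x)
}
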