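#' Polarize sites against the outgroup
#'
#' Orients each site by taking the outgroup allele as ancestral and
#' computing, for each of H1, H2 and H3, the derived-allele frequency: the
#' fraction of that individual's alleles differing from the ancestral
#' allele (0/0.5/1 for a diploid, 0/1 for a haploid call).
#'
#' Sites are flagged `usable` for the biallelic pattern statistics when
#' all three role samples are called, the ancestral allele is determinable
#' (an unambiguous outgroup call, or the REF base when the outgroup is the
#' reference assembly), and at most two alleles segregate across the
#' quartet. Sites with exactly three segregating alleles get `tri = TRUE`
#' and feed the tri-allelic classifier; sites with four alleles, a missing
#' role call or an ambiguous (heterozygous) outgroup are unusable and
#' counted in the skip log (attribute `"skipped"`).
#'
#' @param table a `genotype_table` with roles assigned.
#' @return A data.frame of class `polarized_sites` with columns `chrom`,
#'   `pos`, `out_allele`, `p1`, `p2`, `p3`, `m1`, `m2`, `m3` (majority
#'   allele per role, `NA` on a 50/50 tie), `n_alleles`, `usable`, `tri`.
#' @export
polarize <- function(table) {
  r <- table$roles
  n <- nrow(table$sites)

  if (identical(r[["outgroup"]], "reference")) {
    out_allele <- table$sites$ref
    out_allele[!out_allele %in% c("A", "C", "G", "T")] <- NA_character_
  } else {
    oa1 <- table$a1[, r[["outgroup"]]]
    oa2 <- table$a2[, r[["outgroup"]]]
    out_allele <- ifelse(is.na(oa1), NA_character_,
                         ifelse(is.na(oa2) | oa1 == oa2, oa1, NA_character_))
  }

  role_allele <- function(role) {
    s <- r[[role]]
    list(a1 = table$a1[, s], a2 = table$a2[, s])
  }
  h1 <- role_allele("H1"); h2 <- role_allele("H2"); h3 <- role_allele("H3")

  freq_derived <- function(h) {
    a2 <- ifelse(is.na(h$a2), h$a1, h$a2)  # haploid counts once, as both
    (as.numeric(h$a1 != out_allele) + as.numeric(a2 != out_allele)) / 2
  }
  maj <- function(h) {
    a2 <- ifelse(is.na(h$a2), h$a1, h$a2)
    ifelse(h$a1 == a2, h$a1, NA_character_)  # single-individual het = tie
  }

  p1 <- freq_derived(h1); p2 <- freq_derived(h2); p3 <- freq_derived(h3)

  allele_mat <- cbind(h1$a1, ifelse(is.na(h1$a2), h1$a1, h1$a2),
                      h2$a1, ifelse(is.na(h2$a2), h2$a1, h2$a2),
                      h3$a1, ifelse(is.na(h3$a2), h3$a1, h3$a2),
                      out_allele)
  n_alleles <- apply(allele_mat, 1L, function(x) length(unique(x[!is.na(x)])))

  called <- !is.na(h1$a1) & !is.na(h2$a1) & !is.na(h3$a1) & !is.na(out_allele)
  usable <- called & n_alleles <= 2L
  tri <- called & n_alleles == 3L

  pol <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                    out_allele = out_allele, p1 = p1, p2 = p2, p3 = p3,
                    m1 = maj(h1), m2 = maj(h2), m3 = maj(h3),
                    n_alleles = n_alleles, usable = usable, tri = tri,
                    stringsAsFactors = FALSE)
  class(pol) <- c("polarized_sites", "data.frame")
  attr(pol, "skipped") <- c(missing_outgroup = sum(is.na(out_allele)),
                            missing_role = sum(!called & !is.na(out_allele)),
                            too_many_alleles = sum(called & n_alleles > 3L))
  pol
}

#' Frequency-weighted four-taxon pattern contributions
#'
#' Per-site contributions to the BBAA/ABBA/BABA tallies from the
#' derived-allele frequencies of H1, H2 and H3:
#' `w_ABBA = (1-p1) p2 p3`, `w_BABA = p1 (1-p2) p3`,
#' `w_BBAA = p1 p2 (1-p3)`. On haploid data (frequencies 0/1) these reduce
#' to 0/1 indicators of the string patterns.
#'
#' @param p1,p2,p3 derived-allele frequencies in `[0, 1]`.
#' @return data.frame with columns `w_bbaa`, `w_abba`, `w_baba`.
#' @export
biallelic_weights <- function(p1, p2, p3) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE),
            all(p3 >= 0 & p3 <= 1, na.rm = TRUE))
  data.frame(w_bbaa = p1 * p2 * (1 - p3),
             w_abba = (1 - p1) * p2 * p3,
             w_baba = p1 * (1 - p2) * p3)
}

#' Classify tri-allelic and fully shared derived site patterns
#'
#' Labels each polarized site using the majority allele per role (m1, m2,
#' m3) against the ancestral outgroup allele A:
#' \describe{
#'   \item{BBBA}{all three roles share one derived allele B.}
#'   \item{CBBA}{H2 and H3 share B while H1 carries a third allele C
#'     (a further mutation on the B background in the H1 lineage).}
#'   \item{BCBA}{as CBBA with the roles of H1 and H2 exchanged.}
#'   \item{CCBA}{H1 and H2 share a third allele C while H3 retains B,
#'     with A, B, C all distinct.}
#' }
#' Any site not matching these (including any role with a 50/50 allele
#' tie) is `"other"`. The CBBA/BCBA balance is the basis of the
#' lineage-rate asymmetry test: under equal rates of evolution in H1 and
#' H2 the two counts have equal expectation.
#'
#' @param pol a `polarized_sites` data.frame.
#' @return character vector of labels.
#' @export
classify_triallelic <- function(pol) {
  m1 <- pol$m1; m2 <- pol$m2; m3 <- pol$m3; A <- pol$out_allele
  lab <- rep("other", nrow(pol))
  ok <- !is.na(m1) & !is.na(m2) & !is.na(m3) & !is.na(A)
  bbba <- ok & m1 == m2 & m2 == m3 & m1 != A
  cbba <- ok & m2 == m3 & m2 != A & m1 != A & m1 != m2
  bcba <- ok & m1 == m3 & m1 != A & m2 != A & m2 != m1
  ccba <- ok & m1 == m2 & m1 != A & m3 != A & m3 != m1
  # the four conditions are mutually exclusive
  lab[cbba] <- "CBBA"
  lab[bcba] <- "BCBA"
  lab[ccba] <- "CCBA"
  lab[bbba] <- "BBBA"
  lab
}

#' Tally tri-allelic pattern counts
#'
#' @param pol a `polarized_sites` data.frame.
#' @return one-row data.frame of class `triallelic_counts` with integer
#'   columns `cbba`, `bcba`, `ccba`, `bbba`.
#' @export
tally_triallelic <- function(pol) {
  lab <- classify_triallelic(pol)
  out <- data.frame(cbba = sum(lab == "CBBA"), bcba = sum(lab == "BCBA"),
                    ccba = sum(lab == "CCBA"), bbba = sum(lab == "BBBA"))
  class(out) <- c("triallelic_counts", "data.frame")
  out
}

# window start for a 1-based position under tiling anchored at position 1
window_start <- function(pos, window_bp) {
  ((pos - 1L) %/% window_bp) * window_bp + 1L
}

#' Tally site-pattern weights in genomic windows
#'
#' Non-overlapping windows of `window_bp` tile each chromosome from
#' position 1; every usable site contributes its pattern weights to
#' exactly one window. In `"hard"` mode a site is instead classified by
#' the majority allele of each role (sites with any 50/50 tie are
#' skipped) and contributes an integer count.
#'
#' @param pol a `polarized_sites` data.frame.
#' @param window_bp window size in bp (default 5,000,000).
#' @param mode `"frequency"` (weighted sums, the default) or `"hard"`.
#' @return data.frame of class `pattern_counts` with columns `chrom`,
#'   `start`, `end`, `w_bbaa`, `w_abba`, `w_baba`, `n_sites`; empty
#'   windows are omitted (their count is attached as attribute
#'   `"n_empty_windows"` where chromosome extents are known).
#' @export
tally_windows <- function(pol, window_bp = 5e6, mode = c("frequency", "hard")) {
  mode <- match.arg(mode)
  stopifnot(window_bp > 0)
  window_bp <- as.integer(window_bp)
  use <- pol[pol$usable, , drop = FALSE]
  if (mode == "frequency") {
    w <- biallelic_weights(use$p1, use$p2, use$p3)
  } else {
    A <- use$out_allele
    hard_ok <- !is.na(use$m1) & !is.na(use$m2) & !is.na(use$m3)
    use <- use[hard_ok, , drop = FALSE]
    A <- A[hard_ok]
    d1 <- use$m1 != A; d2 <- use$m2 != A; d3 <- use$m3 != A
    w <- data.frame(w_bbaa = as.numeric(d1 & d2 & !d3),
                    w_abba = as.numeric(!d1 & d2 & d3),
                    w_baba = as.numeric(d1 & !d2 & d3))
  }
  start <- window_start(use$pos, window_bp)
  key <- paste(use$chrom, start, sep = ":")
  agg <- rowsum(cbind(w, n_sites = 1), key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = use$chrom[first], start = start[first],
                    end = start[first] + window_bp - 1L,
                    agg, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("pattern_counts", "data.frame")
  attr(out, "window_bp") <- window_bp
  out
}
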