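# Fixture builders: small genotype tables and VCF texts constructed in code.

# Build a genotype_table from genotype strings like "A/G", "A" (haploid),
# or NA (missing). gt is a character matrix (sites x samples).
mk_table <- function(pos, gt, chrom = "chr1", ref = NULL,
                     dp = NULL, ad1 = NULL, ad2 = NULL,
                     samples = paste0("s", seq_len(ncol(gt))),
                     sexes = NULL,
                     roles = c(H1 = "s1", H2 = "s2", H3 = "s3",
                               outgroup = "reference"),
                     is_indel = FALSE) {
  gt <- as.matrix(gt)
  n <- length(pos)
  stopifnot(nrow(gt) == n)
  a1 <- a2 <- matrix(NA_character_, n, ncol(gt))
  for (j in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, j], "/", fixed = TRUE)
    a1[, j] <- vapply(parts, function(p) if (length(p)) p[1] else NA_character_, "")
    a2[, j] <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  }
  a1[a1 %in% c(".", "NA") | is.na(gt)] <- NA_character_
  a2[is.na(a1)] <- NA_character_
  if (is.null(ref)) ref <- rep("A", n)
  mkm <- function(m, default) {
    if (is.null(m)) m <- matrix(default, n, ncol(gt))
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  }
  dp <- mkm(dp, 20L)
  dp[is.na(a1)] <- NA_integer_
  genotype_table(
    data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
               ref = rep_len(ref, n), alt = character(n),
               is_indel = rep_len(is_indel, n), stringsAsFactors = FALSE),
    a1, a2, dp, mkm(ad1, 10L), mkm(ad2, 10L),
    samples = samples, sexes = sexes, roles = roles)
}

# Write a small VCF by hand (header plus body rows given as vectors of
# tab-less fields); returns the path.
mk_vcf <- function(rows, samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, ...) {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", "GT:DP:AD", ...),
        collapse = "\t")
}

std_roles <- c(H1 = "s1", H2 = "s2", H3 = "s3", outgroup = "reference")

subset_sites_for_test <- function(table, chrom) {
  quartetflow:::subset_sites(table, which(table$sites$chrom == chrom))
}

# Brute-force delete-one block jackknife for a ratio-of-sums statistic;
# the independent oracle for the weighted jackknife under equal weights.
brute_jackknife <- function(num, den) {
  n <- length(num)
  theta <- sum(num) / sum(den)
  theta_mj <- vapply(seq_len(n),
                     function(j) sum(num[-j]) / sum(den[-j]), numeric(1))
  se <- sqrt((n - 1) / n * sum((theta_mj - mean(theta_mj))^2))
  list(estimate = theta, se = se)
}

# String-pattern oracle: classify a four-taxon haploid allele assignment
# (h1, h2, h3, outgroup) into BBAA/ABBA/BABA by literal letter matching.
string_pattern <- function(h1, h2, h3, o) {
  d <- c(h1, h2, h3) != o
  if (d[1] && d[2] && !d[3] && h1 == h2) return("BBAA")
  if (!d[1] && d[2] && d[3] && h2 == h3) return("ABBA")
  if (d[1] && !d[2] && d[3] && h1 == h3) return("BABA")
  "none"
}
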