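#' Genotype table for a four-taxon quartet
#'
#' The central container of the pipeline: an ordered table of sites with
#' per-sample allele calls and read-depth metadata, plus the sample
#' metadata (sex, taxon role) that downstream sex-aware and four-taxon
#' operations need.
#'
#' Calls are stored as parallel site-by-sample matrices: `a1`/`a2` hold the
#' two called alleles (single bases; `a2` is `NA` for a haploid call and
#' both are `NA` for a missing call), `dp` the total read depth, and
#' `ad1`/`ad2` the per-allele read depths of the called alleles.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated alternate alleles, `""` for an invariant row)
#'   and `is_indel`.
#' @param a1,a2 character matrices of called alleles (sites x samples).
#' @param dp integer matrix of total depths.
#' @param ad1,ad2 integer matrices of allele depths for `a1`/`a2`.
#' @param samples character vector of sample names (column order).
#' @param sexes named character vector, one of `"male"`, `"female"`,
#'   `"unknown"` per sample.
#' @param roles named character vector mapping `H1`, `H2`, `H3` and
#'   `outgroup` to sample names; `outgroup` may be the string
#'   `"reference"`, in which case the ancestral allele is the REF base.
#' @param provenance optional character matrix recording how haploid calls
#'   were derived (`"hom"`, `"depth"`, `"tie"`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, a1, a2, dp, ad1, ad2, samples, sexes,
                           roles, provenance = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "is_indel") %in% names(sites)))
  n <- nrow(sites)
  for (m in list(a1, a2, dp, ad1, ad2)) {
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == length(samples))
  }
  if (n > 0 && any(sites$pos < 1)) stop("positions must be >= 1")
  .check_sorted(sites)
  sexes <- .complete_sexes(sexes, samples)
  .check_roles(roles, samples)
  colnames(a1) <- colnames(a2) <- colnames(dp) <-
    colnames(ad1) <- colnames(ad2) <- samples
  structure(list(sites = sites, a1 = a1, a2 = a2, dp = dp,
                 ad1 = ad1, ad2 = ad2, samples = samples,
                 sexes = sexes, roles = roles, provenance = provenance),
            class = "genotype_table")
}

.check_sorted <- function(sites) {
  if (nrow(sites) < 2) return(invisible(TRUE))
  r <- rle(sites$chrom)
  if (anyDuplicated(r$values))
    stop("input not sorted: chromosome blocks are interleaved")
  d <- unlist(tapply(sites$pos, factor(sites$chrom, levels = r$values), diff),
              use.names = FALSE)
  if (length(d) && any(d <= 0))
    stop("input not sorted: positions must be strictly increasing per chromosome")
  invisible(TRUE)
}

.complete_sexes <- function(sexes, samples) {
  out <- rep("unknown", length(samples))
  names(out) <- samples
  if (!is.null(sexes)) {
    bad <- setdiff(names(sexes), samples)
    if (length(bad)) stop("unknown sample in sexes: ", paste(bad, collapse = ", "))
    stopifnot(all(sexes %in% c("male", "female", "unknown")))
    out[names(sexes)] <- sexes
  }
  out
}

.check_roles <- function(roles, samples) {
  need <- c("H1", "H2", "H3", "outgroup")
  if (!all(need %in% names(roles)))
    stop("roles must name H1, H2, H3 and outgroup")
  ingroup <- roles[c("H1", "H2", "H3")]
  bad <- setdiff(ingroup, samples)
  if (length(bad))
    stop("role assigned to unknown sample: ", paste(bad, collapse = ", "))
  if (anyDuplicated(ingroup)) stop("H1, H2 and H3 must be distinct samples")
  og <- roles[["outgroup"]]
  if (!identical(og, "reference") && !(og %in% samples))
    stop("outgroup must be a sample name or \"reference\"")
  invisible(TRUE)
}

#' Samples that carry a taxon role
#'
#' Returns the sample names assigned to H1/H2/H3 plus the outgroup when the
#' outgroup is a sequenced sample (rather than the reference assembly).
#' @param table a `genotype_table`.
#' @export
role_samples <- function(table) {
  r <- table$roles
  out <- r[c("H1", "H2", "H3")]
  if (!identical(r[["outgroup"]], "reference")) out <- c(out, r["outgroup"])
  unname(out)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites, %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("  roles: %s\n",
              paste(names(x$roles), x$roles, sep = "=", collapse = " ")))
  chroms <- unique(x$sites$chrom)
  cat(sprintf("  chromosomes: %s\n", paste(chroms, collapse = ", ")))
  invisible(x)
}

#' Number of sites in a genotype table
#' @param table a `genotype_table`.
#' @export
n_sites <- function(table) nrow(table$sites)

# Row-subset every parallel component of a table.
subset_sites <- function(table, idx) {
  genotype_table(table$sites[idx, , drop = FALSE],
                 table$a1[idx, , drop = FALSE],
                 table$a2[idx, , drop = FALSE],
                 table$dp[idx, , drop = FALSE],
                 table$ad1[idx, , drop = FALSE],
                 table$ad2[idx, , drop = FALSE],
                 table$samples, table$sexes, table$roles,
                 provenance = if (!is.null(table$provenance))
                   table$provenance[idx, , drop = FALSE])
}

# TRUE where the call is missing (no alleles recorded).
missing_calls <- function(table) is.na(table$a1)

# TRUE where the diploid call is heterozygous.
het_calls <- function(table) {
  !is.na(table$a1) & !is.na(table$a2) & table$a1 != table$a2
}

#' Write a genotype table as TSV
#'
#' One row per site with the per-role allele calls, for inspection or
#' downstream joining.
#' @param table a `genotype_table`.
#' @param path output file path.
#' @export
write_genotype_tsv <- function(table, path) {
  gt <- ifelse(is.na(table$a1), ".",
               ifelse(is.na(table$a2), table$a1,
                      paste0(table$a1, "/", table$a2)))
  df <- cbind(table$sites[, c("chrom", "pos", "ref", "alt")],
              as.data.frame(gt, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
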