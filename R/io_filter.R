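#' Site and genotype filter settings
#'
#' @param min_depth minimum per-genotype read depth; calls below it are set
#'   to missing. Default 5 (a 5X cutoff).
#' @param indel_buffer bp removed on both sides of every indel footprint.
#'   Default 3.
#' @param drop_missing drop sites where any role sample has a missing call.
#' @export
filter_config <- function(min_depth = 5L, indel_buffer = 3L,
                          drop_missing = TRUE) {
  stopifnot(min_depth >= 0, indel_buffer >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 indel_buffer = as.integer(indel_buffer),
                 drop_missing = isTRUE(drop_missing)),
            class = "filter_config")
}

#' Read a multi-sample VCF into a genotype table
#'
#' Ingests a VCF (plain or bgzipped) emitted by a joint genotyper, keeping
#' invariant rows, multi-allelic rows and indel rows; filtering is a
#' separate, explicit step. Parsing is delegated to vcfR.
#'
#' @param vcf_path path to a VCF file with GT, DP and AD FORMAT fields.
#' @param sample_roles named character vector mapping `H1`, `H2`, `H3` and
#'   `outgroup` to sample names; `outgroup = "reference"` uses the REF base
#'   as the ancestral allele (no outgroup sample required).
#' @param sexes optional named character vector (`"male"`/`"female"`/
#'   `"unknown"`) per sample.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(vcf_path, sample_roles, sexes = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  .check_roles(sample_roles, samples)

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  alt[is.na(alt) | alt == "."] <- ""
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  is_indel <- nchar(ref) != 1L |
    vapply(alt_list, function(a) any(a == "*" | nchar(a) != 1L), logical(1))

  n <- length(pos)
  s <- length(samples)
  a1 <- a2 <- matrix(NA_character_, n, s)
  dp <- ad1 <- ad2 <- matrix(NA_integer_, n, s)

  gt_f <- vcfR::extract.gt(vcf, element = "GT")
  dp_f <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad_f <- vcfR::extract.gt(vcf, element = "AD")

  # allele index (0 = REF, k = k-th ALT) -> base, per row
  alleles <- mapply(function(r, a) c(r, a[a != ""]), ref, alt_list,
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)

  for (j in seq_len(s)) {
    g <- gt_f[, j]
    parts <- strsplit(g, "[/|]")
    i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    i2raw <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                    "")
    i2 <- suppressWarnings(as.integer(i2raw))
    ok1 <- !is.na(i1)
    b1 <- rep(NA_character_, n)
    b2 <- rep(NA_character_, n)
    b1[ok1] <- mapply(function(al, i) al[i + 1L], alleles[ok1], i1[ok1])
    ok2 <- !is.na(i2)
    b2[ok2] <- mapply(function(al, i) al[i + 1L], alleles[ok2], i2[ok2])
    # spanning-deletion allele is indel evidence, not a usable base call
    span <- (!is.na(b1) & b1 == "*") | (!is.na(b2) & b2 == "*")
    b1[span] <- NA_character_
    b2[span] <- NA_character_
    b2[is.na(b1)] <- NA_character_
    a1[, j] <- b1
    a2[, j] <- b2
    dp[, j] <- as.integer(dp_f[, j])
    adp <- strsplit(ad_f[, j], ",", fixed = TRUE)
    has_ad <- !is.na(ad_f[, j]) & !is.na(b1)
    idx <- which(has_ad)
    if (length(idx)) {
      ad1[idx, j] <- mapply(function(v, i) suppressWarnings(as.integer(v[i + 1L])),
                            adp[idx], i1[idx])
      ad2[idx, j] <- ifelse(is.na(i2[idx]), NA_integer_,
                            mapply(function(v, i) {
                              if (is.na(i)) NA_integer_
                              else suppressWarnings(as.integer(v[i + 1L]))
                            }, adp[idx], i2[idx]))
    }
  }
  dp[is.na(a1)] <- NA_integer_

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      is_indel = is_indel, stringsAsFactors = FALSE)
  genotype_table(sites, a1, a2, dp, ad1, ad2, samples, sexes, sample_roles)
}

#' Build a removal mask around indel sites
#'
#' Every indel row's reference footprint (POS through POS + nchar(REF) - 1)
#' is extended by `buffer` bp in both directions; overlapping intervals are
#' merged.
#'
#' @param table a `genotype_table` read without dropping indel rows.
#' @param buffer bp added on both sides (default 3).
#' @return A [mask_set()].
#' @export
build_indel_mask <- function(table, buffer = 3L) {
  idx <- which(table$sites$is_indel)
  if (!length(idx)) return(mask_set())
  positions_to_mask(table$sites$chrom[idx], table$sites$pos[idx],
                    buffer = as.integer(buffer),
                    ref_len = nchar(table$sites$ref[idx]))
}

#' Remove masked sites from a genotype table
#'
#' Drops every site whose position falls inside any of the given masks.
#' Idempotent. A mask chromosome absent from the table triggers a warning,
#' not an error.
#'
#' @param table a `genotype_table`.
#' @param ... one or more `mask_set` objects.
#' @export
apply_masks <- function(table, ...) {
  masks <- list(...)
  if (!length(masks)) return(table)
  mask <- do.call(merge_masks, masks)
  extra <- setdiff(unique(mask$intervals$chrom), unique(table$sites$chrom))
  if (length(extra))
    warning("mask chromosome(s) not present in table: ",
            paste(extra, collapse = ", "))
  hit <- mask_covers(mask, table$sites$chrom, table$sites$pos)
  subset_sites(table, which(!hit))
}

#' Apply depth and missingness filters to genotypes
#'
#' Genotype calls with depth below `min_depth` are set to missing; when
#' `drop_missing` is set, any site with a missing call in a role sample is
#' removed entirely (a reference outgroup carries no depth and is never
#' filtered).
#'
#' @param table a `genotype_table`.
#' @param config a [filter_config()].
#' @export
filter_genotypes <- function(table, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  low <- !is.na(table$dp) & table$dp < config$min_depth
  table$a1[low] <- NA_character_
  table$a2[low] <- NA_character_
  table$ad1[low] <- NA_integer_
  table$ad2[low] <- NA_integer_
  table$dp[low] <- NA_integer_
  if (config$drop_missing) {
    rs <- role_samples(table)
    miss <- missing_calls(table)[, rs, drop = FALSE]
    keep <- rowSums(miss) == 0L
    table <- subset_sites(table, which(keep))
  }
  table
}
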