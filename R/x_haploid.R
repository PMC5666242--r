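#' Pseudoautosomal region settings for the X chromosome
#'
#' @param x_chrom_name chromosome name carrying the X data.
#' @param par_boundary last 1-based position of the pseudoautosomal region;
#'   sites at or below it are PAR. The default (403495) is the boundary in
#'   the rhemac2 rhesus assembly used as the mapping reference.
#' @export
par_config <- function(x_chrom_name = "chrX", par_boundary = 403495L) {
  stopifnot(par_boundary >= 1)
  structure(list(x_chrom_name = x_chrom_name,
                 par_boundary = as.integer(par_boundary)),
            class = "par_config")
}

#' Haploidize diploid calls by depth of coverage
#'
#' Infers a single allele per site per sample from a diploid call: the
#' allele with the highest allele depth is retained; exact depth ties are
#' broken by a seeded uniform random choice. Homozygous calls pass through
#' unchanged. Intended for hemizygous regions (the X in males) where an
#' apparent heterozygote must be one allele or the other.
#'
#' The tie-break RNG runs in its own seeded stream (the caller's RNG state
#' is untouched), so identical seeds give identical haploid calls
#' regardless of unrelated randomness.
#'
#' @param table a `genotype_table` with allele depths.
#' @param seed integer seed for the tie-break stream.
#' @param samples samples to haploidize (default: all).
#' @return A `genotype_table` whose haploidized calls carry a single allele
#'   and a `provenance` matrix (`"hom"`, `"depth"` or `"tie"`).
#' @export
haploidize_by_depth <- function(table, seed, samples = table$samples) {
  stopifnot(all(samples %in% table$samples))
  prov <- table$provenance
  if (is.null(prov))
    prov <- matrix(NA_character_, nrow(table$a1), ncol(table$a1),
                   dimnames = dimnames(table$a1))
  cols <- match(samples, table$samples)
  het <- het_calls(table)[, cols, drop = FALSE]
  if (any(het & (is.na(table$ad1[, cols, drop = FALSE]) |
                 is.na(table$ad2[, cols, drop = FALSE]))))
    stop("allele depths (AD) absent for heterozygous calls: ",
         "haploidization by depth needs them; use diploid mode instead")

  for (j in cols) {
    h <- which(het_calls(table)[, j])
    called <- which(!is.na(table$a1[, j]))
    prov[called, j] <- "hom"
    if (length(h)) {
      d1 <- table$ad1[h, j]
      d2 <- table$ad2[h, j]
      pick2 <- d2 > d1
      tie <- d1 == d2
      if (any(tie)) {
        coin <- withr::with_seed(seed, stats::runif(length(h)) < 0.5)
        pick2[tie] <- coin[tie]
      }
      prov[h, j] <- ifelse(tie, "tie", "depth")
      keep <- ifelse(pick2, table$a2[h, j], table$a1[h, j])
      keepd <- ifelse(pick2, table$ad2[h, j], table$ad1[h, j])
      table$a1[h, j] <- keep
      table$ad1[h, j] <- keepd
    }
    # collapse to a single recorded allele
    nonmiss <- !is.na(table$a1[, j])
    table$a2[nonmiss, j] <- NA_character_
    table$ad2[nonmiss, j] <- NA_integer_
  }
  table$provenance <- prov
  table
}

#' Remove sites around male heterozygous genotypes
#'
#' In a hemizygous region a male heterozygote is an artefact (mismapped
#' Y-chromosome reads or genotyping error). Every site at which any listed
#' male is heterozygous is removed together with `buffer` bp on both sides;
#' nearby removal intervals merge. Idempotent, and commutes with
#' [apply_masks()].
#'
#' @param table a `genotype_table` with diploid calls.
#' @param male_samples samples to screen; each must be flagged `"male"` in
#'   the table's sex metadata.
#' @param buffer bp removed on both sides of each male-het site (default 3).
#' @return The filtered `genotype_table`, with the removal mask attached as
#'   attribute `"male_het_mask"`.
#' @export
mask_male_het <- function(table, male_samples, buffer = 3L) {
  stopifnot(all(male_samples %in% table$samples))
  notmale <- male_samples[table$sexes[male_samples] != "male"]
  if (length(notmale))
    stop("sample(s) not flagged male: ", paste(notmale, collapse = ", "))
  het <- het_calls(table)[, male_samples, drop = FALSE]
  idx <- which(rowSums(het) > 0L)
  mask <- positions_to_mask(table$sites$chrom[idx], table$sites$pos[idx],
                            buffer = as.integer(buffer))
  out <- if (length(idx)) apply_masks(table, mask) else table
  attr(out, "male_het_mask") <- mask
  out
}

#' Split X-chromosome sites at the pseudoautosomal boundary
#'
#' Sites at positions up to and including the boundary go to the PAR
#' partition (where males are effectively diploid); the rest to the
#' non-PAR partition. The two partitions are disjoint and exhaustive.
#'
#' @param table a `genotype_table` restricted to the X chromosome.
#' @param par a [par_config()].
#' @return A list with elements `par` and `nonpar`.
#' @export
split_par <- function(table, par = par_config()) {
  on_x <- table$sites$chrom == par$x_chrom_name
  if (!all(on_x)) table <- subset_sites(table, which(on_x))
  in_par <- table$sites$pos <= par$par_boundary
  list(par = subset_sites(table, which(in_par)),
       nonpar = subset_sites(table, which(!in_par)))
}

#' Heterozygote sharing across samples
#'
#' For every non-empty subset of the given samples, counts the sites that
#' are heterozygous in exactly that subset (the cells of an Euler diagram
#' of het sharing), plus each sample's heterozygosity rate
#' (het sites / called sites). Used to diagnose pseudo-heterozygous calls
#' on the male non-PAR X, where shared male hets point to systematic
#' artefacts rather than real variation.
#'
#' @param table a `genotype_table` with diploid calls.
#' @param samples samples to tabulate (default: all).
#' @return list with `counts` (named by subsets like `"A&B"`), `rates`
#'   (per sample), and `n_het_sites` (sites het in at least one sample).
#' @export
het_overlap_counts <- function(table, samples = table$samples) {
  stopifnot(all(samples %in% table$samples))
  het <- het_calls(table)[, samples, drop = FALSE]
  called <- !missing_calls(table)[, samples, drop = FALSE]
  k <- length(samples)
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(samples, m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  any_het <- which(rowSums(het) > 0L)
  if (length(any_het)) {
    key <- apply(het[any_het, , drop = FALSE], 1L,
                 function(r) paste(samples[r], collapse = "&"))
    tab <- table(key)
    counts[names(tab)] <- as.integer(tab)
  }
  rates <- colSums(het) / pmax(colSums(called), 1L)
  rates[colSums(called) == 0L] <- NA_real_
  list(counts = counts, rates = rates, n_het_sites = length(any_het))
}
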