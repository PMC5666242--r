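#' Run the full gene-flow analysis pipeline
#'
#' Chains the stages: ingest (or accept a pre-built table), indel and
#' repeat masking, depth/missingness filtering, sex-aware X handling
#' (male-het exclusion and haploidization by depth), polarization,
#' windowed pattern tallies, D and f_dM with weighted block jackknife,
#' the tri-allelic rate-asymmetry report, and per-window conditional
#' divergence. Per-stage site counts are recorded so filter attrition is
#' auditable.
#'
#' @param input a `genotype_table`, or a VCF path (then `roles` and
#'   `sexes` are required).
#' @param roles,sexes passed to [read_genotypes()] when `input` is a path.
#' @param repeat_bed optional BED file of repeat intervals to mask.
#' @param filter a [filter_config()].
#' @param x_handling handle X-chromosome sites sex-aware: one of
#'   `"haploid-all"` (haploidize every sample on X, the default),
#'   `"haploid-males-diploid-female"`, or `"none"`.
#' @param par a [par_config()]; non-PAR X only is used for the X
#'   statistics, and X handling applies when `par$x_chrom_name` is
#'   present in the data.
#' @param mask_male_hets remove male-heterozygote sites (plus buffer)
#'   before haploidizing the X.
#' @param mask_female_hets also remove female-heterozygote sites (plus
#'   buffer) — a conservative variant.
#' @param het_buffer bp buffer around removed het sites.
#' @param window_bp window size for windowed statistics.
#' @param fdm_mode f_dM mode passed to [window_stats()].
#' @param seed seed for the haploidization tie-break stream.
#' @param out_dir if given, TSV/JSON outputs are written there.
#' @return list of class `pipeline_result`: `summary` (genome-wide D and
#'   f_dM with jackknife CIs, pattern totals, tri-allelic counts and the
#'   rate test), `windows` (per-window stats with conditional divergence),
#'   `het_overlap` (non-PAR X het sharing, when X is present),
#'   `attrition` (site counts per stage), and the filtered `table`.
#' @export
run_pipeline <- function(input, roles = NULL, sexes = NULL,
                         repeat_bed = NULL,
                         filter = filter_config(),
                         x_handling = c("haploid-all",
                                        "haploid-males-diploid-female",
                                        "none"),
                         par = par_config(),
                         mask_male_hets = TRUE,
                         mask_female_hets = FALSE,
                         het_buffer = 3L,
                         window_bp = 5e6,
                         fdm_mode = "auto",
                         seed = 1L,
                         out_dir = NULL) {
  x_handling <- match.arg(x_handling)
  table <- if (inherits(input, "genotype_table")) input
           else read_genotypes(input, roles, sexes)
  attrition <- c(ingested = n_sites(table))

  masks <- list(build_indel_mask(table, filter$indel_buffer))
  if (!is.null(repeat_bed)) masks <- c(masks, list(read_bed_mask(repeat_bed)))
  table <- do.call(apply_masks, c(list(table), masks))
  attrition <- c(attrition, masked = n_sites(table))

  table <- filter_genotypes(table, filter)
  attrition <- c(attrition, depth_filtered = n_sites(table))

  het_overlap <- NULL
  on_x <- table$sites$chrom == par$x_chrom_name
  if (any(on_x) && x_handling != "none") {
    xt <- subset_sites(table, which(on_x))
    auto <- subset_sites(table, which(!on_x))
    parts <- split_par(xt, par)
    xt <- parts$nonpar  # PAR excluded from X gene-flow statistics
    het_overlap <- het_overlap_counts(xt)
    males <- names(table$sexes)[table$sexes == "male"]
    males <- intersect(males, role_samples(table))
    if (mask_male_hets && length(males))
      xt <- mask_male_het(xt, males, buffer = het_buffer)
    if (mask_female_hets) {
      females <- intersect(names(table$sexes)[table$sexes == "female"],
                           role_samples(table))
      # same exclusion logic, applied to the female's het sites
      if (length(females)) {
        fh <- het_calls(xt)[, females, drop = FALSE]
        idx <- which(rowSums(fh) > 0L)
        if (length(idx))
          xt <- apply_masks(xt, positions_to_mask(xt$sites$chrom[idx],
                                                  xt$sites$pos[idx],
                                                  buffer = het_buffer))
      }
    }
    hap_samples <- if (x_handling == "haploid-all") xt$samples
                   else names(xt$sexes)[xt$sexes == "male"]
    xt <- haploidize_by_depth(xt, seed = seed, samples = hap_samples)
    attrition <- c(attrition, x_after_het_mask = n_sites(xt))
    table <- .bind_tables(auto, xt)
  }

  pol <- polarize(table)
  win <- window_stats(pol, window_bp = window_bp, mode = fdm_mode)
  d <- patterson_D(win)
  jk_d <- if (nrow(win) >= 2) jackknife_D(win) else NULL
  jk_f <- if (nrow(win) >= 2) jackknife_fdm(win) else NULL
  tri <- tally_triallelic(pol)
  rate <- rate_asymmetry_report(tri)

  r <- table$roles
  d13 <- window_divergence(table, r[["H1"]], r[["H3"]], window_bp = window_bp)
  d23 <- window_divergence(table, r[["H2"]], r[["H3"]], window_bp = window_bp)
  key <- function(w) paste(w$chrom, w$start)
  win <- conditional_divergence(win,
                                d13$divergence[match(key(win), key(d13))],
                                d23$divergence[match(key(win), key(d23))])

  summary <- list(
    D = d$D, abba = d$abba, baba = d$baba, bbaa = sum(win$w_bbaa),
    fdm = genome_fdm(win),
    fdm_mode = attr(win, "fdm_mode"),
    D_jackknife = jk_d, fdm_jackknife = jk_f,
    triallelic = as.list(tri), rate_test = unclass(rate),
    n_windows = nrow(win), attrition = attrition)

  out <- structure(list(summary = summary, windows = win,
                        het_overlap = het_overlap, attrition = attrition,
                        table = table),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("D = %.4f (ABBA %.1f, BABA %.1f), f_dM = %.4f [%s mode], %d windows\n",
              s$D, s$abba, s$baba, s$fdm, s$fdm_mode, s$n_windows))
  if (!is.null(s$fdm_jackknife)) {
    cat("f_dM jackknife: ")
    print(s$fdm_jackknife)
  }
  cat("attrition: ", paste(names(x$attrition), x$attrition, sep = "=",
                           collapse = "  "), "\n")
  invisible(x)
}

.bind_tables <- function(a, b) {
  stopifnot(identical(a$samples, b$samples))
  bindm <- function(f) rbind(a[[f]], b[[f]])
  prov <- if (!is.null(a$provenance) || !is.null(b$provenance)) {
    pa <- a$provenance
    pb <- b$provenance
    if (is.null(pa)) pa <- matrix(NA_character_, n_sites(a), length(a$samples))
    if (is.null(pb)) pb <- matrix(NA_character_, n_sites(b), length(b$samples))
    rbind(pa, pb)
  }
  sites <- rbind(a$sites, b$sites)
  rownames(sites) <- NULL
  genotype_table(sites, bindm("a1"), bindm("a2"), bindm("dp"),
                 bindm("ad1"), bindm("ad2"), a$samples, a$sexes, a$roles,
                 provenance = prov)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  win <- as.data.frame(res$windows)
  utils::write.table(win, file.path(out_dir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- res$summary
  s$D_jackknife <- if (!is.null(s$D_jackknife)) unclass(s$D_jackknife)
  s$fdm_jackknife <- if (!is.null(s$fdm_jackknife)) unclass(s$fdm_jackknife)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$het_overlap)) {
    ho <- data.frame(subset = names(res$het_overlap$counts),
                     n_sites = as.integer(res$het_overlap$counts))
    utils::write.table(ho, file.path(out_dir, "het_overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
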