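#' Configuration for the synthetic four-taxon generator
#'
#' The generator draws independent sites from a categorical site-pattern
#' model of a four-taxon quartet with incomplete lineage sorting (ILS) and
#' directed H3-to-H2 introgression, then renders them as diploid genotype
#' calls with realistic depth, allele-depth, sex-linked error and
#' missingness structure. Because the model is categorical, the expected
#' genome-wide D has a closed form (see [expected_D()]), which anchors
#' recovery tests.
#'
#' Site topology model: with probability `gamma` a site's history is the
#' introgressed one (H2 grouping with H3), otherwise the species history
#' (H1 grouping with H2). Within each history, ILS randomizes the
#' grouping uniformly over the three topologies with probability `rho`
#' (species) or `rho_i` (introgressed). The resulting pattern classes are
#' BBAA, ABBA and BABA; tri-allelic (CBBA/BCBA/CCBA, equiprobable) and
#' BBBA sites are injected at their configured rates.
#'
#' @param chromosomes named numeric vector of chromosome lengths; the
#'   default has one autosome-like and one X-like chromosome.
#' @param x_chrom which chromosome carries X-like (hemizygous-male)
#'   behaviour.
#' @param n_sites sites simulated per chromosome.
#' @param rho,rho_i ILS fractions of the species and introgressed
#'   histories.
#' @param gamma introgression fraction (H3 into H2).
#' @param tri_rate,bbba_rate per-site injection rates of tri-allelic and
#'   BBBA patterns.
#' @param mean_depth mean per-call read depth (40, matching deep
#'   whole-genome coverage).
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   distribution (smaller = more overdispersed).
#' @param male_het_error probability a male hemizygous call on the
#'   non-pseudoautosomal X is rendered as a pseudo-heterozygous diploid
#'   call (default 0.0005, i.e. 0.05%).
#' @param female_het probability a female X call is a true heterozygote.
#' @param missing_rate per-call missingness.
#' @param par_boundary pseudoautosomal boundary on the X-like chromosome.
#' @param samples,sexes sample names and sexes for H1, H2, H3 (defaults: a
#'   female H1 and male H2, H3, mirroring a crested-macaque /
#'   tonkean-macaque / pigtail-macaque quartet against a reference-genome
#'   outgroup).
#' @param window_bp window size used by block-introgression mode.
#' @param intro_window_frac if non-`NA`, fraction of windows that are
#'   introgressed: `gamma` applies only inside those windows (block
#'   mode), zero elsewhere. Default `NA` (every site draws with `gamma`).
#' @param seed integer seed; all generator randomness derives from it.
#' @export
sim_config <- function(chromosomes = c(chr1 = 5e7, chrX = 5e7),
                       x_chrom = "chrX",
                       n_sites = 10000L,
                       rho = 0.3, rho_i = 0.3, gamma = 0,
                       tri_rate = 0.01, bbba_rate = 0.05,
                       mean_depth = 40, depth_dispersion = 10,
                       male_het_error = 5e-4, female_het = 1e-3,
                       missing_rate = 0.002,
                       par_boundary = 403495L,
                       samples = c(H1 = "nigra_F1", H2 = "tonkeana_M1",
                                   H3 = "nemestrina_M1"),
                       sexes = c("female", "male", "male"),
                       window_bp = 5e6,
                       intro_window_frac = NA_real_,
                       seed = 1L) {
  rates <- c(rho = rho, rho_i = rho_i, gamma = gamma, tri_rate = tri_rate,
             bbba_rate = bbba_rate, male_het_error = male_het_error,
             female_het = female_het, missing_rate = missing_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]")
  if (tri_rate + bbba_rate > 1)
    stop("tri_rate + bbba_rate must not exceed 1")
  stopifnot(length(samples) == 3, length(sexes) == 3, n_sites >= 0)
  cfg <- list(chromosomes = chromosomes, x_chrom = x_chrom,
              n_sites = as.integer(n_sites), rho = rho, rho_i = rho_i,
              gamma = gamma, tri_rate = tri_rate, bbba_rate = bbba_rate,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              male_het_error = male_het_error, female_het = female_het,
              missing_rate = missing_rate,
              par_boundary = as.integer(par_boundary),
              samples = samples, sexes = stats::setNames(sexes, samples),
              window_bp = window_bp, intro_window_frac = intro_window_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Closed-form expected D of the categorical model
#'
#' `E[D] = g / (g + 2 m / 3)` with `g = gamma (1 - rho_i)` (the excess
#' ABBA mass from introgressed, non-ILS sites) and
#' `m = (1 - gamma) rho + gamma rho_i` (the symmetric ILS mass split
#' equally across the three topologies).
#'
#' @param gamma introgression fraction.
#' @param rho,rho_i ILS fractions.
#' @export
expected_D <- function(gamma, rho = 0.3, rho_i = 0.3) {
  g <- gamma * (1 - rho_i)
  m <- (1 - gamma) * rho + gamma * rho_i
  if (g + 2 * m / 3 == 0) return(0)
  g / (g + 2 * m / 3)
}

# biallelic topology-class probabilities (BBAA/ABBA/BABA) given gamma
.topology_probs <- function(gamma, rho, rho_i) {
  ils <- (1 - gamma) * rho + gamma * rho_i
  abba <- gamma * (1 - rho_i) + ils / 3
  baba <- ils / 3
  bbaa <- 1 - abba - baba
  c(BBAA = bbaa, ABBA = abba, BABA = baba)
}

# full site-class probabilities including injected tri-allelic and BBBA
pattern_class_probs <- function(config, gamma = config$gamma) {
  rest <- 1 - config$tri_rate - config$bbba_rate
  top <- .topology_probs(gamma, config$rho, config$rho_i) * rest
  c(top,
    BBBA = config$bbba_rate,
    CBBA = config$tri_rate / 3, BCBA = config$tri_rate / 3,
    CCBA = config$tri_rate / 3)
}

.BASES <- c("A", "C", "G", "T")

#' Simulate four-taxon site patterns
#'
#' Draws site positions and pattern classes per chromosome and renders
#' them as (pseudo-)diploid homozygous genotype calls polarized so that
#' the reference base is the ancestral allele — the table's outgroup role
#' is `"reference"`. Depths, sex-linked errors and missingness are added
#' separately by [attach_depths_and_errors()].
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [genotype_table()]) and `truth` (class
#'   `sim_truth`: per-site `class`, ancestral and derived alleles; the
#'   per-window introgression status in block mode; the config; and the
#'   closed-form `expected_d`).
#' @export
simulate_patterns <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_patterns_impl(config))
}

.simulate_patterns_impl <- function(config) {
  classes <- names(pattern_class_probs(config))
  per_chrom <- lapply(names(config$chromosomes), function(ch) {
    len <- config$chromosomes[[ch]]
    n <- min(config$n_sites, len)
    if (n == 0)
      return(list(sites = data.frame(chrom = character(), pos = integer(),
                                     anc = character(), der = character(),
                                     third = character(), class = character(),
                                     stringsAsFactors = FALSE),
                  windows = NULL))
    pos <- sort(sample.int(len, n))
    if (is.na(config$intro_window_frac)) {
      cls <- sample(classes, n, replace = TRUE,
                    prob = pattern_class_probs(config))
      windows <- NULL
    } else {
      wstart <- window_start(pos, as.integer(config$window_bp))
      uw <- unique(wstart)
      intro <- stats::runif(length(uw)) < config$intro_window_frac
      names(intro) <- uw
      p_in <- pattern_class_probs(config, gamma = config$gamma)
      p_out <- pattern_class_probs(config, gamma = 0)
      cls <- character(n)
      is_in <- intro[as.character(wstart)]
      cls[is_in] <- sample(classes, sum(is_in), replace = TRUE, prob = p_in)
      cls[!is_in] <- sample(classes, sum(!is_in), replace = TRUE, prob = p_out)
      windows <- data.frame(chrom = ch, start = uw,
                            end = uw + as.integer(config$window_bp) - 1L,
                            introgressed = unname(intro))
    }
    anc <- sample(.BASES, n, replace = TRUE)
    der <- vapply(anc, function(a) sample(setdiff(.BASES, a), 1L), "")
    third <- mapply(function(a, b) sample(setdiff(.BASES, c(a, b)), 1L),
                    anc, der, USE.NAMES = FALSE)
    list(sites = data.frame(chrom = ch, pos = pos, anc = anc, der = der,
                            third = third, class = cls,
                            stringsAsFactors = FALSE),
         windows = windows)
  })
  st <- do.call(rbind, lapply(per_chrom, `[[`, "sites"))
  windows <- do.call(rbind, lapply(per_chrom, `[[`, "windows"))

  # allele carried by each taxon, by pattern class
  pick <- function(class, anc, der, third, slot) {
    # slot: 1 = H1, 2 = H2, 3 = H3
    code <- c(BBAA = "BBA", ABBA = "ABB", BABA = "BAB", BBBA = "BBB",
              CBBA = "CBB", BCBA = "BCB", CCBA = "CCB")[class]
    ch <- substr(code, slot, slot)
    ifelse(ch == "A", anc, ifelse(ch == "B", der, third))
  }
  n <- nrow(st)
  a <- matrix(NA_character_, n, 3)
  for (slot in 1:3)
    a[, slot] <- pick(st$class, st$anc, st$der, st$third, slot)

  sites <- data.frame(chrom = st$chrom, pos = st$pos, ref = st$anc,
                      alt = character(n), is_indel = logical(n),
                      stringsAsFactors = FALSE)
  empty <- matrix(NA_integer_, n, 3)
  table <- genotype_table(sites, a1 = a, a2 = a,
                          dp = empty, ad1 = empty, ad2 = empty,
                          samples = unname(config$samples),
                          sexes = config$sexes,
                          roles = c(config$samples, outgroup = "reference"))
  table <- .recompute_alt(table)
  truth <- structure(list(sites = st[, c("chrom", "pos", "anc", "der",
                                         "third", "class")],
                          windows = windows, config = config,
                          expected_d = expected_D(
                            if (is.na(config$intro_window_frac)) config$gamma
                            else config$gamma * config$intro_window_frac,
                            config$rho, config$rho_i)),
                     class = "sim_truth")
  list(table = table, truth = truth)
}

#' Attach read depths, sex-linked errors and missingness
#'
#' Renders the generator's clean genotype calls as realistic sequencing
#' output: per-call total depth from a negative binomial around the mean;
#' allele depths consistent with the emitted genotype; true heterozygous
#' calls injected for the female on the X at the configured rate; male
#' hemizygous calls on the non-pseudoautosomal X rendered as
#' pseudo-heterozygous diploid calls (minor allele depth drawn low) at the
#' configured error rate; and missing calls at the configured rate.
#' Randomness derives from `config$seed` (offset so it does not replay the
#' pattern draw).
#'
#' @param table table from [simulate_patterns()].
#' @param config the same [sim_config()].
#' @return The table with `dp`, `ad1`, `ad2` filled and errors injected.
#' @export
attach_depths_and_errors <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1003L, .attach_impl(table, config))
}

.attach_impl <- function(table, config) {
  n <- n_sites(table)
  s <- length(table$samples)
  if (n == 0) return(table)
  dp <- matrix(stats::rnbinom(n * s, mu = config$mean_depth,
                              size = config$depth_dispersion), n, s)
  storage.mode(dp) <- "integer"
  colnames(dp) <- table$samples
  on_x <- table$sites$chrom == config$x_chrom
  nonpar_x <- on_x & table$sites$pos > config$par_boundary
  # partner allele for an injected het: the other allele segregating at
  # the site (ancestral if the carrier is derived, else the derived base)
  partner <- function(cur, i) ifelse(cur == table$sites$ref[i],
                                     .derived_at(table, i), table$sites$ref[i])

  for (j in seq_len(s)) {
    sex <- table$sexes[[table$samples[j]]]
    het <- logical(n)
    if (sex == "female") {
      cand <- which(on_x)
      het[cand] <- stats::runif(length(cand)) < config$female_het
    } else if (sex == "male") {
      cand <- which(nonpar_x)
      het[cand] <- stats::runif(length(cand)) < config$male_het_error
    }
    hi <- which(het)
    if (length(hi)) {
      prt <- partner(table$a1[hi, j], hi)
      ok <- !is.na(prt) & prt != table$a1[hi, j]
      hi <- hi[ok]
      prt <- prt[ok]
    }
    if (length(hi)) {
      table$a2[hi, j] <- prt
      pfrac <- if (sex == "female") 0.5 else 0.25
      d <- pmax(dp[hi, j], 2L)
      dp[hi, j] <- d
      minor <- pmin(pmax(stats::rbinom(length(hi), d, pfrac), 1L), d - 1L)
      table$ad2[hi, j] <- minor
      table$ad1[hi, j] <- d - minor
    }
    hom <- which(!het)
    table$ad1[hom, j] <- dp[hom, j]
    table$ad2[hom, j] <- dp[hom, j]
    miss <- dp[, j] == 0L | stats::runif(n) < config$missing_rate
    table$a1[miss, j] <- NA_character_
    table$a2[miss, j] <- NA_character_
    table$ad1[miss, j] <- NA_integer_
    table$ad2[miss, j] <- NA_integer_
    dp[miss, j] <- NA_integer_
  }
  table$dp <- dp
  .recompute_alt(table)
}

# refresh the ALT column from the alleles actually called at each site
.recompute_alt <- function(table) {
  n <- n_sites(table)
  if (n == 0) return(table)
  ref <- table$sites$ref
  ab <- cbind(table$a1, table$a2)
  table$sites$alt <- vapply(seq_len(n), function(i) {
    alts <- sort(setdiff(unique(ab[i, !is.na(ab[i, ])]), ref[i]))
    paste(alts, collapse = ",")
  }, "")
  table
}

# the non-reference allele segregating at site rows i (first role column
# carrying one; NA if the site is invariant across roles)
.derived_at <- function(table, i) {
  out <- rep(NA_character_, length(i))
  for (j in seq_along(table$samples)) {
    a <- table$a1[i, j]
    hit <- is.na(out) & !is.na(a) & a != table$sites$ref[i]
    out[hit] <- a[hit]
  }
  out[is.na(out)] <- table$sites$ref[i][is.na(out)]
  out
}

#' Simulate per-block pattern counts directly
#'
#' A fast path through the same categorical model: instead of rendering
#' per-sample genotypes, draws multinomial pattern-class counts for each
#' of `n_blocks` equal blocks of `config$n_sites` total sites. Used for
#' calibration studies (many replicates of the jackknife) where the
#' genotype-level detail is irrelevant.
#'
#' @param config a [sim_config()]; `n_sites` is the total across blocks.
#' @param n_blocks number of blocks.
#' @return data.frame with one row per block: `block`, `w_bbaa`,
#'   `w_abba`, `w_baba`, `tri`, `bbba`.
#' @export
simulate_block_counts <- function(config, n_blocks = 20L) {
  stopifnot(inherits(config, "sim_config"), n_blocks >= 1)
  probs <- pattern_class_probs(config)
  probs <- c(probs["BBAA"], probs["ABBA"], probs["BABA"],
             tri = unname(probs["CBBA"] + probs["BCBA"] + probs["CCBA"]),
             BBBA = unname(probs["BBBA"]))
  sizes <- diff(round(seq(0, config$n_sites, length.out = n_blocks + 1)))
  withr::with_seed(config$seed, {
    m <- vapply(sizes, function(sz) stats::rmultinom(1, sz, probs)[, 1],
                numeric(5))
  })
  data.frame(block = seq_len(n_blocks),
             w_bbaa = m[1, ], w_abba = m[2, ], w_baba = m[3, ],
             tri = m[4, ], bbba = m[5, ])
}

#' Write a simulated dataset to disk
#'
#' Emits a plain-text VCF (GT:DP:AD, reference allele = ancestral), the
#' per-site truth as TSV, the per-window truth (block mode) as TSV, and
#' the configuration as JSON. Output is deterministic: the same table
#' writes byte-identical files.
#'
#' @param table a `genotype_table` from the generator.
#' @param truth the matching `sim_truth`.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) named vector of file paths.
#' @export
write_simulation <- function(table, truth, out_dir) {
  stopifnot(inherits(truth, "sim_truth"),
            nrow(truth$sites) == n_sites(table))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(out_dir, "sim.vcf")
  write_vcf(table, vcf)
  truth_path <- file.path(out_dir, "truth_sites.tsv")
  utils::write.table(truth$sites, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(vcf = vcf, truth = truth_path)
  if (!is.null(truth$windows)) {
    wp <- file.path(out_dir, "truth_windows.tsv")
    utils::write.table(truth$windows, wp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, windows = wp)
  }
  cfg_path <- file.path(out_dir, "sim_config.json")
  cfg <- truth$config
  cfg$chromosomes <- as.list(cfg$chromosomes)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, config = cfg_path))
}

#' Write a genotype table as a plain-text VCF
#'
#' Minimal VCF 4.2 emitter with GT, DP and AD FORMAT fields; ALT alleles
#' are the non-reference alleles observed in the calls. Deliberately
#' uncompressed so outputs are diffable and byte-stable.
#'
#' @param table a `genotype_table`.
#' @param path output path.
#' @export
write_vcf <- function(table, path) {
  n <- n_sites(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(table$sites$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$samples), collapse = "\t")),
             con)
  if (n == 0) return(invisible(path))
  rows <- vapply(seq_len(n), function(i) {
    ref <- table$sites$ref[i]
    called <- unique(stats::na.omit(c(table$a1[i, ], table$a2[i, ])))
    alts <- sort(setdiff(called, ref))
    alleles <- c(ref, alts)
    cells <- vapply(seq_along(table$samples), function(j) {
      a1 <- table$a1[i, j]
      if (is.na(a1)) return("./.:.:.")
      a2 <- table$a2[i, j]
      i1 <- match(a1, alleles) - 1L
      gt <- if (is.na(a2)) as.character(i1)
            else paste0(i1, "/", match(a2, alleles) - 1L)
      ad <- integer(length(alleles))
      ad[i1 + 1L] <- table$ad1[i, j]
      if (!is.na(a2) && a2 != a1) ad[match(a2, alleles)] <- table$ad2[i, j]
      dp <- table$dp[i, j]
      paste(gt, if (is.na(dp)) "." else dp,
            paste(ad, collapse = ","), sep = ":")
    }, "")
    paste(c(table$sites$chrom[i], table$sites$pos[i], ".", ref,
            if (length(alts)) paste(alts, collapse = ",") else ".",
            ".", ".", ".", "GT:DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(rows, con)
  invisible(path)
}
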