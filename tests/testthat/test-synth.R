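test_that("pattern class frequencies match the categorical model probabilities", {
  failures <- 0L
  for (seed in 1:50) {
    cfg <- sim_config(gamma = 0.1, n_sites = 20000, seed = seed)
    b <- simulate_block_counts(cfg, n_blocks = 1)
    obs <- c(b$w_bbaa, b$w_abba, b$w_baba, b$tri, b$bbba)
    probs <- quartetflow:::pattern_class_probs(cfg)
    exp_p <- c(probs[["BBAA"]], probs[["ABBA"]], probs[["BABA"]],
               probs[["CBBA"]] + probs[["BCBA"]] + probs[["CCBA"]],
               probs[["BBBA"]])
    p <- stats::chisq.test(obs, p = exp_p)$p.value
    if (p < 0.01) failures <- failures + 1L
  }
  expect_lte(failures, 2L)
})

test_that("realized D tracks the closed-form expectation", {
  cfg <- sim_config(gamma = 0.2, rho = 0.3, rho_i = 0.3, n_sites = 20000,
                    seed = 31)
  sim <- simulate_patterns(cfg)
  expect_equal(sim$truth$expected_d, 0.14 / 0.34)
  tab <- attach_depths_and_errors(sim$table, cfg)
  win <- window_stats(polarize(tab))
  jk <- jackknife_D(win)
  expect_lt(abs(jk$estimate - sim$truth$expected_d), 3 * jk$se)
})

test_that("a null simulation is symmetric and an empty one is valid", {
  # under no introgression |D| stays within 3 jackknife SEs in almost all
  # replicates (the 20-block Z is t-like, so a rare tail draw is expected)
  ok <- vapply(1:100, function(i) {
    cfg <- sim_config(gamma = 0, n_sites = 30000, seed = 1000 + i)
    jk <- jackknife_D(simulate_block_counts(cfg, n_blocks = 20))
    abs(jk$estimate) < 3 * jk$se
  }, logical(1))
  expect_gte(mean(ok), 0.97)

  cfg0 <- sim_config(n_sites = 0, seed = 1)
  sim0 <- simulate_patterns(cfg0)
  expect_equal(n_sites(sim0$table), 0L)
  expect_equal(nrow(sim0$truth$sites), 0L)
  expect_equal(sim0$truth$expected_d, 0)
})

test_that("with zero error rates haploidization recovers the generator truth", {
  cfg <- sim_config(n_sites = 3000, gamma = 0.1, male_het_error = 0,
                    female_het = 0, missing_rate = 0, seed = 13)
  sim <- simulate_patterns(cfg)
  tab <- attach_depths_and_errors(sim$table, cfg)
  hap <- haploidize_by_depth(tab, seed = 2)
  truth_a1 <- sim$table$a1
  called <- !is.na(hap$a1)
  expect_identical(hap$a1[called], truth_a1[called])
  expect_false(any(hap$provenance[called] %in% c("tie", "depth")))
})

test_that("injected male pseudo-het and female het rates are recovered", {
  cfg <- sim_config(chromosomes = c(chrX = 5e7), n_sites = 200000,
                    missing_rate = 0, seed = 17)
  tab <- attach_depths_and_errors(simulate_patterns(cfg)$table, cfg)
  xt <- split_par(tab, par_config())$nonpar
  males <- names(xt$sexes)[xt$sexes == "male"]
  female <- names(xt$sexes)[xt$sexes == "female"]
  ho <- het_overlap_counts(xt)
  het <- quartetflow:::het_calls(xt)
  n_male_calls <- sum(!is.na(xt$a1[, males]))
  ci_m <- stats::binom.test(sum(het[, males]), n_male_calls)$conf.int
  expect_true(ci_m[1] <= cfg$male_het_error && cfg$male_het_error <= ci_m[2])
  ci_f <- stats::binom.test(sum(het[, female]), sum(!is.na(xt$a1[, female])))$conf.int
  expect_true(ci_f[1] <= cfg$female_het && cfg$female_het <= ci_f[2])
  # het-overlap rates agree with the direct tally
  expect_equal(unname(ho$rates[males[1]]),
               sum(het[, males[1]]) / sum(!is.na(xt$a1[, males[1]])))
})

test_that("the depth filter removes the expected tail of the depth distribution", {
  cfg <- sim_config(n_sites = 30000, mean_depth = 40, depth_dispersion = 10,
                    male_het_error = 0, female_het = 0, missing_rate = 0,
                    seed = 23)
  tab <- attach_depths_and_errors(simulate_patterns(cfg)$table, cfg)
  thresh <- 30L
  obs <- sum(tab$dp < thresh, na.rm = TRUE) + sum(is.na(tab$dp))
  n_calls <- length(tab$dp)
  ci <- stats::binom.test(obs, n_calls)$conf.int
  expected <- stats::pnbinom(thresh - 1, mu = cfg$mean_depth,
                             size = cfg$depth_dispersion)
  expect_true(ci[1] <= expected && expected <= ci[2])
})

test_that("written simulations round-trip bit-exactly and deterministically", {
  cfg <- sim_config(n_sites = 800, gamma = 0.2, seed = 7)
  sim <- simulate_patterns(cfg)
  tab <- attach_depths_and_errors(sim$table, cfg)
  d1 <- tempfile("sim1")
  d2 <- tempfile("sim2")
  p1 <- write_simulation(tab, sim$truth, d1)
  write_simulation(tab, sim$truth, d2)
  expect_identical(readLines(file.path(d1, "sim.vcf")),
                   readLines(file.path(d2, "sim.vcf")))
  truth <- utils::read.table(p1[["truth"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), n_sites(tab))

  back <- read_genotypes(p1[["vcf"]], c(cfg$samples, outgroup = "reference"),
                         cfg$sexes)
  keep <- setdiff(names(unclass(tab)), "provenance")
  expect_equal(unclass(back)[keep], unclass(tab)[keep])
})

test_that("realized D increases with the introgression fraction", {
  d <- vapply(c(0, 0.05, 0.1, 0.2), function(g) {
    cfg <- sim_config(gamma = g, n_sites = 30000, seed = 41)
    patterson_D(simulate_block_counts(cfg, 10))$D
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("block-introgression mode confines the signal to introgressed windows", {
  cfg <- sim_config(gamma = 0.6, n_sites = 20000, intro_window_frac = 0.4,
                    seed = 19)
  sim <- simulate_patterns(cfg)
  expect_false(is.null(sim$truth$windows))
  tab <- attach_depths_and_errors(sim$table, cfg)
  win <- window_stats(polarize(tab))
  key <- function(w) paste(w$chrom, w$start)
  status <- sim$truth$windows$introgressed[match(key(win), key(sim$truth$windows))]
  expect_gt(mean(win$D[status]), mean(win$D[!status]))
  # conditional divergence: introgressed windows sit closer to the donor
  r <- tab$roles
  d23 <- window_divergence(tab, r[["H2"]], r[["H3"]])
  d13 <- window_divergence(tab, r[["H1"]], r[["H3"]])
  win <- conditional_divergence(win, d13$divergence[match(key(win), key(d13))],
                                d23$divergence[match(key(win), key(d23))])
  expect_lt(mean(win$cond_div[status & win$fdm > 0]),
            mean(win$cond_div[!status], na.rm = TRUE))
})
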