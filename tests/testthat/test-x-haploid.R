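test_that("haploidization keeps the deeper allele and passes homozygotes through", {
  tab <- mk_table(pos = c(10, 20), chrom = "chrX",
                  gt = rbind(c("A/G", "G/G", "A/A"),
                             c("A/G", "A/A", "G/G")),
                  ad1 = rbind(c(10, 15, 15), c(2, 15, 15)),
                  ad2 = rbind(c(2, 15, 15), c(10, 15, 15)))
  out <- haploidize_by_depth(tab, seed = 1)
  expect_equal(unname(out$a1[1, "s1"]), "A")  # AD (10, 2): reference kept
  expect_equal(unname(out$a1[2, "s1"]), "G")  # AD (2, 10): alt kept
  expect_true(all(is.na(out$a2)))
  expect_equal(unname(out$provenance[1, ]), c("depth", "hom", "hom"))
  # no allele is invented: every haploid call existed in the diploid call
  expect_true(all(out$a1 == tab$a1 | out$a1 == tab$a2, na.rm = TRUE))
})

test_that("depth ties resolve by seeded coin flip, close to 50/50", {
  n <- 10000
  tab <- mk_table(pos = seq_len(n), chrom = "chrX",
                  gt = cbind(rep("A/G", n), rep("A/A", n), rep("A/A", n)),
                  ad1 = cbind(rep(5L, n), rep(10L, n), rep(10L, n)),
                  ad2 = cbind(rep(5L, n), rep(10L, n), rep(10L, n)))
  out <- haploidize_by_depth(tab, seed = 99)
  expect_identical(out$a1, haploidize_by_depth(tab, seed = 99)$a1)
  expect_true(all(out$provenance[, "s1"] == "tie"))
  frac_ref <- mean(out$a1[, "s1"] == "A")
  expect_gt(frac_ref, 0.48)
  expect_lt(frac_ref, 0.52)
})

test_that("haploidization without allele depths is refused", {
  tab <- mk_table(pos = 1, gt = cbind("A/G", "A/A", "A/A"))
  tab$ad1[] <- NA_integer_
  tab$ad2[] <- NA_integer_
  expect_error(haploidize_by_depth(tab, seed = 1), "diploid mode")
})

test_that("male het masking removes het positions plus buffer, merging intervals", {
  sexes <- c(s1 = "female", s2 = "male", s3 = "male")
  tab <- mk_table(pos = c(496, 497, 500, 503, 504, 600), chrom = "chrX",
                  gt = cbind(rep("A/A", 6),
                             c("A/A", "A/A", "A/G", "A/A", "A/A", "A/A"),
                             rep("A/A", 6)),
                  sexes = sexes)
  out <- mask_male_het(tab, c("s2", "s3"), buffer = 3)
  expect_equal(out$sites$pos, c(496L, 504L, 600L))  # 497..503 removed

  # two male-het sites 4 bp apart merge into one removal interval
  tab2 <- mk_table(pos = c(100, 104), chrom = "chrX",
                   gt = cbind(c("A/A", "A/A"), c("A/G", "A/G"), c("A/A", "A/A")),
                   sexes = sexes)
  m <- attr(mask_male_het(tab2, "s2", buffer = 3), "male_het_mask")
  expect_equal(nrow(m$intervals), 1L)
  expect_equal(c(m$intervals$start, m$intervals$end), c(96L, 107L))

  # no male hets: unchanged; non-male sample: configuration error
  expect_equal(n_sites(mask_male_het(tab2, "s3", buffer = 3)), 2L)
  expect_error(mask_male_het(tab, "s1", buffer = 3), "not flagged male")
})

test_that("male het masking is idempotent and commutes with apply_masks", {
  sexes <- c(s1 = "female", s2 = "male", s3 = "male")
  tab <- mk_table(pos = c(10, 40, 50, 90), chrom = "chrX",
                  gt = cbind(rep("A/A", 4),
                             c("A/G", "A/A", "A/G", "A/A"),
                             rep("A/A", 4)),
                  sexes = sexes)
  once <- mask_male_het(tab, "s2", buffer = 3)
  twice <- mask_male_het(once, "s2", buffer = 3)
  expect_identical(once$sites, twice$sites)
  other <- mask_set(data.frame(chrom = "chrX", start = 85, end = 95))
  ab <- apply_masks(mask_male_het(tab, "s2", 3), other)
  ba <- mask_male_het(apply_masks(tab, other), "s2", 3)
  expect_identical(ab$sites, ba$sites)
})

test_that("the PAR split is exhaustive with the boundary site in PAR", {
  tab <- mk_table(pos = c(403494, 403495, 403496, 500000), chrom = "chrX",
                  gt = matrix("A/A", 4, 3))
  parts <- split_par(tab, par_config())
  expect_equal(parts$par$sites$pos, c(403494L, 403495L))
  expect_equal(parts$nonpar$sites$pos, c(403496L, 500000L))
  expect_equal(n_sites(parts$par) + n_sites(parts$nonpar), 4L)
  empty <- split_par(mk_table(integer(), matrix(character(), 0, 3), chrom = "chrX"))
  expect_equal(n_sites(empty$par), 0L)
  expect_equal(n_sites(empty$nonpar), 0L)
})

test_that("het sharing counts match hand enumeration on a 20-site fixture", {
  # hets placed by hand: s1 only at 4 sites, s2 only at 3, s3 only at 2,
  # s1&s2 at 2, s1&s3 at 1, s2&s3 at 2, all three at 1; 5 sites no het
  het_at <- list(s1 = c(1:4, 10:11, 13, 20), s2 = c(5:7, 10:11, 14:15, 20),
                 s3 = c(8:9, 13, 14:15, 20))
  gt <- matrix("A/A", 20, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  for (s in names(het_at)) gt[het_at[[s]], s] <- "A/G"
  tab <- mk_table(pos = 1:20, chrom = "chrX", gt = gt)
  ho <- het_overlap_counts(tab)
  expect_equal(unname(ho$counts[c("s1", "s2", "s3")]), c(4L, 3L, 2L))
  expect_equal(unname(ho$counts[c("s1&s2", "s1&s3", "s2&s3")]), c(2L, 1L, 2L))
  expect_equal(unname(ho$counts["s1&s2&s3"]), 1L)
  expect_equal(sum(ho$counts), ho$n_het_sites)
  expect_equal(unname(ho$rates["s1"]), 8 / 20)

  none <- het_overlap_counts(mk_table(1:5, matrix("A/A", 5, 3)))
  expect_true(all(none$counts == 0L))
  expect_equal(none$n_het_sites, 0L)
})

test_that("after haploidize + male het mask no male non-PAR X call has two alleles", {
  cfg <- sim_config(n_sites = 2000, gamma = 0.1, seed = 11)
  tab <- attach_depths_and_errors(simulate_patterns(cfg)$table, cfg)
  xt <- split_par(subset_sites_for_test(tab, "chrX"), par_config())$nonpar
  males <- names(xt$sexes)[xt$sexes == "male"]
  xt <- mask_male_het(xt, males, buffer = 3)
  xt <- haploidize_by_depth(xt, seed = 5)
  expect_true(all(is.na(xt$a2[, males])))
})
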