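test_that("polarization yields derived-allele fractions against the outgroup", {
  tab <- mk_table(pos = c(10, 20, 30),
                  gt = rbind(c("A", "G", "G"),       # haploid calls
                             c("A/A", "A/G", "G/G"), # diploid H2 het
                             c("A/A", "A/C", "G/G")),# three alleles
                  ref = c("A", "A", "A"))
  pol <- polarize(tab)
  expect_equal(pol$p1, c(0, 0, 0))
  expect_equal(pol$p2, c(1, 0.5, 0.5))
  expect_equal(pol$p3, c(1, 1, 1))
  expect_equal(pol$usable, c(TRUE, TRUE, FALSE))
  expect_equal(pol$tri, c(FALSE, FALSE, TRUE))
})

test_that("an ambiguous or missing outgroup makes the site unusable and is logged", {
  tab <- mk_table(pos = c(10, 20),
                  gt = rbind(c("A/A", "G/G", "G/G", "A/G"),
                             c("A/A", "G/G", "G/G", "C/C")),
                  samples = c("s1", "s2", "s3", "s4"),
                  roles = c(H1 = "s1", H2 = "s2", H3 = "s3", outgroup = "s4"))
  pol <- polarize(tab)
  expect_false(pol$usable[1])   # het outgroup: ancestral state ambiguous
  expect_equal(attr(pol, "skipped")[["missing_outgroup"]], 1)
  expect_true(pol$tri[2])       # outgroup carries a third allele: CCBA-eligible
  expect_false(pol$usable[2])
})

test_that("biallelic weights match their defining products", {
  expect_equal(unlist(biallelic_weights(0, 1, 1)), c(w_bbaa = 0, w_abba = 1, w_baba = 0))
  expect_equal(unlist(biallelic_weights(1, 0, 1)), c(w_bbaa = 0, w_abba = 0, w_baba = 1))
  expect_equal(unlist(biallelic_weights(1, 1, 0)), c(w_bbaa = 1, w_abba = 0, w_baba = 0))
  # diploid het in H2: average over the two equally likely haploid resolutions
  expect_equal(biallelic_weights(0, 0.5, 1)$w_abba, 0.5)
  expect_equal(biallelic_weights(0, 0.5, 1)$w_bbaa, 0)
})

test_that("weights obey the simplex bound and the H1/H2 swap symmetry", {
  grid <- expand.grid(p1 = c(0, 0.25, 0.5, 1), p2 = c(0, 0.5, 0.75, 1),
                      p3 = c(0, 0.5, 1))
  w <- biallelic_weights(grid$p1, grid$p2, grid$p3)
  tot <- rowSums(w)
  expect_true(all(tot <= 1 + 1e-12))
  hard <- grid$p1 %in% c(0, 1) & grid$p2 %in% c(0, 1) & grid$p3 %in% c(0, 1)
  two_derived <- (grid$p1 + grid$p2 + grid$p3 == 2) & hard
  expect_true(all(abs(tot[two_derived] - 1) < 1e-12))
  expect_true(all(tot[!two_derived] < 1 - 1e-12 | !hard[!two_derived]))
  ws <- biallelic_weights(grid$p2, grid$p1, grid$p3)
  expect_equal(ws$w_abba, w$w_baba)
  expect_equal(ws$w_baba, w$w_abba)
  expect_equal(ws$w_bbaa, w$w_bbaa)
})

test_that("haploid weights reproduce the string-pattern oracle over all assignments", {
  combos <- expand.grid(h1 = c("A", "G"), h2 = c("A", "G"), h3 = c("A", "G"),
                        o = c("A", "G"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    w <- biallelic_weights(as.numeric(cb$h1 != cb$o), as.numeric(cb$h2 != cb$o),
                           as.numeric(cb$h3 != cb$o))
    oracle <- string_pattern(cb$h1, cb$h2, cb$h3, cb$o)
    expect_equal(w$w_bbaa, as.numeric(oracle == "BBAA"), info = paste(cb, collapse = ""))
    expect_equal(w$w_abba, as.numeric(oracle == "ABBA"), info = paste(cb, collapse = ""))
    expect_equal(w$w_baba, as.numeric(oracle == "BABA"), info = paste(cb, collapse = ""))
  }
})

test_that("tri-allelic classification follows the majority-allele rules", {
  tab <- mk_table(pos = (1:5) * 10,
                  gt = rbind(c("C", "G", "G"),   # third allele in H1: CBBA
                             c("G", "C", "G"),   # third allele in H2: BCBA
                             c("C", "C", "G"),   # shared third allele: CCBA
                             c("G", "G", "G"),   # shared derived in all: BBBA
                             c("A", "G", "G")),  # plain ABBA: none of these
                  ref = rep("A", 5))
  lab <- classify_triallelic(polarize(tab))
  expect_equal(lab, c("CBBA", "BCBA", "CCBA", "BBBA", "other"))
  counts <- tally_triallelic(polarize(tab))
  expect_equal(unlist(counts), c(cbba = 1L, bcba = 1L, ccba = 1L, bbba = 1L))
  # a 50/50 het in a role is a tie: classified other
  tab2 <- mk_table(pos = 10, gt = cbind("C/A", "G/G", "G/G"), ref = "A")
  expect_equal(classify_triallelic(polarize(tab2)), "other")
})

test_that("windows tile from position 1 and tallies are conserved", {
  pos <- c(1, 4999999, 5000000, 5000001, 9999999, 10000001)
  gt <- do.call(rbind, rep(list(c("A", "G", "G")), 6))
  tab <- mk_table(pos = pos, gt = gt, ref = rep("A", 6))
  win <- tally_windows(polarize(tab), window_bp = 5e6)
  expect_equal(win$start, c(1, 5000001, 10000001))
  expect_equal(win$n_sites, c(3, 2, 1))

  # 12 pure-pattern haploid sites over two windows: exact integer sums
  gt12 <- rbind(matrix(rep(c("A", "G", "G"), 4), 4, byrow = TRUE),
                matrix(rep(c("G", "A", "G"), 3), 3, byrow = TRUE),
                matrix(rep(c("G", "G", "A"), 5), 5, byrow = TRUE))
  pos12 <- c(1:4, 11:13, 5000001 + 1:5)
  tab12 <- mk_table(pos = pos12, gt = gt12[order(pos12), , drop = FALSE],
                    ref = rep("A", 12))
  win12 <- tally_windows(polarize(tab12), window_bp = 5e6)
  expect_equal(win12$w_abba, c(4, 0))
  expect_equal(win12$w_baba, c(3, 0))
  expect_equal(win12$w_bbaa, c(0, 5))
  expect_true(all(win12$w_abba %% 1 == 0))  # haploid input: integer weights
  # conservation: genome totals equal the sum of window tallies
  pol <- polarize(tab12)
  w <- biallelic_weights(pol$p1, pol$p2, pol$p3)
  expect_equal(sum(win12$w_abba), sum(w$w_abba[pol$usable]))
  expect_equal(sum(win12$w_bbaa), sum(w$w_bbaa[pol$usable]))
})

test_that("hard-call mode counts integer patterns and skips 50/50 ties", {
  tab <- mk_table(pos = c(10, 20, 30),
                  gt = rbind(c("A/A", "G/G", "G/G"),
                             c("A/A", "A/G", "G/G"),
                             c("G/G", "G/G", "A/A")),
                  ref = rep("A", 3))
  win <- tally_windows(polarize(tab), window_bp = 5e6, mode = "hard")
  expect_equal(win$w_abba, 1)
  expect_equal(win$w_bbaa, 1)
  expect_equal(win$w_baba, 0)
})
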