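mk_freq <- function(rows, pops = c("P1", "P2", "P3", "O")) {
  m <- do.call(rbind, rows)
  colnames(m) <- pops
  m
}

test_that("site patterns match hand-computed ABBA/BABA weights", {
  f <- mk_freq(list(c(0, 1, 1, 0)))
  sp <- site_patterns(f, c(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "O"))
  expect_equal(sp$abba, 1)
  expect_equal(sp$baba, 0)
  f2 <- mk_freq(list(c(0.2, 0.8, 0.6, 0), c(0.1, 0.1, 0.9, 0)))
  sp2 <- site_patterns(f2, c(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "O"))
  expect_equal(sum(sp2$abba), 0.465, tolerance = 1e-12)
  expect_equal(sum(sp2$baba), 0.105, tolerance = 1e-12)
  # p1 = p2 everywhere: symmetry
  f3 <- mk_freq(list(c(0.3, 0.3, 0.7, 0.1), c(0.6, 0.6, 0.2, 0)))
  sp3 <- site_patterns(f3, c(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "O"))
  expect_equal(sum(sp3$abba), sum(sp3$baba))
  f4m <- f2; f4m[] <- NA_real_
  expect_error(site_patterns(f4m, c(P1 = "P1", P2 = "P2", P3 = "P3",
                                    outgroup = "O")), "masked")
})

test_that("Patterson's D matches hand values, is antisymmetric and
           duplication-invariant", {
  f <- mk_freq(list(c(0.2, 0.8, 0.6, 0), c(0.1, 0.1, 0.9, 0)))
  vt <- variant_table("chr1", c(100, 200), "A", "T")
  trio <- c(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "O")
  d <- patterson_d(f, trio, vt, blocks = rep(1:2, 1))
  expect_equal(d$D, 0.36 / 0.57, tolerance = 1e-12)
  swap <- c(P1 = "P2", P2 = "P1", P3 = "P3", outgroup = "O")
  expect_equal(patterson_d(f, swap, vt, blocks = 1:2)$D, -d$D,
               tolerance = 1e-12)
  fdup <- rbind(f, f)
  vtd <- variant_table("chr1", c(100, 200, 300, 400), "A", "T")
  expect_equal(patterson_d(fdup, trio, vtd, blocks = rep(1:2, 2))$D, d$D,
               tolerance = 1e-12)
})

test_that("f_d matches hand evaluation and respects its domain", {
  trio <- c(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "O")
  f <- mk_freq(list(c(0, 0.5, 1, 0)))
  vt <- variant_table("chr1", 100, "A", "T")
  w <- data.frame(chrom = "chr1", start = 0, end = 1000)
  res <- f_d(f, trio, vt, w, min_sites = 1)
  expect_equal(res$fd, 0.5, tolerance = 1e-12)  # num 0.5 / den 1
  # P2 column equal to P3: complete sharing, f_d = 1
  set.seed(2)
  p2 <- runif(30); p1 <- runif(30) * 0.3; po <- rep(0, 30)
  f2 <- mk_freq(lapply(1:30, function(i) c(p1[i], p2[i], p2[i], po[i])))
  vt2 <- variant_table("chr1", 1:30 * 10, "A", "T")
  res2 <- f_d(f2, trio, vt2, w, min_sites = 1)
  expect_equal(res2$fd, 1, tolerance = 1e-12)
  # windows with D < 0 are NaN
  f3 <- mk_freq(list(c(0.9, 0.1, 0.9, 0), c(0.8, 0.2, 0.7, 0)))
  vt3 <- variant_table("chr1", c(10, 20), "A", "T")
  res3 <- f_d(f3, trio, vt3, w, min_sites = 1)
  expect_true(res3$D < 0)
  expect_true(is.na(res3$fd))
})

test_that("f4 and the f4-ratio match hand products and controls", {
  vt <- variant_table("chr1", c(100, 200), "A", "T")
  f <- mk_freq(list(c(0.8, 0.2, 0.9, 0.1), c(0.3, 0.5, 0.2, 0.6)),
               pops = c("A", "B", "C", "D"))
  r <- f4(f, "A", "B", "C", "D", vt, blocks = 1:2)
  expect_equal(r$f4, 0.28, tolerance = 1e-12)  # (0.48 + 0.08) / 2
  # ratio controls on a 5-population fixture
  set.seed(5)
  n <- 200
  m <- cbind(A = runif(n), O = runif(n), B = runif(n), C = runif(n))
  vt5 <- variant_table("chr1", sort(sample.int(1e6, n)), "A", "T")
  blocks <- rep(1:10, each = 20)
  fx <- cbind(m, X = m[, "B"])  # X = B: unadmixed control
  expect_equal(f4_ratio(fx, c(A = "A", O = "O", X = "X", B = "B", C = "C"),
                        vt5, blocks = blocks)$alpha, 1, tolerance = 1e-12)
  fx2 <- cbind(m, X = m[, "C"])  # X = C
  a0 <- f4_ratio(fx2, c(A = "A", O = "O", X = "X", B = "B", C = "C"),
                 vt5, blocks = blocks)
  expect_equal(a0$alpha, 0, tolerance = 1e-12)
})

test_that("f-branch handles trivial trees and flags planted flow", {
  # 3-leaf case: no testable branch/donor combination
  fix <- freq_fixture(50, seed = 3, n_pops = 3, pops = c("P1", "P2", "O"))
  fb0 <- f_branch("((P1,P2),O);", fix$freqs, "O", fix$vt, blocks = 5)
  expect_equal(nrow(fb0$fb), 0)
  expect_error(f_branch("((P1,P2,P3),O);", fix$freqs, "O", fix$vt),
               "binary")
  # planted flow pop3 -> pop2 on the synthetic cohort
  cfg <- synth_config(n_variants = 20000)
  sim <- simulate_structured_genotypes(cfg, seed = 41)
  rec <- sim$pops$sample[sim$pops$population == "pop2"]
  sim <- plant_introgression_tracts(sim, "pop3", rec, m = 0.15,
                                    tract_len = 1e6, seed = 42)
  vt <- polarize_by_outgroup(sim$variants, sim$genotypes, sim$pops, "outgroup")
  fr <- derived_freqs(sim$genotypes, vt, sim$pops,
                      c("pop1", "pop2", "pop3", "outgroup"))
  fb <- f_branch("(((pop1,pop2),pop3),outgroup);", fr, "outgroup", vt)
  expect_true(fb$fb["pop2", "pop3"] > 0.05)
  expect_true(fb$q["pop2", "pop3"] < 0.001)
  expect_true(is.na(fb$fb["pop2", "pop2"]))  # donor inside the branch
})

test_that("Dxy matches hand values on fixed and intermediate frequencies", {
  w <- data.frame(chrom = "chr1", start = 0, end = 100)
  vt <- variant_table("chr1", 50, "A", "T")
  f <- mk_freq(list(c(1, 0, 0, 0)))
  res <- d_xy(f, "P1", "P2", vt, w, accessible = 10)
  expect_equal(res$dxy, 0.1)  # one fixed difference over 10 sites
  f0 <- mk_freq(list(c(1, 1, 0, 0)))
  expect_equal(d_xy(f0, "P1", "P2", vt, w, accessible = 10)$dxy, 0)
  n <- 20
  fh <- mk_freq(lapply(1:n, function(i) c(0.5, 0.5, 0, 0)))
  vth <- variant_table("chr1", 1:n, "A", "T")
  expect_equal(d_xy(fh, "P1", "P2", vth, w, accessible = n)$dxy, 0.5)
  expect_equal(attr(d_xy(fh, "P1", "P2", vth, w), "denominator"), "window_bp")
})

test_that("diagnostic markers and ancestry profiles follow dosage
           arithmetic", {
  gm <- rbind(d1 = rep(2L, 10), d2 = rep(2L, 10),
              o1 = rep(0L, 10), o2 = rep(0L, 10),
              q_hom = rep(2L, 10),
              q_half = c(rep(1L, 5), rep(2L, 5)) * 0L + c(rep(1L, 5), rep(0L, 5)),
              q_none = rep(0L, 10))
  gm["q_half", ] <- c(rep(1L, 5), rep(0L, 5))
  vt <- variant_table("chr1", 1:10 * 100, "A", "T")
  pm <- data.frame(sample = rownames(gm),
                   population = c("don", "don", "oth", "oth", "q", "q", "q"))
  mk <- diagnostic_markers(gm, pm, "don", "oth")
  expect_equal(nrow(mk), 10)
  expect_true(all(mk$donor_allele == "alt"))
  ap <- ancestry_profile(gm, vt, mk, samples = c("q_hom", "q_half", "q_none"))
  expect_equal(unname(ap$total["q_hom"]), 1)
  expect_equal(unname(ap$total["q_none"]), 0)
  # 5 het-donor + 5 homozygous-other of 10 markers: 5 / 20
  expect_equal(unname(ap$total["q_half"]), 0.25)
  expect_error(diagnostic_markers(gm, pm, "don", "q", min_delta = 1),
               "min_delta")
})
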