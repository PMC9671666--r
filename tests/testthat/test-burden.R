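mk_vt <- function(sift) {
  vt <- variant_table("chr1", seq_along(sift) * 100, "A", "T")
  vt$sift_score <- sift
  vt
}

test_that("deleterious classification is inclusive at the SIFT boundary", {
  vt <- mk_vt(c(0.05, 0.051, 0.2, 0.0))
  ds <- classify_deleterious(vt)
  expect_equal(ds$deleterious_snp, c(1L, 4L))  # 0.05 in, 0.051 out
  vt$lof_flag[3] <- TRUE
  ds2 <- classify_deleterious(vt)
  expect_equal(ds2$lof, 3L)
  expect_equal(ds2$all, c(1L, 3L, 4L))
  sv <- variant_table("chr1", c(100, 200), "N", "N",
                      vtype = c("DEL", "INS"), svlen = c(500L, 300L))
  dsv <- classify_deleterious(sv)
  expect_equal(dsv$deleterious_sv, 1L)  # INS not in the default classes
  expect_warning(classify_deleterious(mk_vt(rep(NA_real_, 3))), "no annotated")
})

test_that("burden counts satisfy the additive identity and handle missing
           genotypes", {
  gm <- rbind(s1 = c(0L, 1L, 2L, 1L), s2 = c(NA, NA, NA, NA))
  vt <- mk_vt(c(0.01, 0.02, 0.03, 0.04))
  ds <- classify_deleterious(vt)
  b <- burden_per_sample(gm, ds, classes = "deleterious_snp")
  s1 <- b[b$sample == "s1", ]
  expect_equal(s1$n_het, 2L)
  expect_equal(s1$n_hom, 1L)
  expect_equal(s1$additive_burden, 4L)
  expect_equal(s1$recessive_burden, 1L)
  s2 <- b[b$sample == "s2", ]
  expect_equal(s2$additive_burden, 0L)
  expect_true(s2$low_call)
  # identity on a synthetic cohort, every sample and class
  cfg <- synth_config(n_variants = 3000, contigs = c(chr1 = 1e6))
  sim <- simulate_structured_genotypes(cfg, seed = 8)
  sim <- attach_deleterious_annotations(sim, fraction = 0.2, seed = 9)
  ball <- burden_per_sample(sim$genotypes, classify_deleterious(sim$variants))
  expect_true(all(ball$additive_burden == ball$n_het + 2 * ball$n_hom))
  expect_true(all(ball$n_hom <= ball$additive_burden / 2))
})

test_that("hybrids with planted heterozygous tracts carry a higher het
           burden than their source population", {
  wins <- 0
  for (sd in 1:5) {
    cfg <- synth_config(n_variants = 8000)
    sim <- simulate_structured_genotypes(cfg, seed = sd)
    rec <- sim$pops$sample[sim$pops$population == "pop2"]
    sim <- plant_introgression_tracts(sim, "pop3", rec, m = 0.2,
                                      tract_len = 1e6, seed = sd + 50)
    sim <- attach_deleterious_annotations(sim, fraction = 0.1, seed = sd + 99)
    b <- burden_per_sample(sim$genotypes, classify_deleterious(sim$variants),
                           classes = "deleterious_snp")
    het_rec <- mean(b$n_het[b$sample %in% rec])
    het_src <- mean(b$n_het[b$sample %in%
                              sim$pops$sample[sim$pops$population == "pop1"]])
    if (het_rec > het_src) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("hemizygosity follows strict >50% merged overlap", {
  genes <- data.frame(chrom = "c1", start = c(0, 2000), end = c(1000, 3000))
  dels <- data.frame(sample = "s1", chrom = "c1", start = 400, end = 1200)
  hz <- hemizygous_fraction(genes, dels)  # 60% of gene 1
  expect_equal(hz$g_h, 0.5)
  # overlap exactly 50% is NOT hemizygous
  dels50 <- data.frame(sample = "s1", chrom = "c1", start = 0, end = 500)
  expect_equal(hemizygous_fraction(genes, dels50)$g_h, 0)
  # merge-then-measure: [0,30) + [20,60) on a 100 bp gene -> 60%
  g100 <- data.frame(chrom = "c1", start = 0, end = 100)
  dmerge <- data.frame(sample = "s1", chrom = "c1",
                       start = c(0, 20), end = c(30, 60))
  expect_equal(hemizygous_fraction(g100, dmerge)$g_h, 1)
  expect_error(hemizygous_fraction(genes[0, ], dels), "zero genes")
})

test_that("g_h is invariant to splitting deletions into abutting pieces", {
  sv <- simulate_sv_and_genes(samples = "s1", hemi_fraction = 0.2, seed = 13)
  split_dels <- do.call(rbind, lapply(seq_len(nrow(sv$deletions)), function(i) {
    d <- sv$deletions[i, ]
    mid <- floor((d$start + d$end) / 2)
    rbind(data.frame(sample = d$sample, chrom = d$chrom, start = d$start,
                     end = mid),
          data.frame(sample = d$sample, chrom = d$chrom, start = mid,
                     end = d$end))
  }))
  expect_equal(hemizygous_fraction(sv$genes, split_dels)$g_h,
               hemizygous_fraction(sv$genes, sv$deletions)$g_h)
})

test_that("Spearman correlation matches brute-force ranks and flags
           degenerate input", {
  expect_equal(spearman_cor(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  perms <- combinat_perms <- NULL
  set.seed(12)
  for (k in 1:30) {
    x <- sample(6); y <- sample(c(1, 1, 2, 3, 3, 4))  # ties included
    r <- spearman_cor(x, y)
    expect_equal(r$rho, bf_spearman_rho(x, y), tolerance = 1e-12)
    tstat <- r$rho * sqrt(4 / (1 - r$rho^2))
    expect_equal(r$p, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
  }
  expect_true(spearman_cor(rep(1, 5), 1:5)$undefined)
})

test_that("burden contrast recovers ratios with bootstrap CIs", {
  b <- data.frame(sample = sprintf("s%02d", 1:20), class = "all",
                  n_het = c(rep(10, 10), rep(10, 10)))
  pm <- data.frame(sample = b$sample,
                   population = rep(c("apo", "sex"), each = 10))
  r1 <- burden_contrast(b, pm, "apo", "sex", seed = 1)
  expect_equal(r1$estimate, 1)
  b$n_het[1:10] <- 2 * b$n_het[11:20]
  expect_equal(burden_contrast(b, pm, "apo", "sex", seed = 1)$estimate, 2)
  # determinism of the seeded bootstrap
  r2 <- burden_contrast(b, pm, "apo", "sex", seed = 7)
  r3 <- burden_contrast(b, pm, "apo", "sex", seed = 7)
  expect_identical(r2$ci, r3$ci)
})
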