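test_that("generator is deterministic and respects the F -> 0 limit", {
  cfg <- synth_config(n_variants = 400, contigs = c(chr1 = 1e6))
  s1 <- simulate_structured_genotypes(cfg, seed = 9)
  s2 <- simulate_structured_genotypes(cfg, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(s1$variants, s1$genotypes, f1)
  write_vcf(s2$variants, s2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical output
  s3 <- simulate_structured_genotypes(cfg, seed = 10)
  expect_false(identical(s1$genotypes, s3$genotypes))
  # F = 0: population frequencies equal the ancestral frequency exactly
  cfg0 <- synth_config(n_pops = 2, n_variants = 200, fst = 0,
                       contigs = c(chr1 = 1e6))
  s0 <- simulate_structured_genotypes(cfg0, seed = 1)
  expect_equal(s0$truth$pop_freq[, "pop1"], s0$truth$ancestral_freq)
  expect_equal(s0$truth$pop_freq[, "pop2"], s0$truth$ancestral_freq)
})

test_that("Hudson Fst on simulated populations recovers the drift parameter", {
  errs <- sapply(1:4, function(sd) {
    cfg <- synth_config(n_pops = 3, n_per_pop = 20, n_variants = 50000,
                        fst = 0.2)
    sim <- simulate_structured_genotypes(cfg, seed = sd)
    pm <- sim$pops
    d1 <- sim$genotypes[pm$sample[pm$population == "pop1"], ]
    d2 <- sim$genotypes[pm$sample[pm$population == "pop2"], ]
    fst <- bf_hudson_fst(colMeans(d1) / 2, colMeans(d2) / 2,
                         2 * nrow(d1), 2 * nrow(d2))
    abs(fst - 0.2)
  })
  # two populations drifted with parameter F from a shared ancestor have
  # pairwise Hudson Fst = F in expectation
  expect_true(all(errs < 0.05))
})

test_that("planted tracts cover exactly the requested fraction and truth
           indexes cleanly", {
  cfg <- synth_config(n_variants = 2000, contigs = c(chr1 = 5e6, chr2 = 5e6))
  sim <- simulate_structured_genotypes(cfg, seed = 21)
  rec <- sim$pops$sample[sim$pops$population == "pop2"][1:4]
  genome <- sum(sim$contigs)
  for (sd in 1:5) {
    s2 <- plant_introgression_tracts(sim, "pop3", rec, m = 0.10,
                                     tract_len = 1e6, seed = sd)
    tr <- s2$truth$tracts
    expect_true(all(tr$start >= 0 & tr$end <= 5e6))       # within contigs
    expect_true(all(tr$chrom %in% names(sim$contigs)))
    for (s in rec) for (h in 1:2) {
      cov <- sum(tr$end[tr$sample == s & tr$hap == h] -
                   tr$start[tr$sample == s & tr$hap == h])
      expect_equal(cov / genome, 0.10, tolerance = 1e-6)
    }
  }
  # m = 0 is a no-op; m = 1 copies donor haplotypes genome-wide
  expect_identical(plant_introgression_tracts(sim, "pop3", rec, m = 0,
                                              tract_len = 1e6, seed = 1),
                   sim)
  s1 <- plant_introgression_tracts(sim, "pop3", rec, m = 1,
                                   tract_len = 1e6, seed = 2)
  hap <- attr(s1$genotypes, "haplotypes")
  donors <- sim$pops$sample[sim$pops$population == "pop3"]
  dpool <- rbind(attr(sim$genotypes, "haplotypes")[[1]][donors, ],
                 attr(sim$genotypes, "haplotypes")[[2]][donors, ])
  for (s in rec[1:2]) {
    match_any <- apply(dpool, 1, function(dh) all(dh == hap[[1]][s, ]))
    expect_true(any(match_any))  # whole haplotype is one donor copy
  }
})

test_that("deleterious annotations round trip through the classifier and
           follow the DFE", {
  cfg <- synth_config(n_variants = 10000, contigs = c(chr1 = 1e7))
  sim <- simulate_structured_genotypes(cfg, seed = 31)
  s0 <- attach_deleterious_annotations(sim, fraction = 0, seed = 1)
  expect_equal(sum(s0$variants$sift_score <= 0.05, na.rm = TRUE), 0L)
  s1 <- attach_deleterious_annotations(sim, fraction = 0.1,
                                       dfe = list(kind = "gamma", shape = 0.5,
                                                  mean = 0.05), seed = 2)
  ds <- classify_deleterious(s1$variants)
  expect_identical(ds$deleterious_snp, s1$truth$deleterious)
  s_del <- s1$truth$s[s1$truth$deleterious]
  expect_equal(mean(s_del), 0.05, tolerance = 0.1)  # gamma DFE mean at 1k sites
  expect_true(all(s1$truth$s[-s1$truth$deleterious] == 0))
})

test_that("F1 bulked-segregant simulation behaves Mendelian", {
  ratios_ok <- 0
  for (sd in 1:5) {
    b <- simulate_f1_bsa(n_progeny = 554, bulk_size = 30, depth = 30,
                         n_markers = 600, seed = sd)
    st <- segregation_test(sum(b$phenotypes), sum(!b$phenotypes))
    if (st$p > 0.05) ratios_ok <- ratios_ok + 1
  }
  expect_gte(ratios_ok, 4)  # 1:1 segregation in nearly all replicates
  b <- simulate_f1_bsa(n_progeny = 400, bulk_size = 40, depth = 100,
                       n_markers = 2000, seed = 11)
  si <- snp_index(b$counts)
  near <- si$chrom == b$truth$qtl$chrom & abs(si$pos - b$truth$qtl$pos) < 5e5
  far <- si$chrom != b$truth$qtl$chrom
  expect_gt(mean(si$delta_snp_index[near], na.rm = TRUE), 0.35)  # linked ~ 0.5
  expect_lt(max(abs(tapply(si$delta_snp_index[far], si$chrom[far], mean,
                           na.rm = TRUE))), 0.1)                 # unlinked ~ 0
  expect_error(simulate_f1_bsa(n_progeny = 50, bulk_size = 30, seed = 1),
               "bulk_size")
})

test_that("SV/gene simulation is consistent with the interval oracle", {
  sv0 <- simulate_sv_and_genes(samples = "s1", hemi_fraction = 0, n_decoys = 0,
                               seed = 2)
  expect_equal(unname(sv0$truth_gh["s1"]), 0)
  sv <- simulate_sv_and_genes(samples = c("s1", "s2"), hemi_fraction = 0.15,
                              seed = 3)
  hz <- hemizygous_fraction(sv$genes, sv$deletions)
  expect_equal(hz$g_h, unname(sv$truth_gh[hz$sample]))
})

test_that("insertion evidence recovers genotypes at stated depth and error", {
  set.seed(77)  # local fixture construction only
  truth <- data.frame(sample = sprintf("s%04d", 1:1000), locus = "mite1",
                      genotype = sample(c("absent", "het", "hom"), 1000,
                                        replace = TRUE))
  ev <- simulate_insertion_evidence(truth, depth = 30, error = 0, seed = 5)
  hom <- ev$genotype == "hom"
  expect_true(all(ev$ins_reads[hom] == 30))  # error = 0: all reads support
  ev2 <- simulate_insertion_evidence(truth, depth = 30, error = 0.01, seed = 6)
  het <- ev2$genotype == "het"
  frac <- ev2$ins_reads[het] / 30
  expect_gte(mean(frac >= 0.2 & frac <= 0.8), 0.95)
  calls <- call_insertion_genotype(ev2$ins_reads, ev2$ref_reads)
  called <- calls$call != "no_call"
  expect_gte(mean(calls$call[called] == ev2$genotype[called]), 0.99)
  expect_gte(mean(called), 0.9)
})
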