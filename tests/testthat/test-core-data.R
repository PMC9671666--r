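test_that("VCF round trip preserves variants, dosages and annotations", {
  cfg <- synth_config(n_variants = 300, contigs = c(chr1 = 1e6, chr2 = 1e6))
  sim <- simulate_structured_genotypes(cfg, seed = 3)
  sim <- attach_deleterious_annotations(sim, fraction = 0.1, seed = 4)
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$genotypes, f)
  rt <- read_vcf(f)
  expect_identical(rt$variants$chrom, sim$variants$chrom)
  expect_identical(rt$variants$pos, sim$variants$pos)
  expect_identical(rt$variants$ref, sim$variants$ref)
  gm <- sim$genotypes; attributes(gm) <- attributes(gm)["dim"]
  expect_identical(unname(rt$genotypes), gm)
  expect_equal(rt$variants$sift_score, sim$variants$sift_score,
               tolerance = 1e-5)
  expect_identical(rt$variants$lof_flag, sim$variants$lof_flag)
})

test_that("GT mapping, missing genotypes and SV conventions parse correctly", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t0/1\t0/0",
    "chr1\t300\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-500\tGT\t0/1\t0/0\t1/1",
    "chr1\t400\t.\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV\tGT\t0/1\t0/0\t0/0",
    "chr1\t500\t.\tA\tT,G\t.\tPASS\t.\tGT\t1/2\t0/1\t2/2"),
    f)
  expect_warning(res <- read_vcf(f), "unknown SVTYPE")
  expect_equal(res$n_skipped, 1L)
  expect_equal(unname(res$genotypes[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(res$genotypes["s1", 2]))
  del <- res$variants[res$variants$pos == 300, ]
  expect_equal(del$vtype, "DEL")
  expect_equal(del$svlen, 500L)  # sign convention normalised
  expect_false(400 %in% res$variants$pos)
  expect_false(500 %in% res$variants$pos)  # multiallelic dropped by default

  res2 <- suppressWarnings(read_vcf(f, multiallelic = "split"))
  split_rows <- res2$variants[res2$variants$pos == 500, ]
  expect_equal(nrow(split_rows), 2L)
  expect_equal(split_rows$alt, c("T", "G"))
  d5 <- res2$genotypes[, res2$variants$pos == 500]
  expect_equal(unname(d5[, 1]), c(1L, 1L, 0L))  # allele T
  expect_equal(unname(d5[, 2]), c(1L, 0L, 2L))  # allele G
})

test_that("malformed VCF raises a parse error naming the file", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all"), f)
  expect_error(read_vcf(f), "malformed VCF")
})

test_that("outgroup polarization follows the major allele and is idempotent", {
  gm <- rbind(s1 = c(0L, 2L, 1L, NA, 1L),
              s2 = c(0L, 2L, 1L, NA, 0L),
              og1 = c(0L, 2L, 1L, NA, 0L),
              og2 = c(0L, 2L, 0L, NA, 0L))
  vt <- variant_table("chr1", 1:5 * 100, "A", "T")
  pm <- data.frame(sample = rownames(gm),
                   population = c("p", "p", "outgroup", "outgroup"))
  v1 <- polarize_by_outgroup(vt, gm, pm, "outgroup", max_og_minor = 0.1)
  expect_equal(v1$ancestral,
               c("ref",      # outgroup all 0/0
                 "alt",      # outgroup all 1/1
                 "unknown",  # outgroup minor freq 0.25 > 0.1
                 "unknown",  # outgroup all missing
                 "ref"))
  v2 <- polarize_by_outgroup(v1, gm, pm, "outgroup", max_og_minor = 0.1)
  expect_identical(v1, v2)
  # threshold rule: outgroup freq(alt) = 0.4 > max_og_minor = 0.1 -> unknown
  gm2 <- rbind(s1 = 1L, og1 = 1L, og2 = 1L, og3 = 0L, og4 = 1L, og5 = 0L)
  pm2 <- data.frame(sample = rownames(gm2),
                    population = c("p", rep("outgroup", 5)))
  vt2 <- variant_table("chr1", 100, "A", "T")
  expect_equal(polarize_by_outgroup(vt2, gm2, pm2, "outgroup")$ancestral,
               "unknown")
  expect_error(polarize_by_outgroup(vt, gm, pm, "nosuchpop"), "no samples")
})

test_that("derived frequencies handle missingness, flipping and min_n", {
  gm <- rbind(a1 = c(1L, 1L, NA), a2 = c(2L, 0L, 2L))
  vt <- variant_table("chr1", c(100, 200, 300), "A", "T")
  vt$ancestral <- c("ref", "alt", "ref")
  pm <- data.frame(sample = c("a1", "a2"), population = "popA")
  f <- derived_freqs(gm, vt, pm, "popA")
  expect_equal(unname(f[1, "popA"]), 3 / 4)        # dosages (1,2) on derived scale
  expect_equal(unname(f[2, "popA"]), 1 - 1 / 4)    # ancestral = alt flips
  expect_equal(unname(f[3, "popA"]), 1.0)          # one missing, one hom: n = 2
  f4n <- derived_freqs(gm, vt, pm, "popA", min_n = 4)
  expect_true(is.na(f4n[3, "popA"]))       # only 2 called alleles
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})

test_that("windows tile contigs with partial final windows and overlap", {
  w1 <- make_windows(c(c1 = 1e5), 25000)
  expect_equal(nrow(w1), 4)
  w2 <- make_windows(c(c1 = 60000), 50000)
  expect_equal(w2$start, c(0, 50000))
  expect_equal(w2$end, c(50000, 60000))
  w3 <- make_windows(c(c1 = 50000), 25000, 12500)
  expect_equal(w3$start, c(0, 12500, 25000, 37500))
  expect_true(all(w3$end > w3$start))
})

test_that("block jackknife matches the classic delete-one formula and is
           weight-scale invariant", {
  # equal weights: SE equals the classic delete-1 jackknife SE of the
  # leave-one-out estimates
  v <- c(4, 7, 1, 9, 3)
  jk <- block_jackknife(v)
  loo <- sapply(seq_along(v), function(j) mean(v[-j]))
  expect_equal(jk$se, bf_jackknife_se(loo), tolerance = 1e-12)
  expect_equal(jk$estimate, mean(v))
  expect_equal(jk$z, jk$estimate / jk$se)
  expect_equal(jk$p, 2 * pnorm(-abs(jk$z)))
  # leave-one-out estimates {1,2,3} arise from block values {3,2,1} * const
  jk2 <- block_jackknife(c(4, 2, 0))
  loo2 <- sapply(1:3, function(j) mean(c(4, 2, 0)[-j]))
  expect_equal(sort(loo2), c(1, 2, 3))
  expect_equal(jk2$se, bf_jackknife_se(loo2), tolerance = 1e-12)
  # unequal weights: brute-force delete-one recomputation
  set.seed(7)
  for (rep in 1:5) {
    v <- runif(8); w <- runif(8, 0.5, 3)
    jk <- block_jackknife(v, w)
    est <- sum(w * v) / sum(w)
    loo <- sapply(1:8, function(j) sum(w[-j] * v[-j]) / sum(w[-j]))
    n <- 8; W <- sum(w); h <- W / w
    tj <- n * est - sum((1 - 1 / h) * loo)
    se <- sqrt(sum((h * est - (h - 1) * loo - tj)^2 / (h - 1)) / n)
    expect_equal(jk$se, se, tolerance = 1e-12)
    jk_scaled <- block_jackknife(v, 2 * w)
    expect_equal(jk_scaled$estimate, jk$estimate, tolerance = 1e-12)
    expect_equal(jk_scaled$se, jk$se, tolerance = 1e-12)
  }
  # degenerate variance
  jk0 <- block_jackknife(c(2, 2, 2))
  expect_true(jk0$degenerate)
  expect_equal(jk0$p, 0)  # nonzero estimate, zero SE
  expect_equal(block_jackknife(c(0, 0, 0))$p, 1)
})

test_that("BH q-values equal the brute-force step-up over permutations", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_true(is.na(bh_fdr(c(0.1, NA))[2]))
  base <- c(0.001, 0.02, 0.2, 0.5, 0.9, 0.04)
  perms <- list(1:6, 6:1, c(3, 1, 4, 2, 6, 5), c(2, 6, 1, 5, 3, 4))
  for (pp in perms) {
    p <- base[pp]
    expect_equal(bh_fdr(p), bf_bh(p), tolerance = 1e-14)
  }
  set.seed(1)
  for (k in 1:20) {
    p <- runif(sample(2:6, 1))
    q <- bh_fdr(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-14)
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted-p order
  }
})

test_that("TSV and BED outputs round trip / serialise deterministically", {
  df <- data.frame(chrom = c("c1", "c1"), start = c(0L, 100L),
                   end = c(100L, 250L), stat = c(0.5, -0.1))
  f <- tempfile(fileext = ".tsv")
  write_result_tsv(df, f)
  expect_identical(read_result_tsv(f), df)
  empty <- df[0, ]
  write_result_tsv(empty, f)
  expect_equal(nrow(read_result_tsv(f)), 0L)
  b <- tempfile(fileext = ".bed")
  write_bed(df, b, score = "stat")
  bed <- read.table(b, sep = "\t")
  expect_equal(bed$V2, df$start)
  expect_equal(bed$V5, df$stat)
})
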