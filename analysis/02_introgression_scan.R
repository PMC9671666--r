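#!/usr/bin/env Rscript
# Step 2: introgression statistics on the simulated cohort, reading the
# standard files written by step 1: Patterson's D with block jackknife,
# window f_d and Dxy, f-branch over the population tree, f4-ratio admixture
# proportion, and diagnostic-marker ancestry profiles.

library(apomixkit)

inp <- "results/inputs"; out <- "results/introgression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vcf <- read_vcf(file.path(inp, "cohort.vcf"))
pm <- read_population_map(file.path(inp, "populations.tsv"))
contigs <- setNames(rep(1e7, 5), paste0("chr", 1:5))

vt <- polarize_by_outgroup(vcf$variants, vcf$genotypes, pm, "outgroup")
cat("polarized", sum(vt$ancestral != "unknown"), "of", nrow(vt), "sites\n")
pops <- c("pop1", "pop2", "pop2X", "pop3A", "pop3B", "outgroup")
fr <- derived_freqs(vcf$genotypes, vt, pm, pops)

trio <- c(P1 = "pop1", P2 = "pop2X", P3 = "pop3A", outgroup = "outgroup")
wins <- make_windows(contigs, 5e5)
d <- patterson_d(fr, trio, vt, windows = wins)
cat(sprintf("genome-wide D = %.4f (Z = %.2f, p = %.2g)\n",
            d$D, d$jackknife$z, d$jackknife$p))
fd <- f_d(fr, trio, vt, wins, min_sites = 20)
cat(sprintf("mean window f_d = %.4f (planted m = 0.10)\n",
            mean(fd$fd, na.rm = TRUE)))
dx <- d_xy(fr, "pop2X", "pop3A", vt, wins)
scan <- fd
scan$dxy <- dx$dxy
write_result_tsv(scan, file.path(out, "window_scan.tsv"))
write_bed(fd[!is.na(fd$fd), ], file.path(out, "fd_windows.bed"), score = "fd")

alpha <- f4_ratio(fr, c(A = "pop3A", O = "outgroup", X = "pop2X",
                        B = "pop3B", C = "pop2"), vt)
cat(sprintf("f4-ratio alpha = %.4f +- %.4f\n", alpha$alpha,
            alpha$jackknife$se))

fb <- f_branch("(((pop1,(pop2,pop2X)),(pop3A,pop3B)),outgroup);", fr,
               "outgroup", vt)
write_result_tsv(data.frame(branch = rownames(fb$fb), fb$fb,
                            check.names = FALSE),
                 file.path(out, "fbranch_matrix.tsv"))
sig <- which(fb$q < 0.001, arr.ind = TRUE)
cat("f-branch entries significant at q < 0.001:",
    paste(sprintf("%s<-%s (f_b=%.3f)", rownames(fb$fb)[sig[, 1]],
                  colnames(fb$fb)[sig[, 2]], fb$fb[sig]), collapse = "; "),
    "\n")

mk <- diagnostic_markers(vcf$genotypes, pm, c("pop3A", "pop3B"), "pop2")
ap <- ancestry_profile(vcf$genotypes, vt, mk, windows = wins,
                       samples = pm$sample[pm$population %in%
                                             c("pop2X", "pop2")])
write_result_tsv(data.frame(sample = names(ap$total),
                            donor_ancestry = unname(ap$total)),
                 file.path(out, "ancestry_totals.tsv"))
write_result_tsv(ap$fragments, file.path(out, "ancestry_fragments.tsv"))
cat(sprintf("mean recovered donor ancestry: recipients %.3f, reference %.3f (%d markers)\n",
            mean(ap$total[pm$sample[pm$population == "pop2X"]]),
            mean(ap$total[pm$sample[pm$population == "pop2"]]), nrow(mk)))
cat("done: tables under", out, "\n")
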