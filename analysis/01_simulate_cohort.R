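#!/usr/bin/env Rscript
# Step 1: generate every input the downstream analyses consume, with
# recorded ground truth, as standard files under results/inputs/.
#
# The cohort: three Citrinae-like populations plus a near-fixed outgroup;
# ten "hybrid" accessions in pop2 carry 10% of their genome in donor (pop3)
# tracts; a deleterious annotation layer (SIFT-like scores); gene models
# with planted heterozygous deletions; a pseudo-testcross BSA family; MITE
# promoter-insertion read evidence and the two insertion haplotypes.

library(apomixkit)

out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

sim <- simulate_admixture_cohort(m = 0.10, seed = seed)
sim <- attach_deleterious_annotations(sim, fraction = 0.05,
                                      dfe = list(kind = "gamma", shape = 0.5,
                                                 mean = 0.05),
                                      seed = seed + 1)
write_vcf(sim$variants, sim$genotypes, file.path(out, "cohort.vcf"))
write_population_map(sim$pops, file.path(out, "populations.tsv"))
write_result_tsv(sim$truth$tracts, file.path(out, "truth_tracts.tsv"))
cat("cohort:", nrow(sim$pops), "samples,", nrow(sim$variants), "variants;",
    "planted m = 0.10 into", length(sim$roles$recipients), "recipients\n")

sv <- simulate_sv_and_genes(samples = sim$pops$sample[1:20],
                            hemi_fraction = 0.1, seed = seed + 2)
write_gff3(sv$genes, file.path(out, "genes.gff3"))
write_result_tsv(sv$deletions, file.path(out, "het_deletions.tsv"))
write_result_tsv(data.frame(sample = names(sv$truth_gh),
                            g_h = unname(sv$truth_gh)),
                 file.path(out, "truth_gh.tsv"))
cat("gene models:", nrow(sv$genes), "genes;",
    nrow(sv$deletions), "heterozygous deletions planted\n")

bsa <- simulate_f1_bsa(n_progeny = 300, bulk_size = 30, depth = 60,
                       n_markers = 5000, seed = seed + 3)
write_result_tsv(bsa$counts, file.path(out, "bsa_counts.tsv"))
write_result_tsv(data.frame(chrom = bsa$truth$qtl$chrom,
                            pos = bsa$truth$qtl$pos),
                 file.path(out, "truth_qtl.tsv"))
cat("BSA family:", length(bsa$phenotypes), "progeny,",
    sum(bsa$phenotypes), "apomictic :", sum(!bsa$phenotypes), "sexual\n")

# promoter-insertion cohort: 127 apomicts (mostly het), 60 sexuals (absent)
ins_truth <- data.frame(
  sample = sprintf("acc%03d", 1:187), locus = "RWP_promoter",
  genotype = c(rep("het", 124), rep("hom", 3), rep("absent", 60)),
  phenotype = c(rep("apomictic", 127), rep("sexual", 60)))
ev <- simulate_insertion_evidence(ins_truth, depth = 30, error = 0.01,
                                  seed = seed + 4)
write_result_tsv(cbind(ev, phenotype = ins_truth$phenotype),
                 file.path(out, "insertion_evidence.tsv"))
writeLines(c(">fortunella_hap_synthetic",
             synth_mite_haplotype(c(202, 202, 202), seed = seed + 5),
             ">citrus_hap_synthetic",
             synth_mite_haplotype(c(202, 227), seed = seed + 6)),
           file.path(out, "mite_insertions.fasta"))
cat("insertion evidence for", nrow(ev), "accessions written\n")
cat("done: inputs under", out, "\n")
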