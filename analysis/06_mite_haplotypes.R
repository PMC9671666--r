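#!/usr/bin/env Rscript
# Step 6: promoter MITE insertion genotyping from read support and
# decomposition of the two insertion haplotypes into MITE units sharing
# 5-bp TSD overlaps.

library(apomixkit)

inp <- "results/inputs"; out <- "results/mite"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ev <- read_result_tsv(file.path(inp, "insertion_evidence.tsv"))
calls <- call_insertion_genotype(ev$ins_reads, ev$ref_reads)
gt <- cbind(ev[, c("sample", "locus")], calls)
write_result_tsv(gt, file.path(out, "insertion_genotypes.tsv"))
called <- calls$call != "no_call"
cat(sprintf("genotype concordance with truth: %.1f%% of %d called (%d no_call)\n",
            100 * mean(calls$call[called] == ev$genotype[called]),
            sum(called), sum(!called)))

cz <- cohort_zygosity_summary(gt, setNames(ev$phenotype, ev$sample))
write_result_tsv(cz$summary, file.path(out, "zygosity_summary.tsv"))
apo_het <- cz$summary[cz$summary$phenotype == "apomictic" &
                        cz$summary$call == "het", ]
cat(sprintf("apomictic accessions heterozygous for the insertion: %.1f%%\n",
            apo_het$percent))

fa <- readLines(file.path(inp, "mite_insertions.fasta"))
seqs <- setNames(fa[!startsWith(fa, ">")], sub("^>", "", fa[startsWith(fa, ">")]))
for (nm in names(seqs)) {
  d <- decompose_insertion(seqs[[nm]])
  cat(sprintf("%s: %d bp = %d unit(s) of {%s} bp with %d-bp TSD overlaps -> %s\n",
              nm, nchar(seqs[[nm]]), d$n_units,
              paste(d$units$length, collapse = ", "), d$tsd_len,
              d$haplotype_class))
  write_result_tsv(cbind(haplotype = nm, d$units),
                   file.path(out, paste0("decomposition_", nm, ".tsv")))
}
cat("done: tables under", out, "\n")
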