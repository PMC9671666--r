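#' Configuration for the structured-genotype generator
#'
#' Defaults emulate a small Citrinae-like resource: three drifted ingroup
#' populations (Balding-Nichols model, F_ST 0.2), a near-fixed outgroup
#' standing in for a diverged genus (F = 0.99), 50k biallelic SNPs on five
#' 10 Mb chromosomes. Every stochastic call in the generator requires an
#' explicit seed; nothing touches the global RNG.
#'
#' @param n_pops number of ingroup populations.
#' @param n_per_pop samples per ingroup population.
#' @param n_outgroup outgroup samples.
#' @param n_variants number of SNP sites.
#' @param fst per-population drift parameter F in \[0, 1).
#' @param fst_outgroup outgroup drift parameter (near 1 so the outgroup is
#'   near-fixed at most sites).
#' @param beta_shape shape of the symmetric Beta for ancestral frequencies.
#' @param contigs named vector of contig lengths in bp.
#' @param pop_names population labels (defaults `pop1..popK` + `outgroup`).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_pops = 3, n_per_pop = 20, n_outgroup = 8,
                         n_variants = 50000, fst = 0.3, fst_outgroup = 0.99,
                         beta_shape = 0.5,
                         contigs = setNames(rep(1e7, 5), paste0("chr", 1:5)),
                         pop_names = NULL) {
  fst <- rep_len(fst, n_pops)
  stopifnot(all(fst >= 0), all(fst < 1), fst_outgroup > 0, fst_outgroup < 1)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pops))
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 n_outgroup = n_outgroup, n_variants = n_variants, fst = fst,
                 fst_outgroup = fst_outgroup, beta_shape = beta_shape,
                 contigs = contigs, pop_names = pop_names),
            class = "synth_config")
}

balding_nichols_freq <- function(p, F) {
  if (F == 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  # guard against degenerate shapes when p is at the boundary
  q <- rbeta(length(p), pmax(a, 1e-12), pmax(b, 1e-12))
  q[p == 0] <- 0; q[p == 1] <- 1
  q
}

#' Simulate structured diploid genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn from a symmetric Beta; each
#' population's frequencies from the Balding-Nichols Beta with its drift
#' parameter F; haplotypes are Bernoulli draws, so genotype dosages are
#' binomial(2, p_pop). The outgroup is simulated as a heavily drifted
#' population (F near 1), near-fixed at most sites, which makes outgroup
#' polarization meaningful.
#'
#' @param cfg [synth_config()].
#' @param seed integer seed (mandatory).
#' @return list with `variants` ([variant_table()]), `genotypes` (dosage
#'   matrix with a `"haplotypes"` attribute holding the two haplotype
#'   matrices), `pops` (population map data.frame), `contigs`, and `truth`
#'   (ancestral/population frequencies; later stages append to it).
#' @export
simulate_structured_genotypes <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, {
    L <- cfg$n_variants
    contigs <- cfg$contigs
    genome <- sum(as.numeric(contigs))
    gpos <- sort(sample.int(genome, L))
    offs <- cumsum(c(0, as.numeric(contigs)))
    ci <- findInterval(gpos - 1, offs, rightmost.closed = FALSE)
    chrom <- names(contigs)[ci]
    pos <- gpos - offs[ci]

    anc <- rbeta(L, cfg$beta_shape, cfg$beta_shape)
    pops <- c(cfg$pop_names, "outgroup")
    Fv <- c(cfg$fst, cfg$fst_outgroup)
    ns <- c(rep(cfg$n_per_pop, cfg$n_pops), cfg$n_outgroup)
    sample_ids <- unlist(lapply(seq_along(pops), function(i)
      sprintf("%s_s%02d", pops[i], seq_len(ns[i]))))
    pm <- data.frame(sample = sample_ids,
                     population = rep(pops, ns), stringsAsFactors = FALSE)

    hapA <- matrix(0L, sum(ns), L, dimnames = list(sample_ids, NULL))
    hapB <- hapA
    pop_freq <- matrix(NA_real_, L, length(pops), dimnames = list(NULL, pops))
    for (i in seq_along(pops)) {
      pf <- balding_nichols_freq(anc, Fv[i])
      pop_freq[, i] <- pf
      rows <- which(pm$population == pops[i])
      hapA[rows, ] <- matrix(rbinom(ns[i] * L, 1L, rep(pf, each = ns[i])), ns[i], L)
      hapB[rows, ] <- matrix(rbinom(ns[i] * L, 1L, rep(pf, each = ns[i])), ns[i], L)
    }
    gm <- hapA + hapB
    attr(gm, "haplotypes") <- list(hapA, hapB)

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    vt <- variant_table(chrom, pos, ref, alt)

    list(variants = vt, genotypes = gm, pops = pm, contigs = contigs,
         truth = list(seed = seed, ancestral_freq = anc, pop_freq = pop_freq,
                      tracts = NULL))
  })
}

# Draw non-overlapping tracts with exact total coverage m * genome:
# geometric lengths (mean tract_len), last tract trimmed, gaps placed by
# uniform stick-breaking over the uncovered space.
draw_tracts <- function(genome, m, tract_len) {
  if (m <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  target <- round(m * genome)
  lens <- numeric(0)
  while (sum(lens) < target)
    lens <- c(lens, rgeom(1, 1 / tract_len) + 1)
  lens[length(lens)] <- target - sum(lens[-length(lens)])
  k <- length(lens)
  free <- genome - target
  cuts <- sort(runif(k)) * free
  gaps <- c(cuts[1], diff(cuts))
  starts <- cumsum(gaps) + cumsum(c(0, lens[-k]))
  data.frame(start = floor(starts), end = floor(starts) + lens)
}

#' Plant introgression tracts from a donor population
#'
#' For each recipient haplotype, replaces non-overlapping tracts (geometric
#' lengths, mean `tract_len` bp) with the corresponding segment of a random
#' donor haplotype until exactly a fraction `m` of the genome is covered
#' (the last tract is trimmed). The exact tracts are recorded in
#' `truth$tracts` as 0-based half-open intervals.
#'
#' @param sim output of [simulate_structured_genotypes()].
#' @param donor donor population label.
#' @param recipients character vector of recipient sample IDs.
#' @param m target ancestry fraction per haplotype in \[0, 1\].
#' @param tract_len mean tract length in bp.
#' @param seed integer seed.
#' @return `sim` with updated haplotypes/dosages and truth tracts.
#' @export
plant_introgression_tracts <- function(sim, donor, recipients, m, tract_len,
                                       seed) {
  stopifnot(m >= 0, m <= 1)
  if (m == 0) return(sim)
  donors <- pop_samples(sim$pops, donor, rownames(sim$genotypes))
  stopifnot(!any(recipients %in% donors))
  with_seed(seed, {
    hap <- attr(sim$genotypes, "haplotypes")
    contigs <- sim$contigs
    offs <- cumsum(c(0, as.numeric(contigs)))
    genome <- sum(as.numeric(contigs))
    vt <- sim$variants
    site_g <- offs[match(vt$chrom, names(contigs))] + (vt$pos - 1)
    rec_tracts <- list()
    for (s in recipients) {
      for (h in 1:2) {
        tr <- if (m >= 1) data.frame(start = 0, end = genome)
              else draw_tracts(genome, m, tract_len)
        for (t in seq_len(nrow(tr))) {
          dsamp <- sample(donors, 1L)
          dh <- sample(1:2, 1L)
          in_tract <- site_g >= tr$start[t] & site_g < tr$end[t]
          hap[[h]][s, in_tract] <- hap[[dh]][dsamp, in_tract]
          # split the genomic tract back into per-chromosome intervals
          for (ci in seq_along(contigs)) {
            a <- max(tr$start[t], offs[ci]); b <- min(tr$end[t], offs[ci + 1])
            if (a < b)
              rec_tracts[[length(rec_tracts) + 1L]] <- data.frame(
                sample = s, hap = h, chrom = names(contigs)[ci],
                start = a - offs[ci], end = b - offs[ci], donor = dsamp)
          }
        }
      }
    }
    gm <- hap[[1]] + hap[[2]]
    attr(gm, "haplotypes") <- hap
    sim$genotypes <- gm
    sim$truth$tracts <- rbind(sim$truth$tracts, do.call(rbind, rec_tracts))
    sim$truth$planted_m <- m
    sim
  })
}

#' Attach a deleterious-variant annotation layer
#'
#' Marks a fraction of SNPs deleterious: SIFT scores uniform in \[0, 0.05\]
#' for deleterious sites and in (0.05, 1\] for neutral ones, a
#' loss-of-function flag on a sub-fraction, and per-site selection/dominance
#' coefficients recorded in the truth (fixed s or gamma-distributed).
#'
#' @param sim generator output (or any list with `variants` + `truth`).
#' @param fraction fraction of SNPs that are deleterious.
#' @param dfe `list(kind = "fixed", s = ...)` or
#'   `list(kind = "gamma", shape = ..., mean = ...)`.
#' @param lof_fraction fraction of deleterious sites also flagged LOF.
#' @param h dominance coefficient recorded in the truth.
#' @param seed integer seed.
#' @return `sim` with annotated variants and `truth$deleterious`,
#'   `truth$s`, `truth$h` filled in.
#' @export
attach_deleterious_annotations <- function(sim, fraction = 0.05,
                                           dfe = list(kind = "fixed", s = 0.05),
                                           lof_fraction = 0.2, h = 0, seed) {
  with_seed(seed, {
    vt <- sim$variants
    snp <- which(vt$vtype == "SNP")
    n_del <- round(fraction * length(snp))
    del <- sort(sample(snp, n_del))
    sift <- rep(NA_real_, nrow(vt))
    sift[snp] <- 0.05 + runif(length(snp)) * 0.95
    sift[del] <- runif(n_del) * 0.05
    lof <- rep(FALSE, nrow(vt))
    lof[sample(del, round(lof_fraction * n_del))] <- TRUE
    s <- rep(0, nrow(vt))
    s[del] <- switch(dfe$kind,
      fixed = dfe$s,
      gamma = rgamma(n_del, shape = dfe$shape, scale = dfe$mean / dfe$shape),
      stop("unknown DFE kind"))
    vt$sift_score <- sift
    vt$lof_flag <- lof
    sim$variants <- vt
    sim$truth$deleterious <- del
    sim$truth$s <- s
    sim$truth$h <- h
    sim
  })
}

#' Simulate the admixture-profiling cohort
#'
#' The fixed study design used for ancestry-profile and f4-ratio parameter
#' recovery: three populations plus outgroup, with the donor population
#' strongly diverged (F = 0.7; species-specific diagnostic markers only
#' exist between strongly diverged species), ten recipient samples drawn
#' from pop2, the remaining thirty pop2 samples as the un-introgressed
#' reference panel, and the donor panel split in half (pop3A/pop3B) so the
#' f4-ratio has a donor-side reference sharing the donor's drift. A
#' fraction `m` of each recipient haplotype is replaced by donor tracts.
#'
#' @param m planted ancestry fraction.
#' @param seed integer seed.
#' @param n_variants marker count (default 30000).
#' @param tract_len mean tract length in bp (default 1 Mb).
#' @return generator output with roles recorded in `sim$roles` and the
#'   population map relabelled (`pop2X` = recipients, `pop3A`/`pop3B` =
#'   donor panel halves).
#' @export
simulate_admixture_cohort <- function(m, seed, n_variants = 30000,
                                      tract_len = 1e6) {
  cfg <- synth_config(n_variants = n_variants, n_per_pop = 40,
                      fst = c(0.3, 0.3, 0.7))
  sim <- simulate_structured_genotypes(cfg, seed = seed)
  pm <- sim$pops
  pop2 <- pm$sample[pm$population == "pop2"]
  pop3 <- pm$sample[pm$population == "pop3"]
  rec <- pop2[1:10]
  if (m > 0)
    sim <- plant_introgression_tracts(sim, "pop3", rec, m = m,
                                      tract_len = tract_len, seed = seed + 1e6)
  pm$population[pm$sample %in% rec] <- "pop2X"
  pm$population[pm$sample %in% pop3[1:20]] <- "pop3A"
  pm$population[pm$sample %in% pop3[21:40]] <- "pop3B"
  sim$pops <- pm
  sim$roles <- list(recipients = rec, donor = "pop3",
                    donor_panels = c("pop3A", "pop3B"), reference = "pop2",
                    m = m)
  sim
}

#' Simulate an F1 pseudo-testcross and bulked-segregant read counts
#'
#' One apomixis QTL, heterozygous in the apomictic parent and absent from
#' the sexual parent; markers likewise heterozygous in the apomictic parent
#' only, so every marker segregates 1:1. The apomictic parent's gametes are
#' generated as a Markov chain along each chromosome with Haldane
#' recombination fractions; phenotype = carries the QTL allele (dominant).
#' Bulks are random subsets of each phenotype class; per-marker read depths
#' are Poisson around `depth` and alt-read counts binomial at the bulk
#' allele frequency.
#'
#' @param n_progeny F1 family size.
#' @param bulk_size individuals per bulk (must be <= `n_progeny / 2`).
#' @param depth mean read depth per marker per bulk.
#' @param n_markers marker count.
#' @param contigs named contig lengths (bp).
#' @param qtl `list(chrom = , pos = )` true QTL location.
#' @param cM_per_Mb genetic map density (default 3 cM/Mb).
#' @param seed integer seed.
#' @return list with `counts` (per-marker bulk read counts: `chrom pos
#'   ref_high alt_high ref_low alt_low`; the "high" bulk carries the QTL),
#'   `phenotypes` (logical per progeny), and `truth` (QTL position).
#' @export
simulate_f1_bsa <- function(n_progeny = 300, bulk_size = 30, depth = 60,
                            n_markers = 5000,
                            contigs = setNames(rep(3.6e7, 9), paste0("chr", 1:9)),
                            qtl = list(chrom = "chr4", pos = 2.8e7),
                            cM_per_Mb = 3, seed) {
  if (bulk_size > n_progeny / 2)
    stop("bulk_size must not exceed n_progeny / 2")
  with_seed(seed, {
    genome <- sum(as.numeric(contigs))
    gpos <- sort(sample.int(genome, n_markers))
    offs <- cumsum(c(0, as.numeric(contigs)))
    ci <- findInterval(gpos - 1, offs)
    chrom <- names(contigs)[ci]
    pos <- gpos - offs[ci]

    morgan_per_bp <- cM_per_Mb / 100 / 1e6
    gam <- matrix(0L, n_progeny, n_markers)
    qtl_allele <- integer(n_progeny)
    for (ch in names(contigs)) {
      idx <- which(chrom == ch)
      p <- pos[idx]
      has_qtl <- identical(ch, qtl$chrom)
      if (has_qtl) {
        p_all <- sort(c(p, qtl$pos))
        qtl_at <- which(p_all == qtl$pos)[1]
      } else p_all <- p
      k <- length(p_all)
      r <- 0.5 * (1 - exp(-2 * diff(p_all) * morgan_per_bp))
      a <- matrix(0L, n_progeny, k)
      a[, 1] <- rbinom(n_progeny, 1L, 0.5)
      for (j in seq_len(k - 1)) {
        flip <- rbinom(n_progeny, 1L, r[j])
        a[, j + 1] <- ifelse(flip == 1L, 1L - a[, j], a[, j])
      }
      if (has_qtl) {
        qtl_allele <- a[, qtl_at]
        a <- a[, -qtl_at, drop = FALSE]
        # when a marker shares the QTL position keep both, marker first
        if (ncol(a) != length(idx)) a <- a[, seq_along(idx), drop = FALSE]
      }
      gam[, idx] <- a
    }
    phen <- qtl_allele == 1L
    carriers <- which(phen); noncar <- which(!phen)
    if (length(carriers) < bulk_size || length(noncar) < bulk_size)
      stop("phenotype classes smaller than bulk_size; increase n_progeny")
    bulk_high <- sample(carriers, bulk_size)
    bulk_low <- sample(noncar, bulk_size)

    count_bulk <- function(rows) {
      freq <- colMeans(gam[rows, , drop = FALSE]) / 2  # other allele from PN is ref
      dp <- rpois(n_markers, depth)
      alt <- rbinom(n_markers, dp, freq)
      cbind(ref = dp - alt, alt = alt)
    }
    hi <- count_bulk(bulk_high); lo <- count_bulk(bulk_low)
    counts <- data.frame(chrom = chrom, pos = pos,
                         ref_high = hi[, "ref"], alt_high = hi[, "alt"],
                         ref_low = lo[, "ref"], alt_low = lo[, "alt"],
                         stringsAsFactors = FALSE)
    list(counts = counts, phenotypes = phen,
         truth = list(qtl = qtl, seed = seed))
  })
}

#' Simulate gene models and per-sample heterozygous deletions
#'
#' Places non-overlapping gene intervals on the contigs, then for each
#' sample plants heterozygous deletions so that exactly a configured
#' fraction of genes is removed by more than half (each such deletion covers
#' 55-95% of its gene); additional decoy deletions cover at most 40% of
#' other genes and must not flip them. The truth records the exact
#' hemizygous-gene fraction per sample.
#'
#' @param contigs named contig lengths (bp).
#' @param n_genes number of genes.
#' @param gene_len gene length in bp.
#' @param samples sample IDs.
#' @param hemi_fraction fraction of genes hemizygous per sample (scalar or
#'   per-sample vector).
#' @param n_decoys decoy deletions per sample (< 50% coverage).
#' @param seed integer seed.
#' @return list with `genes` (0-based data.frame), `deletions` (per-sample
#'   het-deletion intervals), `truth_gh` (named per-sample fractions).
#' @export
simulate_sv_and_genes <- function(contigs = setNames(rep(1e7, 2), c("chr1", "chr2")),
                                  n_genes = 200, gene_len = 3000, samples,
                                  hemi_fraction = 0.1, n_decoys = 5, seed) {
  hemi_fraction <- rep_len(hemi_fraction, length(samples))
  with_seed(seed, {
    per_contig <- diff(round(seq(0, n_genes, length.out = length(contigs) + 1)))
    genes <- do.call(rbind, lapply(seq_along(contigs), function(i) {
      n <- per_contig[i]
      if (n == 0) return(NULL)
      starts <- round(seq(1e4, contigs[[i]] - gene_len - 1e4, length.out = n))
      data.frame(chrom = names(contigs)[i], start = starts,
                 end = starts + gene_len,
                 gene_id = sprintf("%s_g%03d", names(contigs)[i], seq_len(n)),
                 stringsAsFactors = FALSE)
    }))
    dels <- list(); gh <- setNames(numeric(length(samples)), samples)
    for (k in seq_along(samples)) {
      n_hemi <- round(hemi_fraction[k] * nrow(genes))
      hit <- if (n_hemi > 0) sample(nrow(genes), n_hemi) else integer(0)
      rest <- setdiff(seq_len(nrow(genes)), hit)
      decoy <- if (n_decoys > 0) sample(rest, min(n_decoys, length(rest))) else integer(0)
      mk <- function(i, frac) {
        len <- ceiling(frac * gene_len)
        off <- sample.int(gene_len - len + 1L, 1L) - 1L
        data.frame(sample = samples[k], chrom = genes$chrom[i],
                   start = genes$start[i] + off, end = genes$start[i] + off + len,
                   stringsAsFactors = FALSE)
      }
      for (i in hit) dels[[length(dels) + 1L]] <- mk(i, runif(1, 0.55, 0.95))
      for (i in decoy) dels[[length(dels) + 1L]] <- mk(i, runif(1, 0.2, 0.4))
      gh[k] <- n_hemi / nrow(genes)
    }
    list(genes = genes,
         deletions = if (length(dels)) do.call(rbind, dels)
                     else data.frame(sample = character(0), chrom = character(0),
                                     start = numeric(0), end = numeric(0)),
         truth_gh = gh)
  })
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with 0-based `start`, `end`, `gene_id`.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "apomixkit", "gene", genes$start + 1, genes$end,
                   ".", "+", ".", paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate insertion-supporting read evidence
#'
#' Read support for a promoter MITE insertion: insertion-supporting read
#' counts are binomial(depth, theta) with theta = `error`, 0.5 and
#' `1 - error` for absent, heterozygous and homozygous insertion genotypes.
#'
#' @param truth data.frame with columns `sample`, `locus`, `genotype`
#'   (`"absent"`, `"het"`, `"hom"`).
#' @param depth read depth per locus.
#' @param error read misassignment rate.
#' @param seed integer seed.
#' @return data.frame `sample locus ins_reads ref_reads` (plus the truth
#'   genotype column for convenience).
#' @export
simulate_insertion_evidence <- function(truth, depth = 30, error = 0.01, seed) {
  stopifnot(all(truth$genotype %in% c("absent", "het", "hom")))
  with_seed(seed, {
    theta <- c(absent = error, het = 0.5, hom = 1 - error)[truth$genotype]
    ins <- rbinom(nrow(truth), depth, theta)
    data.frame(sample = truth$sample, locus = truth$locus,
               ins_reads = ins, ref_reads = depth - ins,
               genotype = truth$genotype, stringsAsFactors = FALSE)
  })
}
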