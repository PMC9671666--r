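#' Classify deleterious variants
#'
#' Deterministic classification from the annotation layer: SNPs with
#' SIFT score <= `sift_threshold` (inclusive) are deleterious; LOF-flagged
#' SNPs form their own class when `include_lof`; SVs of the listed classes
#' are counted as deleterious wholesale.
#'
#' @param vt annotated [variant_table()].
#' @param sift_threshold SIFT cutoff (default 0.05, inclusive).
#' @param include_lof include the LOF class.
#' @param sv_classes SV types treated as deleterious.
#' @return list of class `deleterious_set` with integer index vectors
#'   `deleterious_snp`, `lof`, `deleterious_sv`, `all` (union) and the
#'   thresholds used. Warns when nothing is annotated.
#' @export
classify_deleterious <- function(vt, sift_threshold = 0.05, include_lof = TRUE,
                                 sv_classes = c("DEL", "DUP", "TRA", "INV")) {
  del_snp <- which(vt$vtype == "SNP" & !is.na(vt$sift_score) &
                     vt$sift_score <= sift_threshold)
  lof <- if (include_lof) which(vt$lof_flag) else integer(0)
  del_sv <- which(vt$vtype %in% sv_classes)
  if (!length(del_snp) && !length(lof) && !length(del_sv))
    warning("no annotated deleterious variants found")
  structure(list(deleterious_snp = del_snp, lof = lof, deleterious_sv = del_sv,
                 all = sort(union(union(del_snp, lof), del_sv)),
                 sift_threshold = sift_threshold, sv_classes = sv_classes),
            class = "deleterious_set")
}

#' Per-sample deleterious burden
#'
#' Counts heterozygous and homozygous-derived deleterious genotypes per
#' sample and class, plus the two load models: additive burden = allele
#' count (`n_het + 2 * n_hom`) and recessive burden = homozygous count.
#' Missing genotypes contribute nothing. Dosages are assumed on the derived
#' scale for polarized data; for the recessive/additive identity only
#' hom-alt (dosage 2) counts as homozygous-derived.
#'
#' @param gm dosage matrix.
#' @param dset [classify_deleterious()] output.
#' @param classes which classes to tabulate (default all three plus pooled).
#' @return data.frame, one row per sample x class, with `n_het`, `n_hom`,
#'   `additive_burden`, `recessive_burden`, `n_called`, `low_call` flag.
#' @export
burden_per_sample <- function(gm, dset,
                              classes = c("deleterious_snp", "lof",
                                          "deleterious_sv", "all")) {
  stopifnot(inherits(dset, "deleterious_set"))
  out <- lapply(classes, function(cl) {
    idx <- dset[[cl]]
    d <- gm[, idx, drop = FALSE]
    n_het <- rowSums(d == 1L, na.rm = TRUE)
    n_hom <- rowSums(d == 2L, na.rm = TRUE)
    n_called <- rowSums(!is.na(d))
    data.frame(sample = rownames(gm), class = cl, n_het = n_het,
               n_hom = n_hom, additive_burden = n_het + 2L * n_hom,
               recessive_burden = n_hom, n_called = n_called,
               low_call = n_called == 0L, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Hemizygous-gene fraction g_h
#'
#' A gene is hemizygous when the merged heterozygous deletions of a genome
#' remove strictly more than `overlap_frac` of its length (strict ">",
#' matching the "missing >50%" definition). Intervals are 0-based
#' half-open; deletions are merged per sample before measuring, so g_h is
#' invariant to splitting a deletion into abutting pieces.
#'
#' @param genes data.frame of gene intervals (`chrom`, `start`, `end`).
#' @param het_deletions data.frame (`sample`, `chrom`, `start`, `end`) of
#'   heterozygous deletion calls.
#' @param overlap_frac overlap fraction threshold (default 0.5).
#' @param samples samples to evaluate (default those present in
#'   `het_deletions`).
#' @return data.frame per sample: `n_genes`, `n_hemizygous`, `g_h`.
#' @export
hemizygous_fraction <- function(genes, het_deletions, overlap_frac = 0.5,
                                samples = unique(het_deletions$sample)) {
  if (nrow(genes) == 0) stop("zero genes supplied")
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1, genes$end))
  res <- lapply(samples, function(s) {
    d <- het_deletions[het_deletions$sample == s, , drop = FALSE]
    n_hemi <- 0L
    if (nrow(d)) {
      dr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        d$chrom, IRanges::IRanges(d$start + 1, d$end)))
      cov <- rep(0, length(g))
      hits <- GenomicRanges::findOverlaps(g, dr)
      if (length(hits)) {
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        w <- IRanges::width(IRanges::pintersect(IRanges::ranges(g)[qh],
                                                IRanges::ranges(dr)[sh]))
        agg <- tapply(w, factor(qh, levels = seq_along(g)), sum)
        cov <- ifelse(is.na(agg), 0, agg)
      }
      n_hemi <- sum(cov / IRanges::width(g) > overlap_frac)
    }
    data.frame(sample = s, n_genes = nrow(genes), n_hemizygous = n_hemi,
               g_h = n_hemi / nrow(genes), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Spearman rank correlation (t approximation)
#'
#' rho is the Pearson correlation of average ranks; the two-sided p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' n - 2 degrees of freedom (documented choice; exact permutation null not
#' used). Requires >= 5 paired observations; constant input yields an
#' undefined rho with a flag.
#'
#' @param x,y numeric vectors.
#' @return list with `rho`, `p`, `n`, `undefined`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 5)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n, undefined = FALSE))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n,
       undefined = FALSE)
}

#' Correlate burden with introgressed ancestry
#'
#' Spearman correlation between a per-sample burden column and the total
#' donor-ancestry proportion from [ancestry_profile()].
#'
#' @param burdens [burden_per_sample()] output (one class).
#' @param ancestry named per-sample ancestry proportions.
#' @param column burden column (default `"n_het"`).
#' @return [spearman_cor()] result.
#' @export
correlate_burden_introgression <- function(burdens, ancestry,
                                           column = "n_het") {
  common <- intersect(burdens$sample, names(ancestry))
  b <- burdens[match(common, burdens$sample), column]
  spearman_cor(ancestry[common], b)
}

#' Group burden contrast with bootstrap CI
#'
#' Ratio (or percent difference) of group mean burdens, with a seeded
#' nonparametric bootstrap (resampling samples within group) percentile CI.
#'
#' @param burdens per-sample burden table (one class).
#' @param pm population map.
#' @param groupA,groupB population label vectors.
#' @param column burden column (default `"n_het"`).
#' @param statistic `"ratio"` (A/B) or `"percent_diff"`
#'   (100 * (B - A) / B).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `estimate`, `ci` (2.5/97.5 percentiles), `mean_a`,
#'   `mean_b`.
#' @export
burden_contrast <- function(burdens, pm, groupA, groupB, column = "n_het",
                            statistic = c("ratio", "percent_diff"),
                            n_boot = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  a <- burdens[burdens$sample %in% pop_samples(pm, groupA), column]
  b <- burdens[burdens$sample %in% pop_samples(pm, groupB), column]
  stopifnot(length(a) > 0, length(b) > 0)
  stat <- function(a, b) switch(statistic,
    ratio = mean(a) / mean(b),
    percent_diff = 100 * (mean(b) - mean(a)) / mean(b))
  boot <- with_seed(seed, replicate(n_boot,
    stat(sample(a, replace = TRUE), sample(b, replace = TRUE))))
  list(estimate = stat(a, b),
       ci = unname(quantile(boot, c(0.025, 0.975))),
       mean_a = mean(a), mean_b = mean(b))
}
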