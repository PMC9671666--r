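#' @useDynLib apomixkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm pchisq plnorm pt cor rbeta rbinom rgeom rpois runif
#'   rgamma rexp mad median quantile setNames p.adjust complete.cases
#' @importFrom utils read.table write.table head tail
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "TRA", "INS")

#' Construct a variant table
#'
#' A variant table is the per-site annotation substrate shared by every
#' analysis: one row per biallelic variant (SNP or SV), sorted by
#' (chrom, pos). Positions are 1-based (as in VCF); all interval arithmetic
#' inside the package is 0-based half-open and conversion happens at I/O.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions.
#' @param ref,alt allele strings (single bases for SNPs).
#' @param vtype one of `"SNP"`, `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`, `"INS"`.
#' @param svlen SV length in bp (`NA` for SNPs); stored as a positive length
#'   regardless of the VCF sign convention for deletions.
#' @param sift_score SIFT score in \[0, 1\] (`NA` when unannotated; SNPs only).
#' @param lof_flag logical loss-of-function flag.
#' @param ancestral `"ref"`, `"alt"` or `"unknown"` (set by
#'   [polarize_by_outgroup()]).
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, vtype = "SNP", svlen = NA_integer_,
                          sift_score = NA_real_, lof_flag = FALSE,
                          ancestral = "unknown") {
  vt <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    vtype = as.character(vtype), svlen = as.integer(svlen),
    sift_score = as.numeric(sift_score), lof_flag = as.logical(lof_flag),
    ancestral = as.character(ancestral),
    stringsAsFactors = FALSE
  )
  stopifnot(all(vt$vtype %in% c("SNP", SV_TYPES)))
  bad_snp <- vt$vtype == "SNP" & (nchar(vt$ref) != 1L | nchar(vt$alt) != 1L)
  if (any(bad_snp)) stop("SNP records must have single-base ref and alt")
  if (any(!is.na(vt$sift_score) & vt$vtype != "SNP"))
    stop("sift_score may only be present for SNPs")
  if (any(!is.na(vt$svlen) & vt$svlen < 1L)) stop("svlen must be >= 1")
  o <- order(vt$chrom, vt$pos)
  if (is.unsorted(o)) vt <- vt[o, , drop = FALSE]
  rownames(vt) <- NULL
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Read a VCF into a variant table and genotype matrix
#'
#' Parses a VCF 4.2+ file (via \pkg{vcfR}) into the package's two core
#' containers: a [variant_table()] and a samples x variants integer dosage
#' matrix (counts of the ALT allele; `NA` for missing genotypes). SV records
#' are recognised by `INFO/SVTYPE` (with `INFO/SVLEN` normalised to a
#' positive length); SIFT scores are read from `INFO/SIFT` and ancestral
#' alleles from `INFO/AA` when present.
#'
#' @param path path to a (plain-text or bgzipped) VCF.
#' @param multiallelic `"drop"` (default) removes multi-allelic records;
#'   `"split"` expands them into one biallelic record per ALT allele, with
#'   dosages counting that allele.
#' @return list with elements `variants` ([variant_table()]), `genotypes`
#'   (integer matrix, samples in rows), and `n_skipped` (records dropped for
#'   unknown SVTYPE, with a warning when non-zero).
#' @export
read_vcf <- function(path, multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt[, -1, drop = FALSE]
  samples <- colnames(gt_raw)
  gt_field <- sub(":.*$", "", gt_raw)  # GT is required first per VCF spec

  info_get <- function(key) {
    m <- regmatches(fix$INFO, regexec(paste0("(?:^|;)", key, "=([^;]+)"), fix$INFO))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  svtype <- info_get("SVTYPE")
  svlen <- suppressWarnings(as.integer(info_get("SVLEN")))
  sift <- suppressWarnings(as.numeric(info_get("SIFT")))
  aa <- info_get("AA")

  is_multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- rep(TRUE, nrow(fix))
  unknown_sv <- !is.na(svtype) & !(svtype %in% SV_TYPES)
  if (any(unknown_sv)) {
    warning(sum(unknown_sv), " record(s) with unknown SVTYPE skipped")
    keep[unknown_sv] <- FALSE
  }

  rows <- list(); dos <- list()
  alleles_of <- function(g) strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
  for (i in which(keep)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (is_multi[i] && multiallelic == "drop") next
    al <- alleles_of(gt_field[i, ])
    for (k in seq_along(alts)) {
      d <- vapply(al, function(a) {
        if (length(a) == 0L || anyNA(a) || any(a == "."))
          return(NA_integer_)
        sum(a == as.character(k))
      }, 1L)
      vt_type <- if (!is.na(svtype[i])) svtype[i] else "SNP"
      if (vt_type == "SNP" && (nchar(fix$REF[i]) != 1L || nchar(alts[k]) != 1L))
        vt_type <- if (nchar(fix$REF[i]) > nchar(alts[k])) "DEL" else "INS"
      anc <- "unknown"
      if (!is.na(aa[i])) {
        anc <- if (identical(aa[i], fix$REF[i])) "ref"
               else if (identical(aa[i], alts[k])) "alt" else "unknown"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], vtype = vt_type,
        svlen = if (is.na(svlen[i])) NA_integer_ else abs(svlen[i]),
        sift_score = if (vt_type == "SNP") sift[i] else NA_real_,
        lof_flag = grepl("(?:^|;)LOF(?:;|$|=1)", fix$INFO[i]),
        ancestral = anc, stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- d
    }
  }
  if (!length(rows)) stop("no usable biallelic records in ", path)
  vt <- do.call(rbind, rows)
  gm <- t(vapply(dos, identity, integer(length(samples))))
  o <- order(vt$chrom, vt$pos)
  vt <- vt[o, , drop = FALSE]; rownames(vt) <- NULL
  gm <- t(gm[o, , drop = FALSE])
  rownames(gm) <- samples
  class(vt) <- c("variant_table", "data.frame")
  list(variants = vt, genotypes = gm, n_skipped = sum(unknown_sv))
}

#' Write a variant table and genotype matrix as VCF 4.2
#'
#' Inverse of [read_vcf()] for the package's own containers; used by the
#' synthetic-data generator so every emitted input is a standard file.
#' Haplotypes (attribute `"haplotypes"` on the genotype matrix) are written
#' phased (`0|1`); otherwise unphased genotypes consistent with the dosage.
#'
#' @param vt [variant_table()].
#' @param gm samples x variants dosage matrix.
#' @param path output path.
#' @export
write_vcf <- function(vt, gm, path) {
  stopifnot(nrow(vt) == ncol(gm))
  hap <- attr(gm, "haplotypes")
  info <- rep("", nrow(vt))
  add <- function(info, txt, mask) ifelse(mask, paste0(info, ifelse(nzchar(info), ";", ""), txt), info)
  info <- add(info, paste0("SVTYPE=", vt$vtype), vt$vtype != "SNP")
  info <- add(info, paste0("SVLEN=", ifelse(vt$vtype == "DEL", -vt$svlen, vt$svlen)), !is.na(vt$svlen))
  info <- add(info, paste0("SIFT=", format(vt$sift_score, trim = TRUE, digits = 6)), !is.na(vt$sift_score))
  info <- add(info, "LOF=1", vt$lof_flag)
  aa <- ifelse(vt$ancestral == "ref", vt$ref, ifelse(vt$ancestral == "alt", vt$alt, NA))
  info <- add(info, paste0("AA=", aa), !is.na(aa))
  info[!nzchar(info)] <- "."

  if (!is.null(hap)) {
    gts <- matrix(paste0(t(hap[[1]]), "|", t(hap[[2]])), nrow = nrow(vt))
    gts[is.na(t(gm))] <- ".|."
  } else {
    d <- t(gm)
    gts <- matrix("./.", nrow = nrow(vt), ncol = nrow(gm))
    gts[d == 0L] <- "0/0"; gts[d == 1L] <- "0/1"; gts[d == 2L] <- "1/1"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=LOF,Number=0,Type=Flag,Description=\"Loss of function\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm)), collapse = "\t"))
  body <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", info, "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' Two-column TSV `sample<TAB>population`. Role bindings (P1/P2/P3/outgroup,
#' donor/recipient) are supplied per analysis as population labels.
#'
#' @param path TSV path.
#' @return data.frame with columns `sample`, `population`.
#' @export
read_population_map <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("sample", "population"))
  pm
}

#' @rdname read_population_map
#' @param pm population map data.frame.
#' @export
write_population_map <- function(pm, path) {
  write.table(pm[, c("sample", "population")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

pop_samples <- function(pm, population, samples = NULL) {
  s <- pm$sample[pm$population %in% population]
  if (!is.null(samples)) s <- intersect(s, samples)
  if (!length(s)) stop("no samples for population(s) ", paste(population, collapse = ","))
  s
}

#' Polarize variants by the outgroup major allele
#'
#' Sets the `ancestral` column of the variant table to the major allele of
#' the outgroup population. Sites where the outgroup minor-allele frequency
#' exceeds `max_og_minor`, or where the outgroup is entirely missing, are
#' marked `"unknown"` and excluded from all polarized statistics downstream.
#' The operation is idempotent: it depends only on the outgroup genotypes.
#'
#' @param vt [variant_table()].
#' @param gm dosage matrix (samples x variants).
#' @param pm population map.
#' @param outgroup outgroup population label(s).
#' @param max_og_minor maximum tolerated outgroup minor-allele frequency
#'   (default 0.1) before a site is treated as unpolarizable.
#' @return `vt` with `ancestral` filled in.
#' @export
polarize_by_outgroup <- function(vt, gm, pm, outgroup, max_og_minor = 0.1) {
  stopifnot(max_og_minor >= 0, max_og_minor < 0.5)
  og <- pop_samples(pm, outgroup, rownames(gm))
  d <- gm[og, , drop = FALSE]
  n <- 2L * colSums(!is.na(d))
  falt <- colSums(d, na.rm = TRUE) / n
  minor <- pmin(falt, 1 - falt)
  anc <- ifelse(falt < 0.5, "ref", ifelse(falt > 0.5, "alt", "unknown"))
  anc[n == 0L | minor > max_og_minor] <- "unknown"
  vt$ancestral <- anc
  vt
}

#' Per-population derived-allele frequencies
#'
#' Computes, for each requested population, the derived-allele frequency at
#' every polarized site: derived count / called alleles, with missing
#' genotypes excluded from the denominator. Sites that are unpolarized, or
#' where any requested population has fewer than `min_n` called alleles, are
#' masked (`NA`).
#'
#' @param gm dosage matrix.
#' @param vt polarized [variant_table()].
#' @param pm population map.
#' @param populations character vector of population labels.
#' @param min_n minimum called alleles per population (default 2).
#' @return numeric matrix, sites x populations, with attribute `"n_alleles"`
#'   (called-allele counts of the same shape).
#' @export
derived_freqs <- function(gm, vt, pm, populations, min_n = 2) {
  f <- matrix(NA_real_, nrow(vt), length(populations),
              dimnames = list(NULL, populations))
  n_all <- f
  for (p in populations) {
    d <- gm[pop_samples(pm, p, rownames(gm)), , drop = FALSE]
    n <- 2L * colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    der <- ifelse(vt$ancestral == "ref", alt,
                  ifelse(vt$ancestral == "alt", n - alt, NA_real_))
    fp <- der / n
    fp[n < min_n] <- NA_real_
    f[, p] <- fp
    n_all[, p] <- n
  }
  f[vt$ancestral == "unknown", ] <- NA_real_
  keep_na <- apply(f, 1, anyNA)
  f[keep_na, ] <- NA_real_  # a site is used only with all populations called
  attr(f, "n_alleles") <- n_all
  f
}

# Alt-allele (unpolarized) population frequencies; used for diagnostic markers.
pop_freqs_alt <- function(gm, pm, populations, min_n = 2) {
  f <- matrix(NA_real_, ncol(gm), length(populations),
              dimnames = list(NULL, populations))
  for (p in populations) {
    d <- gm[pop_samples(pm, p, rownames(gm)), , drop = FALSE]
    n <- 2L * colSums(!is.na(d))
    fp <- colSums(d, na.rm = TRUE) / n
    fp[n < min_n] <- NA_real_
    f[, p] <- fp
  }
  f
}

#' Tile contigs with (possibly overlapping) windows
#'
#' 0-based half-open windows; the final partial window is retained.
#'
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param size window size in bp.
#' @param step step in bp (default `size`, i.e. non-overlapping).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_windows <- function(contig_lengths, size, step = size) {
  stopifnot(size >= 1, step >= 1, !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, len))
  })
  do.call(rbind, out)
}

# Window index of each site (first matching window when overlapping windows
# are used callers should iterate windows instead).
window_of <- function(chrom, pos0, windows) {
  idx <- rep(NA_integer_, length(pos0))
  for (w in seq_len(nrow(windows))) {
    hit <- chrom == windows$chrom[w] & pos0 >= windows$start[w] & pos0 < windows$end[w]
    idx[hit & is.na(idx)] <- w
  }
  idx
}

#' Assign sites to equal-span jackknife blocks
#'
#' Splits the genome (concatenated contigs) into `n_blocks` equal spans and
#' returns the block index of each variant. Used to form the per-block sums
#' consumed by [block_jackknife()].
#'
#' @param vt [variant_table()].
#' @param contig_lengths named contig lengths; defaults to the maximum
#'   position per chromosome.
#' @param n_blocks number of blocks (default 20).
#' @return integer vector of block indices in `1..n_blocks`.
#' @export
make_blocks <- function(vt, contig_lengths = NULL, n_blocks = 20) {
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(vt$pos, vt$chrom, max)
  }
  offs <- cumsum(c(0, as.numeric(contig_lengths)))
  names(offs) <- c(names(contig_lengths), "_end")
  gpos <- offs[vt$chrom] + (vt$pos - 1)
  total <- sum(as.numeric(contig_lengths))
  pmin(n_blocks, 1L + as.integer(floor(gpos / total * n_blocks)))
}

busing_jackknife <- function(est, loo, weights) {
  n <- length(loo)
  W <- sum(weights)
  h <- W / weights
  theta_j <- n * est - sum((1 - 1 / h) * loo)
  var_j <- sum((h * est - (h - 1) * loo - theta_j)^2 / (h - 1)) / n
  se <- sqrt(max(var_j, 0))
  degenerate <- se == 0
  z <- if (se > 0) est / se else if (est == 0) 0 else Inf * sign(est)
  p <- if (se > 0) 2 * pnorm(-abs(z)) else if (est == 0) 1 else 0
  structure(list(estimate = est, se = se, z = z, p = p, n_blocks = n,
                 degenerate = degenerate), class = "block_jackknife")
}

#' Weighted delete-one-block jackknife
#'
#' Busing-style weighted jackknife for a weighted-mean statistic
#' `sum(w * v) / sum(w)` over genomic blocks (for ratio statistics such as
#' Patterson's D, pass per-block values with the per-block denominators as
#' weights, or use the internal ratio path used by the introgression
#' statistics). Returns the estimate, its jackknife SE, `Z = estimate/SE`
#' and a two-sided normal p-value. When all leave-one-out estimates agree
#' the SE is zero and the result carries a `degenerate` flag (p = 0 for a
#' nonzero estimate, p = 1 otherwise).
#'
#' @param values per-block statistic values.
#' @param weights positive per-block weights (e.g. informative sites).
#' @return list with `estimate`, `se`, `z`, `p`, `n_blocks`, `degenerate`.
#' @export
block_jackknife <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), length(values) >= 2,
            all(weights > 0))
  W <- sum(weights)
  est <- sum(weights * values) / W
  loo <- vapply(seq_along(values), function(j)
    sum(weights[-j] * values[-j]) / (W - weights[j]), 0)
  busing_jackknife(est, loo, weights)
}

# Jackknife for a ratio-of-sums statistic sum(num)/sum(den) with separate
# (site-count) weights; the workhorse behind D, f4, f4-ratio and f-hom.
jackknife_ratio <- function(num_blocks, den_blocks, weights) {
  keep <- weights > 0
  num_blocks <- num_blocks[keep]; den_blocks <- den_blocks[keep]
  weights <- weights[keep]
  if (length(weights) < 2 || sum(den_blocks) == 0) return(NULL)
  est <- sum(num_blocks) / sum(den_blocks)
  loo <- vapply(seq_along(weights), function(j) {
    den <- sum(den_blocks[-j])
    if (den == 0) return(NA_real_)
    sum(num_blocks[-j]) / den
  }, 0)
  if (anyNA(loo)) return(NULL)
  busing_jackknife(est, loo, weights)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; `NA` p-values
#' propagate as `NA` q-values.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Write a window table as BED5
#'
#' BED (0-based half-open) with the chosen statistic in the score column;
#' deterministic row order (as supplied).
#'
#' @param wt window table (needs `chrom`, `start`, `end`).
#' @param path output path.
#' @param score column name to place in the BED score field.
#' @export
write_bed <- function(wt, path, score = NULL) {
  sc <- if (is.null(score)) "." else wt[[score]]
  df <- data.frame(wt$chrom, wt$start, wt$end,
                   name = paste0("w", seq_len(nrow(wt))), score = sc)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read result tables as TSV
#'
#' Header-carrying TSV with deterministic row order; `read_result_tsv()` is
#' the exact inverse for data frames of atomic columns.
#' @param x data.frame.
#' @param path file path.
#' @export
write_result_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the
# package funnel through this so that no call touches the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
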