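#' Per-site ABBA/BABA weights
#'
#' Patterson site-pattern weights from polarized derived-allele frequencies
#' for a ((P1, P2), P3), outgroup configuration:
#' `abba = (1 - p1) p2 p3 (1 - pO)` and `baba = p1 (1 - p2) p3 (1 - pO)`.
#' Masked sites (any frequency `NA`) are skipped.
#'
#' @param freqs sites x populations derived-frequency matrix (from
#'   [derived_freqs()]).
#' @param trio named list or character vector with entries `P1`, `P2`, `P3`,
#'   `outgroup` giving the column names in `freqs`.
#' @return data.frame with columns `site` (row index in `freqs`), `abba`,
#'   `baba`. Errors if every site is masked.
#' @export
site_patterns <- function(freqs, trio) {
  p1 <- freqs[, trio[["P1"]]]; p2 <- freqs[, trio[["P2"]]]
  p3 <- freqs[, trio[["P3"]]]; pO <- freqs[, trio[["outgroup"]]]
  used <- which(complete.cases(cbind(p1, p2, p3, pO)))
  if (!length(used)) stop("all sites masked for this trio")
  abba <- (1 - p1[used]) * p2[used] * p3[used] * (1 - pO[used])
  baba <- p1[used] * (1 - p2[used]) * p3[used] * (1 - pO[used])
  data.frame(site = used, abba = abba, baba = baba)
}

#' Patterson's D with block-jackknife significance
#'
#' Genome-wide `D = sum(abba - baba) / sum(abba + baba)` with a weighted
#' delete-one-block jackknife (weights = informative sites per block), plus
#' an optional per-window D track (windows with fewer than `min_sites`
#' informative sites are `NA`).
#'
#' @inheritParams site_patterns
#' @param vt [variant_table()] aligned with `freqs` rows.
#' @param windows optional window table from [make_windows()].
#' @param blocks integer block index per site (e.g. [make_blocks()]), or a
#'   single integer number of equal-span blocks (default 20).
#' @param min_sites minimum informative sites per window (default 10).
#' @return list with `D`, `sum_abba`, `sum_baba`, `n_sites`, `jackknife`
#'   (see [block_jackknife()]) and, when `windows` is given, `windows` with
#'   a `D` column and `n_sites_used`.
#' @export
patterson_d <- function(freqs, trio, vt, windows = NULL, blocks = 20,
                        min_sites = 10) {
  sp <- site_patterns(freqs, trio)
  num <- sp$abba - sp$baba
  den <- sp$abba + sp$baba
  if (sum(den) == 0) {
    return(list(D = NA_real_, sum_abba = sum(sp$abba), sum_baba = sum(sp$baba),
                n_sites = nrow(sp), jackknife = NULL, undefined = TRUE))
  }
  if (length(blocks) == 1L) blocks <- make_blocks(vt, n_blocks = blocks)
  b <- blocks[sp$site]
  informative <- den > 0
  jk <- jackknife_ratio(
    num_blocks = tapply(num, b, sum),
    den_blocks = tapply(den, b, sum),
    weights = as.numeric(tapply(informative, b, sum)))
  out <- list(D = sum(num) / sum(den), sum_abba = sum(sp$abba),
              sum_baba = sum(sp$baba), n_sites = nrow(sp), jackknife = jk,
              undefined = FALSE)
  if (!is.null(windows)) {
    w <- window_of(vt$chrom[sp$site], vt$pos[sp$site] - 1L, windows)
    windows$D <- NA_real_
    windows$n_sites_used <- 0L
    for (wi in unique(w[!is.na(w)])) {
      sel <- which(w == wi & informative)
      windows$n_sites_used[wi] <- length(sel)
      if (length(sel) >= min_sites && sum(den[sel]) > 0)
        windows$D[wi] <- sum(num[sel]) / sum(den[sel])
    }
    out$windows <- windows
  }
  out
}

#' Window f_d statistic (dynamic-donor estimator)
#'
#' Martin et al.'s admixture-fraction estimator per window: the numerator is
#' the ABBA-BABA difference; the denominator replaces both P2 and P3 by
#' whichever of the two has the higher derived frequency at each site (the
#' maximal-donor configuration). Windows where D < 0 are reported `NA`
#' (outside the estimator's domain), as are windows with fewer than
#' `min_sites` informative sites or a zero denominator.
#'
#' @inheritParams patterson_d
#' @param windows window table (required; f_d is a window statistic).
#' @return `windows` with columns `fd`, `D`, `n_sites_used`.
#' @export
f_d <- function(freqs, trio, vt, windows, min_sites = 10) {
  sp <- site_patterns(freqs, trio)
  p1 <- freqs[sp$site, trio[["P1"]]]; p2 <- freqs[sp$site, trio[["P2"]]]
  p3 <- freqs[sp$site, trio[["P3"]]]; pO <- freqs[sp$site, trio[["outgroup"]]]
  pD <- pmax(p2, p3)
  num <- sp$abba - sp$baba
  den_d <- (1 - p1) * pD * pD * (1 - pO) - p1 * (1 - pD) * pD * (1 - pO)
  den_D <- sp$abba + sp$baba
  w <- window_of(vt$chrom[sp$site], vt$pos[sp$site] - 1L, windows)
  windows$fd <- NA_real_; windows$D <- NA_real_; windows$n_sites_used <- 0L
  for (wi in unique(w[!is.na(w)])) {
    sel <- which(w == wi)
    inf <- sel[den_D[sel] > 0]
    windows$n_sites_used[wi] <- length(inf)
    if (length(inf) < min_sites) next
    Dw <- sum(num[sel]) / sum(den_D[sel])
    windows$D[wi] <- Dw
    if (Dw < 0 || sum(den_d[sel]) == 0) next
    windows$fd[wi] <- sum(num[sel]) / sum(den_d[sel])
  }
  windows
}

#' f4 statistic
#'
#' `f4(A, B; C, D) = mean over sites of (pA - pB)(pC - pD)` with a
#' block-jackknife SE.
#'
#' @param freqs derived-frequency matrix.
#' @param A,B,C,D population column names.
#' @param vt variant table aligned with `freqs`.
#' @param blocks block indices or count (default 20).
#' @return list with `f4`, `n_sites`, `jackknife`.
#' @export
f4 <- function(freqs, A, B, C, D, vt, blocks = 20) {
  m <- cbind(freqs[, A], freqs[, B], freqs[, C], freqs[, D])
  used <- which(complete.cases(m))
  if (!length(used)) stop("all sites masked")
  v <- (m[used, 1] - m[used, 2]) * (m[used, 3] - m[used, 4])
  if (length(blocks) == 1L) blocks <- make_blocks(vt, n_blocks = blocks)
  b <- blocks[used]
  nb <- tapply(v, b, length)
  jk <- jackknife_ratio(num_blocks = tapply(v, b, sum),
                        den_blocks = as.numeric(nb),
                        weights = as.numeric(nb))
  list(f4 = mean(v), n_sites = length(used), jackknife = jk)
}

#' f4-ratio admixture proportion
#'
#' Patterson's admixture-proportion estimator
#' `alpha = f4(A, O; X, C) / f4(A, O; B, C)` for a focal population X
#' admixed between B (donor side) and C, with A an unadmixed reference and
#' O the outgroup. The configuration is explicit; no automatic subsetting.
#'
#' @param freqs derived-frequency matrix.
#' @param config named list/vector with entries `A`, `B`, `C`, `X`, `O`.
#' @param vt variant table.
#' @param blocks block indices or count.
#' @param tol denominator magnitude below which alpha is undefined.
#' @return list with `alpha`, `f4_num`, `f4_den`, `jackknife`, `undefined`.
#' @export
f4_ratio <- function(freqs, config, vt, blocks = 20, tol = 1e-12) {
  m <- cbind(freqs[, config[["A"]]], freqs[, config[["O"]]],
             freqs[, config[["X"]]], freqs[, config[["B"]]],
             freqs[, config[["C"]]])
  used <- which(complete.cases(m))
  if (!length(used)) stop("all sites masked")
  pa <- m[used, 1]; po <- m[used, 2]; px <- m[used, 3]
  pb <- m[used, 4]; pc <- m[used, 5]
  num <- (pa - po) * (px - pc)
  den <- (pa - po) * (pb - pc)
  if (abs(sum(den)) < tol)
    return(list(alpha = NA_real_, f4_num = sum(num) / length(used),
                f4_den = sum(den) / length(used), jackknife = NULL,
                undefined = TRUE))
  if (length(blocks) == 1L) blocks <- make_blocks(vt, n_blocks = blocks)
  b <- blocks[used]
  jk <- jackknife_ratio(num_blocks = tapply(num, b, sum),
                        den_blocks = tapply(den, b, sum),
                        weights = as.numeric(tapply(num, b, length)))
  list(alpha = sum(num) / sum(den), f4_num = sum(num) / length(used),
       f4_den = sum(den) / length(used), jackknife = jk, undefined = FALSE)
}

# f-hom admixture-fraction estimator for a trio (A, B; C, O):
# f = sum pC (1-pO) (pB - pA) / sum pC (1-pO) (pC - pA).
f_hom <- function(freqs, A, B, C, O, vt, blocks) {
  m <- cbind(freqs[, A], freqs[, B], freqs[, C], freqs[, O])
  used <- which(complete.cases(m))
  if (!length(used)) return(NULL)
  pa <- m[used, 1]; pb <- m[used, 2]; pc <- m[used, 3]; po <- m[used, 4]
  num <- pc * (1 - po) * (pb - pa)
  den <- pc * (1 - po) * (pc - pa)
  if (sum(den) == 0) return(NULL)
  b <- blocks[used]
  jk <- jackknife_ratio(num_blocks = tapply(num, b, sum),
                        den_blocks = tapply(den, b, sum),
                        weights = as.numeric(tapply(num, b, length)))
  list(f = sum(num) / sum(den), jackknife = jk)
}

#' Branch-specific excess allele sharing (f-branch)
#'
#' Malinsky's tree-aware summary: for every branch b of the rooted ingroup
#' tree and every candidate donor population C not descended from b,
#' `f_b(C) = median over A in descendants of b's sister of (min over B in
#' descendants of b of f-hom(A, B; C, O))`, with the block-jackknife
#' p-value of the pair realising the median-of-minima, and BH correction
#' across the matrix. Donors descended from b are `NA`; within the median
#' the degenerate case A = C is skipped. Negative estimates are floored at
#' zero (excess sharing is non-negative) and carry no significance.
#'
#' @param tree rooted binary `phylo` tree (or newick string/file) whose tips
#'   are population labels; may include the outgroup as a tip (it is
#'   removed before branch enumeration).
#' @param freqs derived-frequency matrix containing all tip populations and
#'   the outgroup.
#' @param outgroup outgroup population name.
#' @param vt variant table aligned with `freqs`.
#' @param blocks block indices or count (default 20).
#' @return list with matrices `fb`, `p`, `q` (rows = branches labelled by
#'   their descendant clade, columns = donor populations) and `pairs`
#'   (bookkeeping of the selected (A, B) pair per entry).
#' @export
f_branch <- function(tree, freqs, outgroup, vt, blocks = 20) {
  if (is.character(tree))
    tree <- if (file.exists(tree[1]) && length(tree) == 1L && !grepl("\\(", tree))
      ape::read.tree(tree) else ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (outgroup %in% tree$tip.label)
    tree <- ape::drop.tip(tree, outgroup)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree must be rooted and binary; resolve polytomies first")
  tips <- tree$tip.label
  if (length(blocks) == 1L) blocks <- make_blocks(vt, n_blocks = blocks)

  ntip <- length(tips)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc_tips <- function(node) {
    if (node <= ntip) return(tips[node])
    unlist(lapply(kids[[as.character(node)]], desc_tips))
  }

  branches <- tree$edge[, 2]  # every branch identified by its child node
  root <- ntip + 1L
  rows <- list()
  fb <- p <- matrix(NA_real_, length(branches), length(tips),
                    dimnames = list(rep("", length(branches)), tips))
  pairs <- vector("list", length(branches))
  for (i in seq_along(branches)) {
    b <- branches[i]
    parent <- tree$edge[tree$edge[, 2] == b, 1]
    sibs <- setdiff(kids[[as.character(parent)]], b)
    B_set <- desc_tips(b)
    A_set <- unlist(lapply(sibs, desc_tips))
    rownames(fb)[i] <- rownames(p)[i] <- paste(B_set, collapse = ",")
    pairs[[i]] <- list()
    for (C in setdiff(tips, B_set)) {
      A_use <- setdiff(A_set, C)
      if (!length(A_use)) next
      per_A <- lapply(A_use, function(A) {
        fits <- lapply(B_set, function(B) f_hom(freqs, A, B, C, outgroup, vt, blocks))
        ok <- !vapply(fits, is.null, TRUE)
        if (!any(ok)) return(NULL)
        fits <- fits[ok]; Bs <- B_set[ok]
        j <- which.min(vapply(fits, `[[`, 0, "f"))
        list(A = A, B = Bs[j], fit = fits[[j]])
      })
      per_A <- per_A[!vapply(per_A, is.null, TRUE)]
      if (!length(per_A)) next
      fs <- vapply(per_A, function(x) x$fit$f, 0)
      med <- sort(fs)[ceiling(length(fs) / 2)]  # lower median: a real pair
      sel <- per_A[[which(fs == med)[1]]]
      # excess sharing is non-negative by definition: negative estimates
      # (degenerate denominators, drift noise) are floored at 0 and carry
      # no significance
      if (sel$fit$f > 0) {
        fb[i, C] <- sel$fit$f
        p[i, C] <- sel$fit$jackknife$p
      } else {
        fb[i, C] <- 0
        p[i, C] <- NA_real_
      }
      pairs[[i]][[C]] <- c(A = sel$A, B = sel$B)
    }
  }
  keep <- rowSums(!is.na(fb)) > 0
  fb <- fb[keep, , drop = FALSE]; p <- p[keep, , drop = FALSE]
  q <- p; q[] <- bh_fdr(as.vector(p))
  list(fb = fb, p = p, q = q, pairs = pairs[keep])
}

#' Window divergence D_xy
#'
#' Mean pairwise divergence between two populations:
#' per variable site `d = p_x (1 - p_y) + p_y (1 - p_x)`, summed per window
#' and divided by the accessible sites in the window (if not provided, the
#' full window width in bp is used and recorded in the output metadata).
#'
#' @param freqs derived- (or alt-) frequency matrix.
#' @param pop_x,pop_y population column names.
#' @param vt variant table aligned with `freqs`.
#' @param windows window table.
#' @param accessible optional per-window accessible-site counts.
#' @return `windows` with `dxy`, `n_sites_used` and attribute
#'   `"denominator"` (`"accessible"` or `"window_bp"`).
#' @export
d_xy <- function(freqs, pop_x, pop_y, vt, windows, accessible = NULL) {
  px <- freqs[, pop_x]; py <- freqs[, pop_y]
  used <- which(!is.na(px) & !is.na(py))
  d <- px[used] * (1 - py[used]) + py[used] * (1 - px[used])
  w <- window_of(vt$chrom[used], vt$pos[used] - 1L, windows)
  denom <- if (is.null(accessible)) windows$end - windows$start else accessible
  windows$dxy <- NA_real_; windows$n_sites_used <- 0L
  sums <- tapply(d, w, sum)
  cnts <- tapply(d, w, length)
  wi <- as.integer(names(sums))
  windows$n_sites_used[wi] <- as.integer(cnts)
  ok <- denom[wi] > 0
  windows$dxy[wi[ok]] <- sums[ok] / denom[wi[ok]]
  windows$dxy[setdiff(seq_len(nrow(windows)), wi)][
    denom[setdiff(seq_len(nrow(windows)), wi)] > 0] <- 0
  attr(windows, "denominator") <- if (is.null(accessible)) "window_bp" else "accessible"
  windows
}

#' Diagnostic (species-specific) markers between two reference panels
#'
#' Sites where the alt-allele frequency difference between the two panels is
#' at least `min_delta` (default 1, i.e. fixed differences). The donor
#' allele at each marker is whichever allele is (near-)fixed in `popA`.
#'
#' @param gm dosage matrix.
#' @param pm population map.
#' @param popA donor reference panel label.
#' @param popB other reference panel label.
#' @param min_delta minimum |frequency difference| (default 1.0).
#' @param min_n minimum called alleles per panel.
#' @return data.frame with `site` (variant index) and `donor_allele`
#'   (`"ref"`/`"alt"`). Errors when no markers pass.
#' @export
diagnostic_markers <- function(gm, pm, popA, popB, min_delta = 1.0, min_n = 2) {
  panel_freq <- function(pops) {
    d <- gm[pop_samples(pm, pops, rownames(gm)), , drop = FALSE]
    n <- 2L * colSums(!is.na(d))
    f <- colSums(d, na.rm = TRUE) / n
    f[n < min_n] <- NA_real_
    f
  }
  delta <- panel_freq(popA) - panel_freq(popB)
  sel <- which(!is.na(delta) & abs(delta) >= min_delta - 1e-9)
  if (!length(sel))
    stop("no diagnostic markers at min_delta = ", min_delta,
         "; consider lowering min_delta")
  data.frame(site = sel,
             donor_allele = ifelse(delta[sel] > 0, "alt", "ref"),
             stringsAsFactors = FALSE)
}

#' Per-sample donor-ancestry profile from diagnostic markers
#'
#' Total donor ancestry per sample = sum of donor-allele dosages over
#' genotyped markers / (2 x markers genotyped); per-window donor fractions;
#' inferred fragments = maximal runs of windows with donor fraction >= 0.5
#' (a heterozygous donor tract contributes 0.5).
#'
#' @param gm dosage matrix.
#' @param vt variant table.
#' @param markers marker table from [diagnostic_markers()].
#' @param windows optional window table for the per-window track.
#' @param samples samples to profile (default all rows of `gm`).
#' @return list with `total` (named per-sample proportions), `by_window`
#'   (samples x windows matrix, when windows given) and `fragments`
#'   (data.frame of called donor fragments).
#' @export
ancestry_profile <- function(gm, vt, markers, windows = NULL,
                             samples = rownames(gm)) {
  d <- gm[samples, markers$site, drop = FALSE]
  flip <- markers$donor_allele == "ref"
  d[, flip] <- 2L - d[, flip]
  total <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  out <- list(total = total)
  if (!is.null(windows)) {
    w <- window_of(vt$chrom[markers$site], vt$pos[markers$site] - 1L, windows)
    bw <- matrix(NA_real_, length(samples), nrow(windows),
                 dimnames = list(samples, NULL))
    for (wi in unique(w[!is.na(w)])) {
      sub <- d[, w == wi, drop = FALSE]
      bw[, wi] <- rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
    }
    frags <- list()
    for (s in samples) {
      for (ch in unique(windows$chrom)) {
        wi <- which(windows$chrom == ch)
        hit <- !is.na(bw[s, wi]) & bw[s, wi] >= 0.5
        r <- rle(hit)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        for (k in which(r$values)) {
          frags[[length(frags) + 1L]] <- data.frame(
            sample = s, chrom = ch,
            start = windows$start[wi[starts[k]]],
            end = windows$end[wi[ends[k]]], stringsAsFactors = FALSE)
        }
      }
    }
    out$by_window <- bw
    out$fragments <- if (length(frags)) do.call(rbind, frags)
                     else data.frame(sample = character(0), chrom = character(0),
                                     start = numeric(0), end = numeric(0))
  }
  out
}
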