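#' Per-bulk SNP index and delta SNP-index
#'
#' SNP index = alt reads / (ref + alt) per bulk; delta = high - low.
#' Markers with depth below `min_depth` in either bulk are masked.
#'
#' @param counts data.frame `chrom pos ref_high alt_high ref_low alt_low`.
#' @param min_depth minimum per-bulk depth (default 10).
#' @return `counts` with `snp_index_high`, `snp_index_low`,
#'   `delta_snp_index`, `masked`.
#' @export
snp_index <- function(counts, min_depth = 10) {
  dh <- counts$ref_high + counts$alt_high
  dl <- counts$ref_low + counts$alt_low
  masked <- dh < min_depth | dl < min_depth
  hi <- ifelse(dh > 0, counts$alt_high / dh, NA_real_)
  lo <- ifelse(dl > 0, counts$alt_low / dl, NA_real_)
  hi[masked] <- NA_real_; lo[masked] <- NA_real_
  counts$snp_index_high <- hi
  counts$snp_index_low <- lo
  counts$delta_snp_index <- hi - lo
  counts$masked <- masked
  counts
}

#' Per-marker G statistic
#'
#' Likelihood-ratio statistic of the 2x2 bulk x allele read-count table:
#' `G = 2 * sum(n * log(n / e))` with expected counts from the margins and
#' the convention `0 * log(0) = 0`. G = 0 iff the table is proportional;
#' masked markers propagate `NA`.
#'
#' @inheritParams snp_index
#' @return numeric G per marker.
#' @export
g_statistic <- function(counts, min_depth = 10) {
  n11 <- counts$ref_high; n12 <- counts$alt_high
  n21 <- counts$ref_low;  n22 <- counts$alt_low
  N <- n11 + n12 + n21 + n22
  masked <- (n11 + n12) < min_depth | (n21 + n22) < min_depth
  xlogx <- function(n, e) ifelse(n == 0, 0, n * log(n / e))
  G <- 2 * (xlogx(n11, (n11 + n12) * (n11 + n21) / N) +
            xlogx(n12, (n11 + n12) * (n12 + n22) / N) +
            xlogx(n21, (n21 + n22) * (n11 + n21) / N) +
            xlogx(n22, (n21 + n22) * (n12 + n22) / N))
  G[masked] <- NA_real_
  pmax(G, 0)
}

#' Tricube-smoothed G' values
#'
#' Local weighted mean of G over markers within `half_window_bp` of the
#' focal marker (same chromosome), with tricube weights
#' `w = (1 - (d / W)^3)^3` renormalised within the window. An isolated
#' marker keeps its own G; G' is a convex combination of in-window G.
#'
#' @param G per-marker G values (NA allowed, skipped).
#' @param chrom,pos marker coordinates (sorted within chromosome).
#' @param half_window_bp tricube half-window W in bp (default 1 Mb).
#' @return numeric G' per marker.
#' @export
g_prime <- function(G, chrom, pos, half_window_bp = 1e6) {
  stopifnot(half_window_bp > 0, length(G) == length(pos))
  gp <- rep(NA_real_, length(G))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- idx[order(pos[idx])]
    p <- pos[o]; g <- G[o]
    lo <- findInterval(p - half_window_bp, p) + 1L  # first marker with d < W... inclusive below
    hi <- findInterval(p + half_window_bp, p)
    for (k in seq_along(o)) {
      if (is.na(g[k])) next
      j <- lo[k]:hi[k]
      j <- j[!is.na(g[j])]
      d <- abs(p[j] - p[k])
      keep <- d <= half_window_bp
      j <- j[keep]; d <- d[keep]
      w <- (1 - (d / half_window_bp)^3)^3
      if (sum(w) == 0) { gp[o[k]] <- g[k]; next }
      gp[o[k]] <- sum(w * g[j]) / sum(w)
    }
  }
  gp
}

#' p- and q-values for G' from a robust log-normal null
#'
#' Fits a log-normal null to the bulk of the G' distribution using robust
#' location/scale on the log scale (median and MAD by default; Hampel's
#' outlier-trimmed moments behind `method = "hampel"`), then reports
#' upper-tail p-values and BH q-values.
#'
#' @param gprime G' values (NA skipped).
#' @param method `"median_mad"` (default) or `"hampel"`.
#' @return data.frame with `p`, `q` (NA where G' was NA). Errors when G' is
#'   constant.
#' @export
gprime_pvalues <- function(gprime, method = c("median_mad", "hampel")) {
  method <- match.arg(method)
  ok <- !is.na(gprime) & gprime > 0
  lg <- log(gprime[ok])
  if (length(unique(lg)) < 2) stop("degenerate (constant) G' distribution")
  if (method == "median_mad") {
    mu <- median(lg); sig <- mad(lg)
  } else {
    # Hampel: trim points beyond median +- 5.2 * MAD, then use moments
    m0 <- median(lg); s0 <- mad(lg)
    core <- lg[abs(lg - m0) <= 5.2 * s0]
    mu <- mean(core); sig <- stats::sd(core)
  }
  if (sig == 0) stop("degenerate (constant) G' distribution")
  p <- rep(NA_real_, length(gprime))
  p[ok] <- plnorm(gprime[ok], meanlog = mu, sdlog = sig, lower.tail = FALSE)
  data.frame(p = p, q = bh_fdr(p))
}

#' Call significant QTL intervals from a scan
#'
#' Maximal runs of at least `min_markers` consecutive markers with
#' q < `q_threshold`, merged across gaps smaller than `gap_bp`.
#'
#' @param scan data.frame with `chrom`, `pos`, `q` (marker order within
#'   chromosome is established internally).
#' @param q_threshold q cutoff (default 0.01).
#' @param min_markers minimum markers per run (default 3).
#' @param gap_bp merge runs separated by less than this (default 500 kb).
#' @return data.frame of intervals `chrom`, `start`, `end`, `n_markers`
#'   (positions of first/last significant marker).
#' @export
significant_regions <- function(scan, q_threshold = 0.01, min_markers = 3,
                                gap_bp = 5e5) {
  out <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, ]
    s <- s[order(s$pos), ]
    sig <- !is.na(s$q) & s$q < q_threshold
    if (!any(sig)) next
    pos <- s$pos[sig]
    runs <- cumsum(c(1, diff(pos) >= gap_bp))
    for (r in unique(runs)) {
      p <- pos[runs == r]
      if (length(p) < min_markers) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(p), end = max(p), n_markers = length(p),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_markers = integer(0)))
  do.call(rbind, out)
}

#' Full BSA scan
#'
#' Convenience wrapper: SNP indices, G, tricube G', log-normal p/q and
#' significant intervals in one call.
#'
#' @inheritParams snp_index
#' @param half_window_bp tricube half-window (default 1 Mb).
#' @param q_threshold significance cutoff on q (default 0.01).
#' @param ... passed to [significant_regions()].
#' @return list with `markers` (per-marker table) and `regions`.
#' @export
bsa_scan <- function(counts, min_depth = 10, half_window_bp = 1e6,
                     q_threshold = 0.01, ...) {
  m <- snp_index(counts, min_depth)
  m$G <- g_statistic(counts, min_depth)
  m$Gprime <- g_prime(m$G, m$chrom, m$pos, half_window_bp)
  pq <- gprime_pvalues(m$Gprime)
  m$p <- pq$p; m$q <- pq$q
  list(markers = m,
       regions = significant_regions(m, q_threshold = q_threshold, ...))
}

#' F1 segregation chi-squared test
#'
#' Pearson chi-squared (1 df, no continuity correction) of two phenotype
#' class counts against an expected ratio.
#'
#' @param n1,n2 observed class counts.
#' @param ratio expected ratio (default `c(1, 1)`).
#' @return list with `n_class1`, `n_class2`, `expected_ratio`, `chi2`, `p`.
#' @export
segregation_test <- function(n1, n2, ratio = c(1, 1)) {
  n <- n1 + n2
  if (n <= 0) stop("zero total count")
  e <- n * ratio / sum(ratio)
  chi2 <- sum((c(n1, n2) - e)^2 / e)
  list(n_class1 = n1, n_class2 = n2, expected_ratio = ratio, chi2 = chi2,
       p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
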