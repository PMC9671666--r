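# Independent brute-force oracles, kept deliberately naive (per-element
# loops, textbook formulas) and separate from the package implementations.

# step-up FDR from the definition: q_(i) = min_{j >= i} p_(j) * n / j
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cands <- sapply(i:n, function(j) p[o[j]] * n / j)
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# classic delete-one jackknife SE from leave-one-out estimates
bf_jackknife_se <- function(loo) {
  n <- length(loo)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

# Spearman rho from the definition (average ranks, Pearson on ranks)
bf_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# per-site ABBA/BABA and D, plain loop
bf_d_stat <- function(p1, p2, p3, po) {
  num <- 0; den <- 0
  for (i in seq_along(p1)) {
    abba <- (1 - p1[i]) * p2[i] * p3[i] * (1 - po[i])
    baba <- p1[i] * (1 - p2[i]) * p3[i] * (1 - po[i])
    num <- num + (abba - baba)
    den <- den + (abba + baba)
  }
  num / den
}

bf_f4 <- function(pa, pb, pc, pd) {
  tot <- 0
  for (i in seq_along(pa)) tot <- tot + (pa[i] - pb[i]) * (pc[i] - pd[i])
  tot / length(pa)
}

bf_fd_window <- function(p1, p2, p3, po) {
  num <- 0; dend <- 0
  for (i in seq_along(p1)) {
    num <- num + (1 - p1[i]) * p2[i] * p3[i] * (1 - po[i]) -
      p1[i] * (1 - p2[i]) * p3[i] * (1 - po[i])
    pd <- max(p2[i], p3[i])
    dend <- dend + (1 - p1[i]) * pd * pd * (1 - po[i]) -
      p1[i] * (1 - pd) * pd * (1 - po[i])
  }
  num / dend
}

bf_dxy <- function(px, py, n_accessible) {
  tot <- 0
  for (i in seq_along(px)) tot <- tot + px[i] * (1 - py[i]) + py[i] * (1 - px[i])
  tot / n_accessible
}

bf_g_stat <- function(rh, ah, rl, al) {
  n <- c(rh, ah, rl, al)
  N <- sum(n)
  e <- c((rh + ah) * (rh + rl), (rh + ah) * (ah + al),
         (rl + al) * (rh + rl), (rl + al) * (ah + al)) / N
  g <- 0
  for (k in 1:4) if (n[k] > 0) g <- g + n[k] * log(n[k] / e[k])
  2 * g
}

bf_gprime <- function(G, pos, W) {
  out <- numeric(length(G))
  for (k in seq_along(G)) {
    num <- 0; den <- 0
    for (j in seq_along(G)) {
      d <- abs(pos[j] - pos[k])
      if (d <= W) {
        w <- (1 - (d / W)^3)^3
        num <- num + w * G[j]
        den <- den + w
      }
    }
    out[k] <- if (den > 0) num / den else G[k]
  }
  out
}

# Hudson Fst, ratio-of-averages
bf_hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

# tiny polarized frequency fixture: explicit matrix + matching variant table
freq_fixture <- function(n_sites, seed, n_pops = 4,
                         pops = c("P1", "P2", "P3", "O")) {
  set.seed(seed)
  f <- matrix(runif(n_sites * n_pops), n_sites, n_pops,
              dimnames = list(NULL, pops))
  vt <- variant_table(chrom = "chr1", pos = sort(sample.int(1e6, n_sites)),
                      ref = "A", alt = "T")
  list(freqs = f, vt = vt)
}
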