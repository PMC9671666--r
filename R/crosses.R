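#' Expected F1 homozygous-deleterious ratio for one parent pair
#'
#' Primary hypothetical-cross metric: under Mendelian gamete sampling, a
#' locus where the parents carry derived dosages `d_i`, `d_j` yields a
#' homozygous-derived F1 with probability `(d_i / 2)(d_j / 2)`; the metric
#' is the mean of that probability over all usable deleterious loci
#' (loci missing in either parent are excluded pairwise).
#'
#' @param dosage_i,dosage_j parental dosage vectors over the full variant
#'   set.
#' @param dset [classify_deleterious()] set (its `all` indices are used).
#' @return list with `r` (in \[0, 1\]) and `n_loci`; when no loci are
#'   usable, `r` is `NA` and `undefined` is `TRUE`.
#' @export
expected_f1_hom_ratio <- function(dosage_i, dosage_j, dset) {
  idx <- dset$all
  di <- dosage_i[idx]; dj <- dosage_j[idx]
  ok <- !is.na(di) & !is.na(dj)
  if (!any(ok)) return(list(r = NA_real_, n_loci = 0L, undefined = TRUE))
  r <- mean((di[ok] / 2) * (dj[ok] / 2))
  list(r = r, n_loci = sum(ok), undefined = FALSE)
}

#' Shared-carrier (Jaccard) ratio for one parent pair
#'
#' Alternative reading of "overlapping deleterious mutations": the Jaccard
#' overlap of the parental carrier sets (loci with dosage >= 1) over
#' deleterious loci.
#'
#' @inheritParams expected_f1_hom_ratio
#' @return list with `r`, `n_loci`, `undefined`.
#' @export
shared_carrier_ratio <- function(dosage_i, dosage_j, dset) {
  idx <- dset$all
  di <- dosage_i[idx]; dj <- dosage_j[idx]
  ok <- !is.na(di) & !is.na(dj)
  if (!any(ok)) return(list(r = NA_real_, n_loci = 0L, undefined = TRUE))
  ci <- di[ok] >= 1L; cj <- dj[ok] >= 1L
  un <- sum(ci | cj)
  r <- if (un == 0) 0 else sum(ci & cj) / un
  list(r = r, n_loci = sum(ok), undefined = FALSE)
}

#' Hypothetical-cross cohorts: within- and between-group pair enumeration
#'
#' Down-samples each group to a common size (without replacement, seeded),
#' enumerates all unordered pairs within group A, within group B, and
#' between groups (no self-crosses), and evaluates the chosen overlap
#' metric for each pair.
#'
#' @param gm dosage matrix.
#' @param dset deleterious set.
#' @param pm population map.
#' @param groupA,groupB population label vectors defining the two groups.
#' @param downsample_n common group size after down-sampling (must not
#'   exceed either group).
#' @param metric `"expected_hom"` (default) or `"shared_carrier"`.
#' @param seed integer seed for the down-sampling draw.
#' @return data.frame, one row per pair: `design` (`within_A`, `within_B`,
#'   `between`), `parent_i`, `parent_j`, `r`.
#' @export
cross_cohort <- function(gm, dset, pm, groupA, groupB, downsample_n,
                         metric = c("expected_hom", "shared_carrier"),
                         seed = 1) {
  metric <- match.arg(metric)
  fn <- switch(metric, expected_hom = expected_f1_hom_ratio,
               shared_carrier = shared_carrier_ratio)
  sa <- pop_samples(pm, groupA, rownames(gm))
  sb <- pop_samples(pm, groupB, rownames(gm))
  if (downsample_n > length(sa) || downsample_n > length(sb))
    stop("downsample_n exceeds a group size")
  picked <- with_seed(seed, list(a = sample(sa, downsample_n),
                                 b = sample(sb, downsample_n)))
  pairs_of <- function(ss) {
    if (length(ss) < 2) return(NULL)
    cb <- utils::combn(ss, 2)
    data.frame(parent_i = cb[1, ], parent_j = cb[2, ], stringsAsFactors = FALSE)
  }
  designs <- list(
    within_A = pairs_of(picked$a),
    within_B = pairs_of(picked$b),
    between = expand.grid(parent_i = picked$a, parent_j = picked$b,
                          stringsAsFactors = FALSE))
  out <- lapply(names(designs), function(dn) {
    df <- designs[[dn]]
    if (is.null(df)) return(NULL)
    df$design <- dn
    df$r <- vapply(seq_len(nrow(df)), function(k)
      fn(gm[df$parent_i[k], ], gm[df$parent_j[k], ], dset)$r, 0)
    df[, c("design", "parent_i", "parent_j", "r")]
  })
  do.call(rbind, out)
}

#' Between- versus within-group percent change in overlap ratio
#'
#' `100 * (mean_within - mean_between) / mean_within`, where the within
#' mean pools both within-group designs.
#'
#' @param results [cross_cohort()] output.
#' @return list with `percent_change`, `mean_within`, `mean_between` and
#'   per-design means.
#' @export
compare_within_between <- function(results) {
  mw <- mean(results$r[results$design %in% c("within_A", "within_B")], na.rm = TRUE)
  mb <- mean(results$r[results$design == "between"], na.rm = TRUE)
  list(percent_change = 100 * (mw - mb) / mw, mean_within = mw,
       mean_between = mb,
       by_design = tapply(results$r, results$design, mean, na.rm = TRUE))
}

#' Monte-Carlo check of the expected F1 homozygous ratio
#'
#' Seeded gamete-sampling simulation of F1s from one parent pair; converges
#' to [expected_f1_hom_ratio()] and is kept for validation only.
#'
#' @inheritParams expected_f1_hom_ratio
#' @param n_draws number of simulated F1 genomes.
#' @param seed integer seed.
#' @return mean simulated fraction of deleterious loci homozygous-derived.
#' @export
mc_f1_hom_ratio <- function(dosage_i, dosage_j, dset, n_draws = 10000,
                            seed = 1) {
  idx <- dset$all
  di <- dosage_i[idx]; dj <- dosage_j[idx]
  ok <- !is.na(di) & !is.na(dj)
  di <- di[ok]; dj <- dj[ok]
  with_seed(seed, {
    n <- length(di)
    mean(vapply(seq_len(n_draws), function(k) {
      gi <- rbinom(n, 1L, di / 2)
      gj <- rbinom(n, 1L, dj / 2)
      mean(gi + gj == 2L)
    }, 0))
  })
}
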