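#' Call a promoter-insertion genotype from read support
#'
#' Band rules on the insertion-supporting read fraction
#' `ins / (ins + ref)`: below `absent_max` -> absent; inside `het_range` ->
#' heterozygous; above `hom_min` -> homozygous; depth below `min_depth` or
#' a fraction falling between bands -> no_call.
#'
#' @param ins_reads,ref_reads non-negative read counts (vectorised).
#' @param min_depth minimum depth for a call (default 10).
#' @param absent_max upper fraction bound for absent (default 0.05).
#' @param het_range heterozygous fraction band (default `c(0.2, 0.8)`).
#' @param hom_min lower fraction bound for homozygous (default 0.95).
#' @return data.frame with `call` (`absent`/`het`/`hom`/`no_call`),
#'   `insertion_fraction`, `depth`.
#' @export
call_insertion_genotype <- function(ins_reads, ref_reads, min_depth = 10,
                                    absent_max = 0.05, het_range = c(0.2, 0.8),
                                    hom_min = 0.95) {
  if (any(ins_reads < 0 | ref_reads < 0)) stop("negative read counts")
  stopifnot(absent_max < het_range[1], het_range[2] < hom_min)
  depth <- ins_reads + ref_reads
  frac <- ifelse(depth > 0, ins_reads / depth, NA_real_)
  call <- rep("no_call", length(depth))
  call[!is.na(frac) & frac <= absent_max] <- "absent"
  call[!is.na(frac) & frac >= het_range[1] & frac <= het_range[2]] <- "het"
  call[!is.na(frac) & frac >= hom_min] <- "hom"
  call[depth < min_depth] <- "no_call"
  data.frame(call = call, insertion_fraction = frac, depth = depth,
             stringsAsFactors = FALSE)
}

#' Cohort zygosity summary by phenotype class
#'
#' Counts and percentages of absent/het/hom insertion calls within each
#' phenotype class (apomictic vs sexual), flagging apomictic accessions
#' with no insertion (discordant with the insertion-apomixis association).
#'
#' @param genotypes data.frame with `sample` and `call` columns.
#' @param phenotypes named character vector (`"apomictic"`/`"sexual"`) per
#'   sample.
#' @return list with `summary` (class x call counts and percentages over
#'   called genotypes) and `discordant` (apomictic samples called absent).
#'   Classes with no called genotypes are flagged undefined.
#' @export
cohort_zygosity_summary <- function(genotypes, phenotypes) {
  genotypes$phenotype <- phenotypes[genotypes$sample]
  called <- genotypes[genotypes$call != "no_call", ]
  res <- lapply(unique(genotypes$phenotype), function(ph) {
    sub <- called[called$phenotype == ph, ]
    n <- nrow(sub)
    counts <- table(factor(sub$call, levels = c("absent", "het", "hom")))
    data.frame(phenotype = ph, call = names(counts),
               n = as.integer(counts),
               percent = if (n > 0) 100 * as.integer(counts) / n else NA_real_,
               undefined = n == 0, stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, res),
       discordant = called$sample[called$phenotype == "apomictic" &
                                    called$call == "absent"])
}

hamming <- function(a, b) sum(a != b)

#' Decompose a promoter insertion into MITE units with TSD overlaps
#'
#' Detects the internal repeat structure of an insertion sequence: unit
#' boundaries are positions where the leading bases of the sequence recur
#' (k-mer anchor match, small mismatch tolerance), such that consecutive
#' units share exactly a `tsd_len`-bp direct repeat (the overlapping target
#' site duplication). The decomposition satisfies the length identity
#' `sum(unit lengths) - (n_units - 1) * tsd_len == nchar(seq)` by
#' construction and is verified; unit pairwise identity is checked by
#' alignment. Unresolvable sequences return a single unit of class
#' `"other"`.
#'
#' @param seq insertion sequence (character scalar, ACGT).
#' @param min_unit minimum unit length in bp (default 100).
#' @param min_identity minimum pairwise unit identity (default 0.8).
#' @param tsd_len target-site-duplication length (default 5).
#' @return list of class `mite_decomposition`: `units` (data.frame `start`,
#'   `end`, `length`, 1-based inclusive), `n_units`, `tsd_len`,
#'   `reconstructed_total`, `haplotype_class`.
#' @export
decompose_insertion <- function(seq, min_unit = 100, min_identity = 0.8,
                                tsd_len = 5) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < min_unit) stop("sequence shorter than min_unit")
  anchor_len <- min(12L, min_unit)
  anchor <- s[seq_len(anchor_len)]
  cand <- which(vapply(seq_len(n - anchor_len + 1L), function(p)
    hamming(s[p:(p + anchor_len - 1L)], anchor) <= 2L, TRUE))
  # greedy left-to-right boundary acceptance with minimum spacing
  bounds <- 1L
  for (p in cand[cand > 1L]) {
    if (p - bounds[length(bounds)] >= min_unit - tsd_len &&
        n - p + 1L >= min_unit) bounds <- c(bounds, p)
  }
  single <- function() {
    structure(list(units = data.frame(start = 1L, end = n, length = n),
                   n_units = 1L, tsd_len = tsd_len, reconstructed_total = n,
                   haplotype_class = "other"), class = "mite_decomposition")
  }
  if (length(bounds) < 2L) return(single())
  starts <- bounds
  ends <- c(starts[-1L] + tsd_len - 1L, n)
  units <- data.frame(start = starts, end = ends, length = ends - starts + 1L)
  # TSD check: every unit begins with (a near-copy of) the same tsd_len bases
  tsd_ok <- all(vapply(starts, function(p)
    hamming(s[p:(p + tsd_len - 1L)], s[1:tsd_len]) <= 1L, TRUE))
  total <- sum(units$length) - (nrow(units) - 1L) * tsd_len
  if (!tsd_ok || total != n || any(units$length < min_unit)) return(single())
  # pairwise unit identity via global alignment
  useq <- vapply(seq_len(nrow(units)), function(k)
    paste(s[units$start[k]:units$end[k]], collapse = ""), "")
  for (a in seq_len(length(useq) - 1L)) for (b in (a + 1L):length(useq)) {
    al <- Biostrings::pairwiseAlignment(useq[a], useq[b])
    if (Biostrings::pid(al) / 100 < min_identity) return(single())
  }
  dec <- structure(list(units = units, n_units = nrow(units),
                        tsd_len = tsd_len, reconstructed_total = total,
                        haplotype_class = "other"),
                   class = "mite_decomposition")
  dec$haplotype_class <- classify_haplotype(dec)
  dec
}

#' Classify a MITE decomposition into known promoter haplotypes
#'
#' Three units all within `length_tol` of 202 bp -> `"fortunella_3x202"`
#' (the 596-bp haplotype: 3 x 202 - 2 x 5); two units within tolerance of
#' 202 and 227 bp -> `"citrus_202_227"` (the 424-bp haplotype:
#' 202 + 227 - 5); otherwise `"other"` (or `"none"` for an empty
#' decomposition).
#'
#' @param decomposition [decompose_insertion()] result (or a list with a
#'   `units` data.frame).
#' @param length_tol unit length tolerance in bp (default 5).
#' @return character haplotype class.
#' @export
classify_haplotype <- function(decomposition, length_tol = 5) {
  lens <- decomposition$units$length
  if (!length(lens)) return("none")
  if (length(lens) == 3L && all(abs(lens - 202) <= length_tol))
    return("fortunella_3x202")
  if (length(lens) == 2L) {
    ok <- (abs(lens[1] - 202) <= length_tol && abs(lens[2] - 227) <= length_tol) ||
          (abs(lens[1] - 227) <= length_tol && abs(lens[2] - 202) <= length_tol)
    if (ok) return("citrus_202_227")
  }
  "other"
}

#' Construct a synthetic MITE insertion haplotype
#'
#' Builds an insertion sequence from unit lengths, chaining units so that
#' consecutive units share a `tsd_len`-bp overlap (each unit begins and
#' ends with the same TSD sequence). Units beyond the first reuse the first
#' unit's sequence, lengthened or shortened internally, so decomposition's
#' identity checks hold. Used by tests and the worked examples; real
#' insertion sequences come from FASTA input.
#'
#' @param unit_lengths e.g. `c(202, 202, 202)` or `c(202, 227)`.
#' @param tsd_len TSD length (default 5).
#' @param seed integer seed for the random unit body.
#' @return character sequence of length
#'   `sum(unit_lengths) - (n - 1) * tsd_len`.
#' @export
synth_mite_haplotype <- function(unit_lengths, tsd_len = 5, seed = 1) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    tsd <- sample(bases, tsd_len, replace = TRUE)
    base_len <- unit_lengths[1]
    body <- sample(bases, base_len - 2 * tsd_len, replace = TRUE)
    unit1 <- c(tsd, body, tsd)  # starts and ends with the TSD
    units <- lapply(unit_lengths, function(L) {
      if (L == base_len) return(unit1)
      if (L > base_len) {   # internal expansion keeps both TSD ends
        ins <- sample(bases, L - base_len, replace = TRUE)
        at <- floor(base_len / 2)
        c(unit1[1:at], ins, unit1[(at + 1):base_len])
      } else {
        at <- floor(base_len / 2)
        c(unit1[1:at], unit1[(at + 1 + (base_len - L)):base_len])
      }
    })
    out <- units[[1]]
    for (k in seq_along(units)[-1])
      out <- c(out, units[[k]][(tsd_len + 1):length(units[[k]])])
    paste(out, collapse = "")
  })
}
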