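#' Forward-simulation configuration
#'
#' Parameterises the Wright-Fisher simulator of deleterious-load dynamics.
#' `U` is the per-diploid-genome per-generation deleterious mutation rate
#' (so the per-locus per-haplotype rate is `U / (2 L)`); `h` selects the
#' selection model (0 recessive, 0.5 additive); `sigma` is the residual-sex
#' fraction of the facultatively apomictic mode. The demographic schedule
#' mirrors the reproductive-mode-transition scenario: a sexual burn-in of
#' `burn_in_multiplier * N` generations, a split into pO (sexual) and pI
#' (apomictic), a single introgression pulse pO -> pI moving a fraction
#' `pulse_f` of pI's ancestry, an apomictic phase, then a split of pI into
#' pS (switching to sexual at the split) and pA (remaining apomictic).
#'
#' @param N population size per deme.
#' @param L number of modelled loci.
#' @param U per-diploid-genome deleterious mutation rate per generation.
#' @param s fixed selection coefficient (ignored when `dfe` is gamma).
#' @param h dominance coefficient in \[0, 1\].
#' @param dfe `list(kind = "fixed")` or `list(kind = "gamma", shape = ,
#'   mean = )`.
#' @param sigma residual-sex fraction for the apomictic mode (default 0.05).
#' @param q0 initial derived-allele frequency (standing variation).
#' @param burn_in_multiplier burn-in length in units of N (default 10).
#' @param pulse_f introgression pulse fraction (default 0.10).
#' @param t_apomictic generations between the two splits.
#' @param t_post generations after the pS/pA split.
#' @param max_nl refuse configurations with `N * L` above this cap.
#' @return list of class `forward_config`.
#' @export
forward_config <- function(N = 1000, L = 5000, U = 0.2, s = 0.05, h = 0,
                           dfe = list(kind = "fixed"), sigma = 0.05, q0 = 0,
                           burn_in_multiplier = 10, pulse_f = 0.1,
                           t_apomictic = 500, t_post = 500, max_nl = 5e8) {
  stopifnot(s >= 0, s <= 1, h >= 0, h <= 1, sigma >= 0, sigma <= 1,
            pulse_f >= 0, pulse_f <= 1)
  if (as.numeric(N) * L > max_nl)
    stop("N * L = ", format(N * L, scientific = TRUE), " exceeds the cap (",
         format(max_nl, scientific = TRUE),
         "); reduce N or L, or raise max_nl explicitly")
  structure(as.list(environment()), class = "forward_config")
}

new_sim <- function(cfg, seed) {
  gamma_dfe <- identical(cfg$dfe$kind, "gamma")
  .fwd_new(as.integer(cfg$L), cfg$U / (2 * cfg$L), cfg$h, cfg$s, gamma_dfe,
           if (gamma_dfe) cfg$dfe$shape else 1,
           if (gamma_dfe) cfg$dfe$mean else cfg$s,
           as.integer(seed))
}

#' Run the reproductive-mode-transition scenario
#'
#' Executes the full schedule of [forward_config()] and records, for every
#' population and generation: mean fitness (including the contribution of
#' fixed deleterious alleles), mean heterozygous and homozygous-deleterious
#' counts per individual, segregating deleterious sites and the minimum
#' load class. Identical `cfg` + `seed` give identical trajectories.
#'
#' @param cfg [forward_config()].
#' @param seed integer seed.
#' @return list with `trajectories` (named list of per-population matrices),
#'   `switch_generation` (index of the pS sexual switch within the pS/pA
#'   trajectories, i.e. 1) and `cfg`.
#' @export
run_forward <- function(cfg, seed) {
  stopifnot(inherits(cfg, "forward_config"))
  sim <- new_sim(cfg, seed)
  .fwd_add_pop(sim, "pAnc", as.integer(cfg$N), cfg$q0)
  burn <- .fwd_run(sim, "pAnc", as.integer(cfg$burn_in_multiplier * cfg$N),
                   "sexual", 1)
  .fwd_split(sim, "pAnc", "pO", "pI", as.integer(cfg$N), as.integer(cfg$N))
  .fwd_pulse(sim, "pO", "pI", cfg$pulse_f, "apomictic", cfg$sigma)
  tra_O1 <- .fwd_run(sim, "pO", as.integer(cfg$t_apomictic), "sexual", 1)
  tra_I <- .fwd_run(sim, "pI", as.integer(cfg$t_apomictic), "apomictic",
                    cfg$sigma)
  .fwd_split(sim, "pI", "pS", "pA", as.integer(cfg$N), as.integer(cfg$N))
  tra_S <- .fwd_run(sim, "pS", as.integer(cfg$t_post), "sexual", 1)
  tra_A <- .fwd_run(sim, "pA", as.integer(cfg$t_post), "apomictic", cfg$sigma)
  tra_O2 <- .fwd_run(sim, "pO", as.integer(cfg$t_post), "sexual", 1)
  list(trajectories = list(burn_in = burn, pO = rbind(tra_O1, tra_O2),
                           pI = tra_I, pS = tra_S, pA = tra_A),
       switch_generation = 1L, cfg = cfg)
}

#' Evolve a single population (building block)
#'
#' Low-level single-deme runner used by the validation checks (drift decay,
#' mutation-selection balance, Muller's ratchet) and available for custom
#' schedules.
#'
#' @param cfg [forward_config()] (only N, L, U, s, h, dfe, q0 are used).
#' @param gens generations to run.
#' @param mode `"sexual"` or `"apomictic"`.
#' @param sigma residual-sex fraction when apomictic.
#' @param seed integer seed.
#' @param purge_every fold fixed loci into the permanent fitness term every
#'   this many generations (0 disables; disable when tracking cumulative
#'   neutral load).
#' @return list with `trajectory` (matrix) and `freqs` (final per-locus
#'   derived-allele frequencies).
#' @export
run_single_pop <- function(cfg, gens, mode = c("sexual", "apomictic"),
                           sigma = cfg$sigma, seed, purge_every = 100) {
  mode <- match.arg(mode)
  sim <- new_sim(cfg, seed)
  .fwd_add_pop(sim, "p", as.integer(cfg$N), cfg$q0)
  traj <- .fwd_run(sim, "p", as.integer(gens), mode, sigma,
                   as.integer(purge_every))
  list(trajectory = traj, freqs = .fwd_freqs(sim, "p"))
}

#' Multiplicative fitness of a genotype
#'
#' `w = prod (1 - h s_l)^[het at l] * (1 - s_l)^[hom at l]`; the reference
#' implementation of the fitness model used inside the simulator, exposed
#' for direct checks.
#'
#' @param het_s selection coefficients of heterozygous loci.
#' @param hom_s selection coefficients of homozygous loci.
#' @param h dominance coefficient.
#' @return fitness in \[0, 1\] (1 for a mutation-free genotype).
#' @export
compute_fitness <- function(het_s, hom_s, h) {
  stopifnot(all(het_s >= 0 & het_s <= 1), all(hom_s >= 0 & hom_s <= 1))
  prod(1 - h * het_s) * prod(1 - hom_s)
}

#' Summarise a fitness trajectory around a reproductive-mode switch
#'
#' `decline_pct = 100 * (w_pre - min w in the post-switch window) / w_pre`
#' with `w_pre` the mean fitness just before the switch; recovery is the
#' first post-minimum generation whose fitness is within `eps` (relative)
#' of the no-switch control trajectory (or of `w_pre` when no control is
#' given).
#'
#' @param traj trajectory matrix with a `mean_w` column (post-switch
#'   generations).
#' @param w_pre mean fitness immediately before the switch.
#' @param window generations after the switch to search for the minimum
#'   (default: whole trajectory).
#' @param control optional control trajectory matrix aligned with `traj`.
#' @param eps relative recovery tolerance (default 0.005).
#' @return list with `decline_pct`, `min_generation`,
#'   `recovery_generation` (NA if never recovered).
#' @export
summarize_transition <- function(traj, w_pre, window = nrow(traj),
                                 control = NULL, eps = 0.005) {
  w <- traj[, "mean_w"]
  window <- min(window, length(w))
  i_min <- which.min(w[seq_len(window)])
  decline <- 100 * (w_pre - w[i_min]) / w_pre
  ref <- if (is.null(control)) rep(w_pre, length(w)) else control[, "mean_w"]
  rec <- NA_integer_
  for (g in i_min:length(w)) {
    if (w[g] >= ref[g] * (1 - eps)) { rec <- g; break }
  }
  list(decline_pct = decline, min_generation = i_min,
       recovery_generation = rec)
}
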