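## Thermodynamic stability: folded energy as a sum of contact potentials,
## an unfolded-state ensemble summarized by the mean and (population)
## variance of decoy energies under a Gaussian approximation, and the
## resulting free energy difference
##   dG = E_F - Ebar + (beta/2) dE2 + (1/beta) ln N_U,   N_U = nu^L,
## with fitness the probability of occupying the native fold,
##   P_fold = exp(-beta dG) / (exp(-beta dG) + 1).

#' Energetics parameters
#'
#' @param kT Thermal energy unit; beta = 1/kT. Default 0.6.
#' @param nu Unfolded configurations per residue; the unfolded state has
#'   N_U = nu^L microstates. Default 3.4.
#' @return An object of class `energetics_params`.
#' @export
energetics_params <- function(kT = 0.6, nu = 3.4) {
  stopifnot(kT > 0, nu > 1)
  structure(list(kT = kT, beta = 1 / kT, nu = nu), class = "energetics_params")
}

#' Contact energy of a sequence on a map
#'
#' Sum of pairwise potentials over contacting residue pairs.
#'
#' @param aa_seq Character vector of amino acids (length = map size).
#' @param map A [contact_map()].
#' @param pot A [contact_potentials()].
#' @return Scalar energy.
#' @export
contact_energy <- function(aa_seq, map, pot) {
  if (length(aa_seq) != map$L) stop("sequence length != contact map size")
  if (nrow(map$pairs) == 0) return(0)
  idx <- aa_index(aa_seq)
  sum(pot$epsilon[cbind(idx[map$pairs[, 1]], idx[map$pairs[, 2]])])
}

#' Unfolded-ensemble energy moments
#'
#' Mean and population variance (divide-by-n, matching a Gaussian fit by
#' moments) of the sequence's contact energy over the decoy maps.
#'
#' @param aa_seq Amino acid sequence.
#' @param decoys A [generate_decoys()] ensemble.
#' @param pot A [contact_potentials()].
#' @return List with `E_bar` and `dE2`.
#' @export
unfolded_stats <- function(aa_seq, decoys, pot) {
  stopifnot(inherits(decoys, "decoy_set"))
  if (decoys$n_decoys < 2) stop("need >= 2 decoys to estimate a variance")
  e <- vapply(decoys$maps, function(m) contact_energy(aa_seq, m, pot),
              numeric(1))
  list(E_bar = mean(e), dE2 = mean(e^2) - mean(e)^2)
}

#' Folding free energy and fitness of a sequence
#'
#' @param aa_seq Amino acid sequence.
#' @param native Native [contact_map()].
#' @param decoys Decoy ensemble for the unfolded state.
#' @param pot A [contact_potentials()].
#' @param params An [energetics_params()].
#' @return An object of class `stability_result` with fields `E_F`, `E_bar`,
#'   `dE2`, `ln_Z_U`, `delta_G`, `fitness`.
#' @export
delta_G <- function(aa_seq, native, decoys, pot,
                    params = energetics_params()) {
  if (length(aa_seq) != native$L) stop("sequence length != contact map size")
  if (decoys$L != native$L) stop("decoy size != native size")
  E_F <- contact_energy(aa_seq, native, pot)
  u <- unfolded_stats(aa_seq, decoys, pot)
  beta <- params$beta
  L <- native$L
  ## ln Z_U kept in log space: ln N_U + beta^2 dE2 / 2 - beta Ebar
  ln_Z_U <- L * log(params$nu) + 0.5 * beta^2 * u$dE2 - beta * u$E_bar
  dG <- E_F + ln_Z_U / beta
  structure(list(E_F = E_F, E_bar = u$E_bar, dE2 = u$dE2, ln_Z_U = ln_Z_U,
                 delta_G = dG, fitness = fitness_from_dG(dG, params)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: dG = %.4f, fitness = %.6f\n",
              x$delta_G, x$fitness))
  invisible(x)
}

#' Fitness (probability of folding) from a free energy
#'
#' Logistic in -beta dG, evaluated via `plogis` so large |beta dG| cannot
#' overflow; output is strictly inside (0, 1) up to double precision.
#'
#' @param dG Free energy (scalar or vector).
#' @param params An [energetics_params()].
#' @export
fitness_from_dG <- function(dG, params = energetics_params()) {
  stats::plogis(-params$beta * dG)
}

#' Incremental energy state for repeated single-site substitutions
#'
#' Caches the folded energy, every decoy energy, and per-site contact index
#' structures, so the stability effect of a point substitution costs
#' O(contacts x n_decoys) instead of a full recomputation.
#'
#' @param aa_seq Amino acid sequence.
#' @inheritParams delta_G
#' @return An object of class `energy_cache`.
#' @export
energy_cache <- function(aa_seq, native, decoys, pot,
                         params = energetics_params()) {
  idx <- aa_index(aa_seq)
  L <- native$L
  ## Per-site native contact partners.
  nat_partners <- lapply(seq_len(L), function(h) {
    c(native$pairs[native$pairs[, 1] == h, 2],
      native$pairs[native$pairs[, 2] == h, 1])
  })
  ## Per-site decoy contact partners, flattened with a decoy grouping.
  dec_partners <- vector("list", L)
  dec_group <- vector("list", L)
  for (d in seq_len(decoys$n_decoys)) {
    p <- decoys$maps[[d]]$pairs
    for (col in 1:2) {
      h <- p[, col]
      j <- p[, 3 - col]
      for (r in seq_along(h)) {
        dec_partners[[h[r]]] <- c(dec_partners[[h[r]]], j[r])
        dec_group[[h[r]]] <- c(dec_group[[h[r]]], d)
      }
    }
  }
  e_dec <- vapply(decoys$maps, function(m) contact_energy(aa_seq, m, pot),
                  numeric(1))
  structure(list(aa_idx = idx, E_F = contact_energy(aa_seq, native, pot),
                 E_dec = e_dec, nat_partners = nat_partners,
                 dec_partners = dec_partners, dec_group = dec_group,
                 n_decoys = decoys$n_decoys, L = L, pot = pot$epsilon,
                 params = params),
            class = "energy_cache")
}

#' @noRd
.cache_dG <- function(cache) {
  Ebar <- mean(cache$E_dec)
  dE2 <- mean(cache$E_dec^2) - Ebar^2
  beta <- cache$params$beta
  cache$E_F - Ebar + 0.5 * beta * dE2 +
    cache$L * log(cache$params$nu) / beta
}

#' Stability effect of a single substitution, computed incrementally
#'
#' Updates only the energy terms that involve the mutated site, in the
#' native map and in every decoy. Negative ddG = stabilizing.
#'
#' @param cache An [energy_cache()] for the current sequence.
#' @param site Site index (1..L).
#' @param new_aa Replacement amino acid (one-letter code).
#' @return List with `ddG` and `cache` (advanced to the mutant sequence).
#' @export
ddG_of_substitution <- function(cache, site, new_aa) {
  stopifnot(inherits(cache, "energy_cache"))
  new_idx <- aa_index(new_aa)
  old_idx <- cache$aa_idx[site]
  dG0 <- .cache_dG(cache)
  if (new_idx != old_idx) {
    np <- cache$nat_partners[[site]]
    if (length(np) > 0) {
      cache$E_F <- cache$E_F +
        sum(cache$pot[new_idx, cache$aa_idx[np]]) -
        sum(cache$pot[old_idx, cache$aa_idx[np]])
    }
    dp <- cache$dec_partners[[site]]
    if (length(dp) > 0) {
      delta <- cache$pot[new_idx, cache$aa_idx[dp]] -
        cache$pot[old_idx, cache$aa_idx[dp]]
      per_decoy <- rowsum(delta, cache$dec_group[[site]])
      ids <- as.integer(rownames(per_decoy))
      cache$E_dec[ids] <- cache$E_dec[ids] + per_decoy[, 1]
    }
    cache$aa_idx[site] <- new_idx
  }
  list(ddG = .cache_dG(cache) - dG0, cache = cache)
}
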