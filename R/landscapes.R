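## Site-specific fitness and propensity landscapes, landscape entropy, and
## the per-substitution effects (resident-propensity changes and entropy
## changes) behind the permissive/restrictive classification.

#' Site-specific fitness landscape
#'
#' Fitness of each of the 20 amino acids at one site, holding the rest of
#' the sequence constant; computed via incremental energy substitution.
#'
#' @param ctx An [evol_context()].
#' @param state An [make_state()] state.
#' @param site Site index (1..L); `NULL` returns the full L x 20 matrix.
#' @return Named 20-vector (or L x 20 matrix) of fitness values.
#' @export
site_fitness_landscape <- function(ctx, state, site = NULL) {
  land <- .state_landscape(ctx, state, need_prop = FALSE)
  f <- land$f_mat
  colnames(f) <- aa_alphabet()
  if (is.null(site)) f else f[site, ]
}

#' Propensities from a fitness landscape
#'
#' pi_a proportional to pi0_a * exp(c f_a), normalized over the 20 amino
#' acids. Under the `"reported"` convention c = 2 Ne; under
#' `"detailed_balance"` c = 4 Ne - 2, the exponent for which the stationary
#' law of the diploid fixation process is exactly of this form.
#'
#' @param fitness_vector 20-vector of fitness values.
#' @param pi0 Neutral amino acid frequencies (sums to 1).
#' @param Ne Effective population size.
#' @param exponent Convention, `"reported"` (default) or `"detailed_balance"`.
#' @return Named 20-vector summing to 1.
#' @export
site_propensities <- function(fitness_vector, pi0, Ne,
                              exponent = c("reported", "detailed_balance")) {
  exponent <- match.arg(exponent)
  stopifnot(length(fitness_vector) == 20, length(pi0) == 20)
  if (abs(sum(pi0) - 1) > 1e-6) stop("pi0 must sum to 1")
  cc <- if (exponent == "reported") 2 * Ne else 4 * Ne - 2
  w <- pi0 * exp(cc * (fitness_vector - max(fitness_vector)))
  stats::setNames(w / sum(w), aa_alphabet())
}

#' Full propensity landscape of a state
#'
#' @inheritParams site_fitness_landscape
#' @return Named 20-vector (or L x 20 matrix) of propensities.
#' @export
site_propensity_landscape <- function(ctx, state, site = NULL) {
  land <- .state_landscape(ctx, state, need_prop = TRUE)
  p <- land$prop_mat
  colnames(p) <- aa_alphabet()
  if (is.null(site)) p else p[site, ]
}

#' Expected replacement rate at a site
#'
#' Sum of jump-chain rates over all single-nucleotide neighbors whose amino
#' acid at the site differs from the resident.
#'
#' @inheritParams site_fitness_landscape
#' @return Scalar rate (or length-L vector if `site = NULL`).
#' @export
replacement_rate <- function(ctx, state, site = NULL) {
  nb <- neighbor_rates(ctx, state)
  nonsyn <- !nb$synonymous & !is.na(nb$neighbor_codon)
  r <- rowSums(nb$rates * nonsyn)
  if (is.null(site)) r else r[site]
}

#' Shannon entropy of a propensity landscape
#'
#' -sum pi log pi with 0 log 0 := 0; in [0, log 20].
#'
#' @param propensity_vector Normalized nonnegative vector.
#' @return Entropy in nats.
#' @export
landscape_entropy <- function(propensity_vector) {
  p <- propensity_vector
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6) {
    stop("propensity vector must be nonnegative and sum to 1")
  }
  lp <- p * log(p)
  lp[p <= 0] <- 0
  -sum(lp)
}

#' Effect of one substitution on every site's landscape
#'
#' Compares the landscapes before and after a single-nucleotide
#' substitution: the change in the propensity of each site's resident amino
#' acid (at the substituted site, pi_b(after) - pi_a(before), i.e. the
#' incoming versus outgoing resident), the per-site entropy change, their
#' averages, and the permissive / restrictive / neutral classification by
#' the sign of the average entropy change.
#'
#' @param ctx An [evol_context()].
#' @param state_before,state_after States differing by exactly one
#'   nucleotide.
#' @return An object of class `substitution_effect`: list with `ddG`,
#'   `d_prop` (per-site), `d_entropy` (per-site), `avg_dU`,
#'   `frac_sites_neg_dprop`, `classification`, `synonymous`.
#' @export
substitution_effect <- function(ctx, state_before, state_after) {
  c1 <- state_codons(ctx, state_before)
  c2 <- state_codons(ctx, state_after)
  ndiff <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, c1, c2))
  if (ndiff != 1) {
    stop("states must differ by exactly one nucleotide (found ", ndiff, ")")
  }
  lb <- .state_landscape(ctx, state_before, need_prop = TRUE)
  la <- .state_landscape(ctx, state_after, need_prop = TRUE)
  L <- ctx$L
  res_before <- state_before$aa
  res_after <- state_after$aa
  ## Resident propensity after, tracked at the *new* resident of the
  ## substituted site and the (unchanged) resident elsewhere.
  p_before <- lb$prop_mat[cbind(seq_len(L), res_before)]
  p_after <- la$prop_mat[cbind(seq_len(L), res_after)]
  d_prop <- p_after - p_before
  d_entropy <- la$entropy - lb$entropy
  avg_dU <- mean(d_entropy)
  ddG <- state_after$dG - state_before$dG
  synonymous <- all(res_before == res_after)
  classification <- if (avg_dU > 0) "permissive"
    else if (avg_dU < 0) "restrictive" else "neutral"
  structure(list(ddG = ddG, d_prop = d_prop, d_entropy = d_entropy,
                 avg_dU = avg_dU,
                 frac_sites_neg_dprop = mean(d_prop < 0),
                 classification = classification, synonymous = synonymous),
            class = "substitution_effect")
}

#' @export
print.substitution_effect <- function(x, ...) {
  cat(sprintf(
    "substitution_effect: ddG = %.4f, avg dU = %.5f (%s), %d%% sites dPi<0\n",
    x$ddG, x$avg_dU, x$classification,
    round(100 * x$frac_sites_neg_dprop)))
  invisible(x)
}

#' Per-substitution effects read off a recorded trajectory
#'
#' Uses the recorded resident propensities and entropies, so the change at
#' the substituted site compares the incoming resident to the outgoing one.
#'
#' @param traj A [simulate_trajectory()] record.
#' @return Data frame: step, synonymous, ddG, avg_dU, frac_sites_neg_dprop,
#'   classification.
#' @export
substitution_effects_from_trajectory <- function(traj) {
  n <- traj$n
  if (n == 0) {
    return(data.frame(step = integer(0), synonymous = logical(0),
                      ddG = numeric(0), avg_dU = numeric(0),
                      frac_sites_neg_dprop = numeric(0),
                      classification = character(0)))
  }
  d_prop <- traj$resident_prop[-1, , drop = FALSE] -
    traj$resident_prop[-(n + 1), , drop = FALSE]
  d_entropy <- traj$entropy[-1, , drop = FALSE] -
    traj$entropy[-(n + 1), , drop = FALSE]
  avg_dU <- rowMeans(d_entropy)
  data.frame(step = seq_len(n), synonymous = traj$steps$synonymous,
             ddG = traj$steps$ddG, avg_dU = avg_dU,
             frac_sites_neg_dprop = rowMeans(d_prop < 0),
             classification = ifelse(avg_dU > 0, "permissive",
                                     ifelse(avg_dU < 0, "restrictive",
                                            "neutral")))
}

#' Stability / uniformity profile of a trajectory
#'
#' Per-state (dG, site-averaged landscape entropy) and per-substitution
#' (ddG, site-averaged entropy change) tables, with their Spearman rank
#' correlations. Substitution-level correlations are computed over
#' nonsynonymous substitutions (synonymous ones change neither quantity by
#' construction). Zero-variance columns give NA correlations.
#'
#' @param traj A [simulate_trajectory()] record.
#' @return List: `states` and `substitutions` data frames,
#'   `spearman_dG_avgU`, `spearman_ddG_avg_dU`.
#' @export
stability_uniformity_profile <- function(traj) {
  states <- data.frame(state = 0:traj$n, dG = traj$dG,
                       avg_U = traj$avg_entropy)
  subs <- substitution_effects_from_trajectory(traj)
  safe_spearman <- function(x, y) {
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
  }
  ns <- subs[!subs$synonymous, , drop = FALSE]
  list(states = states, substitutions = subs,
       spearman_dG_avgU = safe_spearman(states$dG, states$avg_U),
       spearman_ddG_avg_dU = safe_spearman(ns$ddG, ns$avg_dU))
}
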