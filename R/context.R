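## Evolution context: everything fixed during a simulation (structure,
## decoys, potentials, mutation model, population size), plus sparse
## precomputations that make per-state site-landscape evaluation cheap.
##
## For a sequence state we need, at every site h and amino acid b, the free
## energy of the variant with b at h. Writing P[b, j] = epsilon(b, a_j) for
## the current sequence a, the native-energy change is a column of P %*% CM
## (CM the native adjacency), and the decoy-energy changes are columns of
## P %*% W where W column-binds all decoy adjacencies. Both products are
## sparse-dense and cost O(20 x total contacts) per state.

#' Build an evolution context
#'
#' @param native Native [contact_map()].
#' @param decoys [generate_decoys()] ensemble (same L).
#' @param pot A [contact_potentials()].
#' @param mut A [mutation_params()].
#' @param Ne Effective population size (default 100).
#' @param params An [energetics_params()] (kT = 0.6, nu = 3.4 by default).
#' @param exponent Propensity exponent convention: `"reported"` uses
#'   2 Ne f (the form propensities are reported in), `"detailed_balance"`
#'   uses (4 Ne - 2) f, the exponent implied by the diploid fixation
#'   probability and under which the process is exactly reversible.
#' @return An object of class `evol_context`.
#' @export
evol_context <- function(native, decoys, pot, mut, Ne = 100,
                         params = energetics_params(),
                         exponent = c("reported", "detailed_balance")) {
  stopifnot(inherits(native, "contact_map"), inherits(decoys, "decoy_set"),
            inherits(pot, "contact_potentials"),
            inherits(mut, "mutation_params"), Ne >= 1)
  if (decoys$L != native$L) stop("decoy size != native size")
  exponent <- match.arg(exponent)
  L <- native$L
  nd <- decoys$n_decoys
  adj <- function(map) {
    p <- map$pairs
    Matrix::sparseMatrix(i = c(p[, 1], p[, 2]), j = c(p[, 2], p[, 1]),
                         x = 1, dims = c(L, L))
  }
  CM <- adj(native)
  W <- do.call(cbind, lapply(decoys$maps, adj))   # L x (L * nd)
  tabs <- codon_tables()
  ## Per-codon relative mutation rate to each of the 9 neighbors.
  mu_tab <- matrix(mut$pi_nuc[tabs$nbr_newnuc], tabs$n, 9L)
  mu_tab[tabs$nbr_is_ts] <- mu_tab[tabs$nbr_is_ts] * mut$kappa
  mu_tab[is.na(tabs$nbr_codon)] <- 0          # stop-codon neighbors
  cfreq <- neutral_codon_frequencies(mut)
  pi0 <- neutral_aa_frequencies(cfreq)
  sel <- if (exponent == "reported") 2 * Ne else 4 * Ne - 2
  structure(list(native = native, decoys = decoys, pot = pot, mut = mut,
                 Ne = Ne, params = params, exponent = exponent,
                 sel_coef = sel, L = L, n_decoys = nd,
                 eps = pot$epsilon, CM = CM, W = W, tabs = tabs,
                 mu_tab = mu_tab, codon_freqs = cfreq, pi0 = pi0,
                 const_dG = L * log(params$nu) / params$beta),
            class = "evol_context")
}

#' @export
print.evol_context <- function(x, ...) {
  cat("evol_context: L =", x$L, ",", x$n_decoys, "decoys, Ne =", x$Ne,
      ", kT =", x$params$kT, ", exponent =", x$exponent, "\n")
  invisible(x)
}

#' Sequence state of the jump chain
#'
#' Builds the evolving state (codon sequence plus cached energies) for a
#' context. Codons may be given as strings or as indices into the 61 sense
#' codons.
#'
#' @param ctx An [evol_context()].
#' @param codons Character vector of codon strings (or integer sense-codon
#'   indices), length L.
#' @return An object of class `evol_state`.
#' @export
make_state <- function(ctx, codons) {
  tabs <- ctx$tabs
  if (is.character(codons)) {
    idx <- tabs$codon_index[codons]
    if (anyNA(idx)) stop("stop codon or invalid codon in sequence")
    codons <- unname(idx)
  }
  codons <- as.integer(codons)
  stopifnot(length(codons) == ctx$L, all(codons >= 1), all(codons <= tabs$n))
  aa <- tabs$codon_aa[codons]
  P <- ctx$eps[, aa, drop = FALSE]
  aa_chr <- aa_alphabet()[aa]
  E_F <- contact_energy(aa_chr, ctx$native, ctx$pot)
  E_dec <- vapply(ctx$decoys$maps,
                  function(m) contact_energy(aa_chr, m, ctx$pot), numeric(1))
  st <- list(codons = codons, aa = aa, P = P, E_F = E_F, E_dec = E_dec)
  st[c("dG", "fitness")] <- .state_dG(ctx, st)
  structure(st, class = "evol_state")
}

#' @export
print.evol_state <- function(x, ...) {
  cat(sprintf("evol_state: L = %d, dG = %.4f, fitness = %.6f\n",
              length(x$codons), x$dG, x$fitness))
  invisible(x)
}

#' @noRd
.state_dG <- function(ctx, st) {
  Ebar <- mean(st$E_dec)
  dE2 <- mean(st$E_dec^2) - Ebar^2
  dG <- st$E_F - Ebar + 0.5 * ctx$params$beta * dE2 + ctx$const_dG
  list(dG = dG, fitness = fitness_from_dG(dG, ctx$params))
}

#' Codon strings of a state
#' @param ctx An [evol_context()]; `state` an [make_state()] state.
#' @param state An `evol_state`.
#' @export
state_codons <- function(ctx, state) ctx$tabs$codons[state$codons]

#' Amino acid sequence of a state
#' @inheritParams state_codons
#' @export
state_aa <- function(ctx, state) aa_alphabet()[state$aa]

## Full per-site landscape of a state. Returns (as a list):
##   dG_mat, f_mat, prop_mat : L x 20 matrices over amino acids
##   entropy, resident_prop  : length-L vectors
##   dNall (20 x L), Dall (20 x L*nd) : energy-delta building blocks kept
##   for the O(contacts) state update after a substitution.
#' @noRd
.state_landscape <- function(ctx, st, need_prop = TRUE) {
  L <- ctx$L
  nd <- ctx$n_decoys
  beta <- ctx$params$beta
  dNall <- as.matrix(st$P %*% ctx$CM)
  Dall <- as.matrix(st$P %*% ctx$W)
  dG_mat <- matrix(0, L, 20L)
  inv_nd <- 1 / nd
  for (h in seq_len(L)) {
    a_h <- st$aa[h]
    dN <- dNall[, h]
    Df <- Dall[, h + L * 0:(nd - 1), drop = FALSE]
    ## decoy energies of each variant b: E_dec + Df[b, ] - Df[a_h, ]
    Eb <- Df + matrix(st$E_dec - Df[a_h, ], 20L, nd, byrow = TRUE)
    m1 <- rowSums(Eb) * inv_nd
    v <- rowSums(Eb * Eb) * inv_nd - m1 * m1
    dG_mat[h, ] <- (st$E_F - dN[a_h] + dN) - m1 + 0.5 * beta * v +
      ctx$const_dG
  }
  f_mat <- stats::plogis(-beta * dG_mat)
  out <- list(dG_mat = dG_mat, f_mat = f_mat, dNall = dNall, Dall = Dall)
  if (need_prop) {
    w <- exp(ctx$sel_coef * (f_mat - matrixStats_rowMax(f_mat)))
    w <- w * matrix(ctx$pi0, L, 20L, byrow = TRUE)
    prop <- w / rowSums(w)
    lp <- prop * log(prop)
    lp[prop == 0] <- 0
    out$prop_mat <- prop
    out$entropy <- -rowSums(lp)
    out$resident_prop <- prop[cbind(seq_len(L), st$aa)]
  }
  out
}

#' @noRd
matrixStats_rowMax <- function(m) {
  ## row maxima without a matrixStats dependency
  do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
}

## Neighbor substitution rates of a state: L x 9 matrix over the single-
## nucleotide codon neighbors; q = 2 Ne mu P_fix, with stop neighbors 0 and
## synonymous neighbors at the neutral rate mu.
#' @noRd
.state_rates <- function(ctx, st, land) {
  tabs <- ctx$tabs
  L <- ctx$L
  mu <- ctx$mu_tab[st$codons, , drop = FALSE]
  A <- tabs$nbr_aa[st$codons, , drop = FALSE]
  syn <- tabs$nbr_syn[st$codons, , drop = FALSE]
  rates <- mu                                     # synonymous: 2 Ne mu / (2 Ne)
  ns <- which(!syn & mu > 0)
  if (length(ns) > 0) {
    h <- (ns - 1L) %% L + 1L
    f_t <- land$f_mat[cbind(h, A[ns])]
    pfix <- fixation_probability(st$fitness, f_t, ctx$Ne)
    rates[ns] <- 2 * ctx$Ne * mu[ns] * pfix
  }
  rates
}

## Apply the substitution chosen as flat index `pick` of the L x 9 rate
## matrix; uses the landscape's cached energy deltas for an O(1) update.
#' @noRd
.apply_substitution <- function(ctx, st, land, pick) {
  L <- ctx$L
  h <- (pick - 1L) %% L + 1L
  k <- (pick - 1L) %/% L + 1L
  tabs <- ctx$tabs
  old_codon <- st$codons[h]
  new_codon <- tabs$nbr_codon[old_codon, k]
  if (is.na(new_codon)) stop("internal: substitution into a stop codon")
  old_aa <- st$aa[h]
  new_aa <- tabs$codon_aa[new_codon]
  st$codons[h] <- new_codon
  if (new_aa != old_aa) {
    dN <- land$dNall[, h]
    Df <- land$Dall[, h + L * 0:(ctx$n_decoys - 1), drop = FALSE]
    st$E_F <- st$E_F + dN[new_aa] - dN[old_aa]
    st$E_dec <- st$E_dec + Df[new_aa, ] - Df[old_aa, ]
    st$aa[h] <- new_aa
    st$P[, h] <- ctx$eps[, new_aa]
    st$dG <- land$dG_mat[h, new_aa]
    st$fitness <- land$f_mat[h, new_aa]
  }
  attr(st, "last") <- list(site = h, old_codon = old_codon,
                           new_codon = new_codon,
                           old_aa = old_aa, new_aa = new_aa,
                           synonymous = new_aa == old_aa)
  st
}

## Recompute cached energies from scratch (guards against float drift on
## very long chains).
#' @noRd
.resync_state <- function(ctx, st) {
  aa_chr <- aa_alphabet()[st$aa]
  st$E_F <- contact_energy(aa_chr, ctx$native, ctx$pot)
  st$E_dec <- vapply(ctx$decoys$maps,
                     function(m) contact_energy(aa_chr, m, ctx$pot),
                     numeric(1))
  st[c("dG", "fitness")] <- .state_dG(ctx, st)
  st
}
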