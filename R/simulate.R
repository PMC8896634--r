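## The origin-fixation jump chain: at each step every single-nucleotide
## neighbor of the current codon sequence gets rate q = 2 Ne mu P_fix, the
## next state is a categorical draw proportional to q, and time is counted
## in substitutions (synonymous included).

#' Substitution rates to all single-nucleotide neighbors
#'
#' @param ctx An [evol_context()].
#' @param state An [make_state()] state.
#' @return List: `rates` (L x 9 matrix, 0 for stop-codon neighbors),
#'   `site`, `neighbor_codon`, `neighbor_aa`, `synonymous` (same shape),
#'   and the state's `landscape`.
#' @export
neighbor_rates <- function(ctx, state) {
  land <- .state_landscape(ctx, state, need_prop = FALSE)
  rates <- .state_rates(ctx, state, land)
  tabs <- ctx$tabs
  list(rates = rates,
       site = matrix(seq_len(ctx$L), ctx$L, 9L),
       neighbor_codon = tabs$nbr_codon[state$codons, , drop = FALSE],
       neighbor_aa = tabs$nbr_aa[state$codons, , drop = FALSE],
       synonymous = tabs$nbr_syn[state$codons, , drop = FALSE],
       landscape = land)
}

#' Sample the next substitution from a rate table
#'
#' Categorical draw with probability q / sum(q); uses the current RNG state.
#'
#' @param rates Numeric vector or matrix of nonnegative rates.
#' @return Flat index of the chosen neighbor.
#' @export
sample_substitution <- function(rates) {
  r <- as.numeric(rates)
  tot <- sum(r)
  if (!is.finite(tot) || tot <= 0) {
    stop("all substitution rates are zero: absorbing state")
  }
  sample.int(length(r), 1L, prob = r)
}

#' Draw a random stop-free codon sequence from the neutral codon frequencies
#'
#' @param ctx An [evol_context()].
#' @return An [make_state()] state.
#' @export
random_start_state <- function(ctx) {
  idx <- sample.int(ctx$tabs$n, ctx$L, replace = TRUE,
                    prob = ctx$codon_freqs)
  make_state(ctx, idx)
}

#' Equilibrate a sequence on its structure
#'
#' Two phases. Phase 1: from a random stop-free sequence, greedy uphill --
#' repeatedly accept the single-nucleotide nonsynonymous neighbor with the
#' lowest variant dG -- until fitness >= `fitness_target`. Phase 2: evolve
#' under the full substitution process for `burn_in` substitutions and
#' require a dG plateau: over the last `plateau_window` substitutions the
#' mean per-step dG drift must be indistinguishable from zero -- below
#' `max(plateau_slope, 2 SE)` where SE is the standard error of the mean
#' step increment. The SE term adapts the test to the equilibrium wander of
#' dG (a mean-reverting walk whose raw local slope does not shrink to zero),
#' while `plateau_slope` is the hard floor. Burn-in continues in
#' `plateau_window`-sized blocks up to `max_burn_in` if the plateau is not
#' yet reached.
#'
#' @param ctx An [evol_context()].
#' @param fitness_target Equilibration fitness threshold (default 0.99).
#' @param burn_in Substitutions of full-model burn-in (default 200).
#' @param plateau_window Window for the slope test (default 100).
#' @param plateau_slope Plateau tolerance, energy units per substitution
#'   (default 0.01).
#' @param max_uphill Step budget for phase 1 (default 50 * L).
#' @param max_burn_in Total burn-in budget (default 1000).
#' @param start Optional starting state (default: random).
#' @return An equilibrated `evol_state`; attribute `"equilibration"` carries
#'   diagnostics (uphill steps, burn-in length, final dG slope).
#' @export
equilibrate <- function(ctx, fitness_target = 0.99, burn_in = 200L,
                        plateau_window = 100L, plateau_slope = 0.01,
                        max_uphill = 50L * ctx$L, max_burn_in = 2000L,
                        start = NULL) {
  st <- if (is.null(start)) random_start_state(ctx) else start
  tabs <- ctx$tabs
  L <- ctx$L
  ## Phase 1: steepest descent in dG over nonsynonymous neighbors. If the
  ## greedy walk stalls in a local optimum below the target, the stochastic
  ## jump chain takes over (near the threshold it crosses readily).
  uphill <- 0L
  while (st$fitness < fitness_target) {
    if (uphill >= max_uphill) {
      stop("equilibration failed: fitness ", format(st$fitness),
           " < ", fitness_target, " after ", uphill, " uphill steps")
    }
    land <- .state_landscape(ctx, st, need_prop = FALSE)
    A <- tabs$nbr_aa[st$codons, , drop = FALSE]
    ok <- !is.na(A) & A != matrix(st$aa, L, 9L)
    cand_dG <- matrix(Inf, L, 9L)
    idx <- which(ok)
    h <- (idx - 1L) %% L + 1L
    cand_dG[idx] <- land$dG_mat[cbind(h, A[idx])]
    best <- which.min(cand_dG)
    if (cand_dG[best] >= st$dG) {
      st <- .apply_substitution(ctx, st, land,
                                sample_substitution(.state_rates(ctx, st,
                                                                 land)))
    } else {
      st <- .apply_substitution(ctx, st, land, best)
    }
    uphill <- uphill + 1L
  }
  ## Phase 2: full-model burn-in until the dG trace plateaus.
  dG_trace <- numeric(0)
  total <- 0L
  block <- burn_in
  slope <- Inf
  repeat {
    for (i in seq_len(block)) {
      land <- .state_landscape(ctx, st, need_prop = FALSE)
      rates <- .state_rates(ctx, st, land)
      st <- .apply_substitution(ctx, st, land, sample_substitution(rates))
      dG_trace <- c(dG_trace, st$dG)
    }
    total <- total + block
    inc <- diff(utils::tail(dG_trace, plateau_window + 1L))
    slope <- mean(inc)
    tol <- max(plateau_slope, 2 * stats::sd(inc) / sqrt(length(inc)))
    if (abs(slope) < tol) break
    if (total >= max_burn_in) {
      stop("equilibration failed: |dG slope| = ", format(abs(slope)),
           " after ", total, " burn-in substitutions")
    }
    block <- plateau_window
  }
  st <- .resync_state(ctx, st)
  attr(st, "equilibration") <- list(uphill_steps = uphill,
                                    burn_in = total,
                                    dG_slope = slope,
                                    dG = st$dG, fitness = st$fitness)
  st
}

#' Simulate the substitution process and record the trajectory
#'
#' Runs `n_substitutions` jump-chain steps from `state` (normally an
#' [equilibrate()]d sequence), recording per step the substitution, dG,
#' ddG and fitness, and per state per site the resident amino acid, its
#' propensity, the landscape entropy and (optionally) the replacement rate
#' and the full 20-vector propensity landscape.
#'
#' @param ctx An [evol_context()].
#' @param state Starting `evol_state`.
#' @param n_substitutions Number of substitutions (>= 0).
#' @param record_replacement_rate Record per-site replacement rates
#'   (default TRUE; cheap, derived from the rates already computed).
#' @param record_full_landscapes Keep the full L x 20 propensity matrix at
#'   every state (default FALSE; storage grows as n x L x 20).
#' @param resync_every Recompute cached energies from scratch every this
#'   many steps (default 500).
#' @return An object of class `trajectory`; see Details.
#' @details The record holds states 0..n (rows of the per-site matrices) and
#'   substitutions 1..n (rows of `$steps`). Consecutive states differ by one
#'   nucleotide and `ddG[x] = dG[x] - dG[x-1]` by construction.
#' @export
simulate_trajectory <- function(ctx, state, n_substitutions = 500L,
                                record_replacement_rate = TRUE,
                                record_full_landscapes = FALSE,
                                resync_every = 500L) {
  n <- as.integer(n_substitutions)
  stopifnot(n >= 0)
  L <- ctx$L
  resident_prop <- matrix(NA_real_, n + 1L, L)
  entropy <- matrix(NA_real_, n + 1L, L)
  resident_aa <- matrix(NA_integer_, n + 1L, L)
  repl_rate <- if (record_replacement_rate) matrix(NA_real_, n + 1L, L)
  prop_full <- if (record_full_landscapes) array(NA_real_, c(n + 1L, L, 20L))
  dG <- numeric(n + 1L)
  fitness <- numeric(n + 1L)
  steps <- data.frame(step = seq_len(n), site = rep(NA_integer_, n),
                      old_codon = rep(NA_character_, n),
                      new_codon = rep(NA_character_, n),
                      old_aa = rep(NA_character_, n),
                      new_aa = rep(NA_character_, n),
                      synonymous = rep(NA, n), dG = rep(NA_real_, n),
                      ddG = rep(NA_real_, n), fitness = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
  st <- state
  tabs <- ctx$tabs
  aa <- aa_alphabet()
  for (x in 0:n) {
    land <- .state_landscape(ctx, st, need_prop = TRUE)
    row <- x + 1L
    resident_prop[row, ] <- land$resident_prop
    entropy[row, ] <- land$entropy
    resident_aa[row, ] <- st$aa
    dG[row] <- st$dG
    fitness[row] <- st$fitness
    if (record_full_landscapes) prop_full[row, , ] <- land$prop_mat
    last_needed <- record_replacement_rate || x < n
    if (last_needed) {
      rates <- .state_rates(ctx, st, land)
      if (record_replacement_rate) {
        nonsyn <- !tabs$nbr_syn[st$codons, , drop = FALSE] &
          !is.na(tabs$nbr_codon[st$codons, , drop = FALSE])
        repl_rate[row, ] <- rowSums(rates * nonsyn)
      }
    }
    if (x == n) break
    st <- .apply_substitution(ctx, st, land, sample_substitution(rates))
    if (x %% resync_every == resync_every - 1L) st <- .resync_state(ctx, st)
    ev <- attr(st, "last")
    steps$site[x + 1L] <- ev$site
    steps$old_codon[x + 1L] <- tabs$codons[ev$old_codon]
    steps$new_codon[x + 1L] <- tabs$codons[ev$new_codon]
    steps$old_aa[x + 1L] <- aa[ev$old_aa]
    steps$new_aa[x + 1L] <- aa[ev$new_aa]
    steps$synonymous[x + 1L] <- ev$synonymous
    steps$dG[x + 1L] <- st$dG
    steps$fitness[x + 1L] <- st$fitness
  }
  steps$ddG <- steps$dG - dG[seq_len(n)]
  structure(list(steps = steps, resident_prop = resident_prop,
                 entropy = entropy, resident_aa = resident_aa,
                 repl_rate = repl_rate, prop_full = prop_full,
                 dG = dG, fitness = fitness,
                 avg_entropy = rowMeans(entropy),
                 L = L, n = n, final_state = st),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n, "substitutions, L =", x$L,
      sprintf(", dG %.2f -> %.2f\n", x$dG[1], x$dG[length(x$dG)]))
  invisible(x)
}

#' Write a trajectory's step table (TSV) and endpoint sequences (FASTA)
#'
#' @param traj A [simulate_trajectory()] record.
#' @param ctx The context it was simulated under.
#' @param prefix Output path prefix; writes `<prefix>_steps.tsv`,
#'   `<prefix>_resident_propensity.tsv` and `<prefix>_seqs.fasta`.
#' @export
write_trajectory <- function(traj, ctx, prefix) {
  utils::write.table(traj$steps, paste0(prefix, "_steps.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rp <- as.data.frame(traj$resident_prop)
  names(rp) <- paste0("site", seq_len(traj$L))
  utils::write.table(cbind(step = 0:traj$n, rp),
                     paste0(prefix, "_resident_propensity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  aa0 <- paste(aa_alphabet()[traj$resident_aa[1, ]], collapse = "")
  aan <- paste(aa_alphabet()[traj$resident_aa[traj$n + 1L, ]], collapse = "")
  seqs <- Biostrings::AAStringSet(c(initial = aa0, final = aan))
  Biostrings::writeXStringSet(seqs, paste0(prefix, "_seqs.fasta"))
  invisible(prefix)
}
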