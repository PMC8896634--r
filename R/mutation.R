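## HKY85 mutation model at the codon level and the diploid fixation
## probability of the origin-fixation (jump-chain) substitution process.

#' HKY85 mutation parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param pi_nuc Named or ordered (A, C, G, T) nucleotide frequencies;
#'   must be positive and sum to 1 (renormalized if `normalize = TRUE`).
#' @param normalize Renormalize frequencies to sum to 1.
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(kappa, pi_nuc, normalize = FALSE) {
  stopifnot(kappa > 0, length(pi_nuc) == 4, all(pi_nuc > 0))
  pi_nuc <- as.numeric(pi_nuc)
  if (normalize) pi_nuc <- pi_nuc / sum(pi_nuc)
  if (abs(sum(pi_nuc) - 1) > 1e-6) {
    stop("nucleotide frequencies must sum to 1 (use normalize = TRUE)")
  }
  names(pi_nuc) <- NUC
  structure(list(kappa = kappa, pi_nuc = pi_nuc), class = "mutation_params")
}

#' Neutral stationary frequencies of the 61 sense codons
#'
#' Frequency of codon lmn proportional to pi_l pi_m pi_n, normalized over
#' sense codons (stop codons are inaccessible states of the process).
#'
#' @param mut A [mutation_params()].
#' @return Named numeric 61-vector summing to 1.
#' @export
neutral_codon_frequencies <- function(mut) {
  tabs <- codon_tables()
  f <- apply(tabs$codon_nuc, 1, function(n) prod(mut$pi_nuc[n]))
  stats::setNames(f / sum(f), tabs$codons)
}

#' Neutral amino acid frequencies
#'
#' Per amino acid, the sum of its synonymous codons' neutral frequencies.
#' With `uniform = TRUE` returns the mutation-free alternative (1/20 each),
#' under which propensities reduce to purely thermodynamic preferences.
#'
#' @param codon_freqs Output of [neutral_codon_frequencies()] (ignored when
#'   `uniform = TRUE`).
#' @param uniform Use the uniform definition instead.
#' @return Named 20-vector summing to 1, in [aa_alphabet()] order.
#' @export
neutral_aa_frequencies <- function(codon_freqs = NULL, uniform = FALSE) {
  aa <- aa_alphabet()
  if (uniform) return(stats::setNames(rep(1 / 20, 20), aa))
  stopifnot(!is.null(codon_freqs))
  tabs <- codon_tables()
  f <- vapply(seq_len(20), function(a) sum(codon_freqs[tabs$codon_aa == a]),
              numeric(1))
  stats::setNames(f / sum(f), aa)
}

#' Relative mutation rate between two codons
#'
#' Zero unless the codons differ at exactly one nucleotide and the target is
#' a sense codon; otherwise pi_n for a transversion and kappa * pi_n for a
#' transition, where n is the new nucleotide.
#'
#' @param c_from,c_to Codon strings.
#' @param mut A [mutation_params()].
#' @return Relative rate (scalar).
#' @export
mutation_rate <- function(c_from, c_to, mut) {
  tabs <- codon_tables()
  if (is.na(tabs$codon_index[c_from])) stop("c_from is not a sense codon")
  if (is.na(tabs$codon_index[c_to])) return(0)
  n1 <- tabs$codon_nuc[tabs$codon_index[c_from], ]
  n2 <- tabs$codon_nuc[tabs$codon_index[c_to], ]
  diff <- which(n1 != n2)
  if (length(diff) != 1) return(0)
  new <- n2[diff]
  is_ts <- .ts_partner[[NUC[n1[diff]]]] == new
  unname(mut$pi_nuc[new] * if (is_ts) mut$kappa else 1)
}

#' Kimura fixation probability in a diploid population
#'
#' P_fix = (1 - exp(-2 df)) / (1 - exp(-4 Ne df)) with df = f_t - f_s.
#' Within `tol` of neutrality the limit 1/(2 Ne) is returned, which keeps the
#' function continuous where the ratio is numerically 0/0.
#'
#' @param f_s,f_t Fitness of the current and the mutant sequence, in (0, 1).
#'   Vectorized over `f_t`.
#' @param Ne Effective population size.
#' @param tol Neutrality tolerance on |df| (default 1e-12).
#' @return Fixation probability (same length as `f_t`).
#' @export
fixation_probability <- function(f_s, f_t, Ne, tol = 1e-12) {
  df <- f_t - f_s
  p <- ifelse(abs(df) < tol,
              1 / (2 * Ne),
              -expm1(-2 * df) / -expm1(-4 * Ne * df))
  unname(p)
}
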