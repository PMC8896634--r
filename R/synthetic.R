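## Synthetic inputs: compact chain structures with tunable contact density,
## random symmetric potential tables, and the reported study parameter sets,
## so the whole pipeline runs with no external downloads.

#' Generate a synthetic compact protein structure and its contact map
#'
#' Coordinates come from a seeded compact self-avoiding-walk-like chain
#' (unit bonds, hard core, centripetal bias keeping the chain inside a
#' globule of volume proportional to L), then the chain is rescaled by
#' bisection so the contact map at the 7 Angstrom cutoff reaches the target
#' mean contacts per site within 10%. The resulting bond lengths land near
#' 3.5-4 Angstrom, the C-beta spacing of real proteins.
#'
#' @param L Residue count (>= 10).
#' @param target_density Mean contacts per site (2..12; study proteins span
#'   6.9-8.4).
#' @param rng_seed Integer seed; fully deterministic given the seed.
#' @param cutoff,min_sep Contact-map parameters (defaults 7 Angstrom, 2).
#' @param residues Optional residue assignment (default all "A"; the contact
#'   map, not the residue identity, is what downstream energetics consume).
#' @return List: `structure` ([protein_structure()]), `map`
#'   ([contact_map()]), `density` (realized mean contacts per site).
#' @export
synthetic_structure <- function(L = 60L, target_density = 7,
                                rng_seed = 1L, cutoff = 7.0, min_sep = 2L,
                                residues = NULL) {
  stopifnot(L >= 10, target_density >= 2, target_density <= 12)
  coords <- withr::with_seed(rng_seed, .compact_chain(L))
  if (is.null(residues)) residues <- rep("A", L)
  ## Uniform rescaling: density at cutoff 7 of s * X is monotone
  ## nonincreasing in s, so bisect on s.
  dens <- function(s) {
    st <- protein_structure(coords * s, residues, source_id = "synthetic")
    contact_density(build_contact_map(st, cutoff = cutoff, min_sep = min_sep))
  }
  lo <- 0.2
  hi <- 30
  if (dens(lo) < target_density) {
    stop("target density ", target_density, " unreachable for L = ", L,
         " (max ", format(dens(lo), digits = 3), " at tightest packing)")
  }
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    if (dens(mid) > target_density) lo <- mid else hi <- mid
  }
  s_best <- if (abs(dens(lo) - target_density) < abs(dens(hi) - target_density))
    lo else hi
  realized <- dens(s_best)
  if (abs(realized - target_density) > 0.1 * target_density) {
    stop("could not reach density ", target_density, " within 10% (got ",
         format(realized, digits = 3), "); try another seed or L")
  }
  st <- protein_structure(coords * s_best, residues,
                          source_id = sprintf("synthetic(L=%d,seed=%d)",
                                              L, rng_seed))
  list(structure = st,
       map = build_contact_map(st, cutoff = cutoff, min_sep = min_sep),
       density = realized)
}

## Compact chain in unit-bond coordinates: hard core 0.8, globule radius
## for ~30% packing fraction, centripetal bias when near the edge.
#' @noRd
.compact_chain <- function(L, max_restarts = 50L) {
  r_max <- (L / 0.3 / (4 * pi / 3))^(1 / 3)
  for (restart in seq_len(max_restarts)) {
    pts <- matrix(0, L, 3)
    ok <- TRUE
    for (i in 2:L) {
      placed <- FALSE
      for (try in 1:60) {
        dir <- stats::rnorm(3)
        prev <- pts[i - 1, ]
        if (sqrt(sum(prev^2)) > 0.75 * r_max) {
          dir <- dir / sqrt(sum(dir^2)) - 1.2 * prev / sqrt(sum(prev^2))
        }
        dir <- dir / sqrt(sum(dir^2))
        cand <- prev + dir
        if (sqrt(sum(cand^2)) > r_max) next
        d2 <- rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                         matrix(cand, i - 1, 3, byrow = TRUE))^2)
        if (min(d2) < 0.8^2) next
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(pts)
  }
  stop("failed to grow a compact chain of length ", L)
}

#' Random symmetric contact-potential table
#'
#' Entries are the symmetrized average of i.i.d. N(-2.5, 0.8) draws --
#' mildly attractive on average, on the scale of knowledge-based contact
#' potentials. Used by the test suite so correctness never depends on the
#' packaged table.
#'
#' @param rng_seed Integer seed.
#' @param mean,sd Entry distribution parameters.
#' @return A [contact_potentials()].
#' @export
random_potentials <- function(rng_seed = 1L, mean = -2.5, sd = 0.8) {
  eps <- withr::with_seed(rng_seed, {
    a <- matrix(stats::rnorm(400, mean, sd), 20, 20)
    (a + t(a)) / 2
  })
  contact_potentials(eps, label = sprintf("random(seed=%d)", rng_seed))
}

#' Reference mutation-parameter sets of the three study proteins
#'
#' The (kappa, pi_A, pi_C, pi_G, pi_T) values reported for the 1qhw, 1pek and
#' 2ppn proteins, kept verbatim, plus a normalized variant of each frequency
#' quadruple. The reported 1pek frequencies sum to 1.31 -- preserved as
#' reported, with `mutation` built from the normalized variant.
#'
#' @return Named list (per protein) with `kappa`, `pi_reported`,
#'   `pi_normalized`, `mutation` ([mutation_params()]), `length_aa`,
#'   `contact_density`.
#' @export
study_fixtures <- function() {
  raw <- list(
    `1qhw` = list(kappa = 4.37, pi = c(0.21, 0.32, 0.28, 0.20),
                  length_aa = 300L, contact_density = 7.5),
    `2ppn` = list(kappa = 2.50, pi = c(0.27, 0.24, 0.29, 0.19),
                  length_aa = 107L, contact_density = 6.9),
    `1pek` = list(kappa = 0.90, pi = c(0.19, 0.35, 0.56, 0.21),
                  length_aa = 297L, contact_density = 8.4))
  lapply(raw, function(x) {
    pin <- stats::setNames(x$pi, NUC)
    list(kappa = x$kappa, pi_reported = pin,
         pi_normalized = pin / sum(pin),
         mutation = mutation_params(x$kappa, pin, normalize = TRUE),
         length_aa = x$length_aa, contact_density = x$contact_density)
  })
}
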