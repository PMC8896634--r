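## Shared fixtures: tiny structures, random potentials, and a small
## evolution context cached across test files (built once per session).

.fixture_env <- new.env(parent = emptyenv())

## A hand-built 6-residue structure with irregular coordinates.
tiny_structure <- function() {
  coords <- matrix(c(0, 0, 0,
                     3.8, 0, 0,
                     5.0, 3.5, 0,
                     2.0, 5.5, 1.0,
                     -1.5, 3.8, 2.0,
                     -2.0, 0.2, 4.0), ncol = 3, byrow = TRUE)
  protein_structure(coords, c("A", "G", "V", "D", "K", "F"),
                    source_id = "tiny")
}

## Toy PDB text: chain A has three residues (ALA, GLY, VAL), chain B one.
## Glycine has no CB on purpose; VAL has both CA and CB.
toy_pdb_lines <- function() {
  fmt <- function(serial, name, res, chain, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, res, chain, resno, x, y, z,
            substr(name, 1, 1))
  }
  c(fmt(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    fmt(2, "CA", "ALA", "A", 1, 1.0, 0.0, 0.0),
    fmt(3, "CB", "ALA", "A", 1, 1.5, 1.2, 0.0),
    fmt(4, "N",  "GLY", "A", 2, 2.5, 0.5, 1.0),
    fmt(5, "CA", "GLY", "A", 2, 3.5, 0.5, 1.5),
    fmt(6, "N",  "VAL", "A", 3, 5.0, 1.0, 2.0),
    fmt(7, "CA", "VAL", "A", 3, 6.0, 1.0, 2.5),
    fmt(8, "CB", "VAL", "A", 3, 6.5, 2.3, 3.0),
    fmt(9, "CA", "LEU", "B", 1, 20.0, 20.0, 20.0),
    fmt(10, "CB", "LEU", "B", 1, 21.0, 20.0, 20.0),
    "END")
}

## Small but nontrivial evolution context (L = 30, ~6 contacts/site,
## 20 decoys, random potentials, 1qhw mutation parameters).
small_ctx <- function(exponent = "reported") {
  key <- paste0("ctx_", exponent)
  if (is.null(.fixture_env[[key]])) {
    syn <- synthetic_structure(L = 30, target_density = 6, rng_seed = 42)
    dec <- generate_decoys(syn$map, n_decoys = 20, rng_seed = 43)
    .fixture_env[[key]] <- evol_context(
      syn$map, dec, random_potentials(44),
      study_fixtures()[["1qhw"]]$mutation, Ne = 100, exponent = exponent)
  }
  .fixture_env[[key]]
}

## Enumerable 2-site system: one native contact, a mixed decoy ensemble so
## fitness varies with the amino acid pair.
two_site_ctx <- function(Ne = 10, exponent = "detailed_balance") {
  nat <- contact_map(2, matrix(c(1, 2), 1), min_sep = 1)
  empty <- contact_map(2, matrix(integer(0), ncol = 2), min_sep = 1)
  dec <- structure(list(n_decoys = 3L, maps = list(nat, empty, empty),
                        L = 2L),
                   class = "decoy_set")
  evol_context(nat, dec, random_potentials(7),
               study_fixtures()[["1qhw"]]$mutation, Ne = Ne,
               exponent = exponent)
}

## An equilibrated small-system trajectory, cached (used by several files).
small_trajectory <- function() {
  if (is.null(.fixture_env$traj)) {
    ctx <- small_ctx()
    .fixture_env$traj <- withr::with_seed(7, {
      st <- equilibrate(ctx, burn_in = 150)
      simulate_trajectory(ctx, st, n_substitutions = 250)
    })
  }
  .fixture_env$traj
}
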