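## Folded-structure contact maps and unfolded-state decoy ensembles.
##
## A contact map is the only structural information the stability model sees:
## two residues interact iff their side-chain reference points (C-beta, or
## C-alpha for glycine) lie within a distance cutoff (default 7 Angstrom).

#' Construct a protein structure object
#'
#' Holds one representative 3D point per residue (C-beta, or C-alpha for
#' glycine) plus residue identities. Internal indexing is 0-based-free:
#' residues are numbered 1..L in sequence order; author numbering from a PDB
#' is kept as an attribute only.
#'
#' @param coords Numeric L x 3 matrix of coordinates in Angstrom.
#' @param residues Character vector of amino acid one-letter codes, length L.
#' @param source_id Free-text provenance label.
#' @param author_resno Optional integer vector of author residue numbers.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(coords, residues, source_id = "unknown",
                              author_resno = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(residues))
  if (nrow(coords) < 2) stop("a structure needs at least 2 residues")
  structure(list(L = nrow(coords), coords = coords,
                 residues = as.character(residues), source_id = source_id,
                 author_resno = author_resno),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", x$L, "residues, source", x$source_id, "\n")
  invisible(x)
}

## 3-letter -> 1-letter residue codes for the 20 standard amino acids.
.aa3to1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
             GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
             MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
             SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

#' Parse a PDB file or text into a protein structure
#'
#' Reads ATOM records of the first model for one chain and extracts one
#' representative point per residue: the C-beta atom, or C-alpha when the
#' residue is glycine. A non-glycine residue missing its C-beta is an error
#' rather than a silent C-alpha fallback, so malformed inputs surface.
#' Alternate locations other than "A"/blank are dropped.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB record lines.
#' @param chain Chain identifier (single letter). Default "A".
#' @return A [protein_structure()].
#' @export
parse_structure <- function(pdb, chain = "A") {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
  }
  pdbobj <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdbobj$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in PDB input")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ## Residues in order of first appearance (sequence order in the records).
  key <- paste(at$resno, at$insert %|NA|% "", sep = "_")
  res_keys <- unique(key)
  coords <- matrix(NA_real_, length(res_keys), 3)
  res1 <- character(length(res_keys))
  resno <- integer(length(res_keys))
  for (r in seq_along(res_keys)) {
    rows <- at[key == res_keys[r], , drop = FALSE]
    resnm <- rows$resid[1]
    code <- .aa3to1[resnm]
    if (is.na(code)) {
      stop("non-standard residue ", resnm, " at ", res_keys[r])
    }
    want <- if (code == "G") "CA" else "CB"
    hit <- which(rows$elety == want)
    if (length(hit) == 0 && code == "G") hit <- which(rows$elety == "CA")
    if (length(hit) == 0) {
      stop("residue ", resnm, " ", res_keys[r], " lacks a ", want, " atom")
    }
    coords[r, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
    res1[r] <- code
    resno[r] <- rows$resno[1]
  }
  protein_structure(coords, res1, source_id = paste0(path, ":", chain),
                    author_resno = resno)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Construct a contact map object
#'
#' @param L Number of residues.
#' @param pairs Two-column integer matrix of contacting pairs (any order;
#'   stored with i < j, duplicates removed, self-contacts forbidden).
#' @param cutoff,min_sep Provenance of the map (distance cutoff in Angstrom
#'   and minimum sequence separation), stored for reporting.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(L, pairs, cutoff = NA_real_, min_sep = NA_integer_) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    if (any(pairs < 1L) || any(pairs > L)) stop("pair index out of range")
    if (any(pairs[, 1] == pairs[, 2])) stop("self-contacts are not allowed")
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  structure(list(L = as.integer(L), pairs = pairs,
                 cutoff = cutoff, min_sep = min_sep),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map: L =", x$L, ",", nrow(x$pairs), "contacts (",
      format(contact_density(x), digits = 3), "per site )\n")
  invisible(x)
}

#' Build a contact map from a structure
#'
#' Residues x and y are in contact iff the Euclidean distance between their
#' representative points is at most `cutoff` and |x - y| >= `min_sep`.
#' `min_sep = 2` excludes backbone neighbors, whose contacts carry almost no
#' sequence information.
#'
#' @param structure A [protein_structure()].
#' @param cutoff Distance cutoff in Angstrom (default 7).
#' @param min_sep Minimum sequence separation (default 2).
#' @return A [contact_map()].
#' @export
build_contact_map <- function(structure, cutoff = 7.0, min_sep = 2L) {
  stopifnot(inherits(structure, "protein_structure"), cutoff > 0)
  d <- as.matrix(stats::dist(structure$coords))
  sep <- abs(row(d) - col(d))
  hit <- which(d <= cutoff & sep >= min_sep & upper.tri(d), arr.ind = TRUE)
  contact_map(structure$L, hit, cutoff = cutoff, min_sep = as.integer(min_sep))
}

#' Mean number of contacts per site
#'
#' @param map A [contact_map()].
#' @return (2 x number of contact pairs) / L.
#' @export
contact_density <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  2 * nrow(map$pairs) / map$L
}

#' Per-site contact counts
#' @param map A [contact_map()].
#' @return Integer vector of length L.
#' @export
contact_counts <- function(map) {
  tabulate(c(map$pairs[, 1], map$pairs[, 2]), nbins = map$L)
}

#' Generate a decoy contact-map ensemble for the unfolded state
#'
#' Each decoy is a random rewiring of the reference map with exactly the
#' reference's number of contacts. By default the contact pairs are
#' resampled uniformly (without replacement) from all residue pairs with
#' sequence separation >= `min_sep`. With `preserve_degree = TRUE` the
#' rewiring instead performs repeated double-edge swaps --
#' (a,b),(c,d) -> (a,d),(c,b) accepted when the new pairs are valid -- so
#' every site also keeps its native contact count. The ensemble stands in
#' for compact alternative conformations with matched density, from which
#' the unfolded-state energy distribution is estimated by moments.
#'
#' @param reference A [contact_map()] (its `min_sep` is reused; if absent, 2).
#' @param n_decoys Number of decoys (>= 2 so a variance is estimable).
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @param preserve_degree Also preserve per-site contact counts (default
#'   FALSE; see Details).
#' @param swaps_per_contact Attempted edge swaps per contact per decoy when
#'   `preserve_degree = TRUE` (default 10).
#' @details Degree-preserving decoys keep hub sites hubs in every
#'   alternative conformation, which narrows the gap between native and
#'   decoy energies and tightens the equilibrium stability distribution;
#'   uniform resampling gives a less constrained ensemble. Uniform
#'   resampling is the default.
#' @return An object of class `decoy_set`: list of `contact_map`s.
#' @export
generate_decoys <- function(reference, n_decoys = 55L, rng_seed = 1L,
                            preserve_degree = FALSE,
                            swaps_per_contact = 10L) {
  stopifnot(inherits(reference, "contact_map"), n_decoys >= 2)
  L <- reference$L
  min_sep <- if (is.na(reference$min_sep)) 2L else reference$min_sep
  C <- nrow(reference$pairs)
  if (C < 2) stop("reference map needs at least 2 contacts to rewire")
  elig <- which(abs(row(diag(L)) - col(diag(L))) >= min_sep &
                  upper.tri(diag(L)), arr.ind = TRUE)
  if (nrow(elig) < C) {
    stop("not enough eligible pairs to place ", C, " contacts")
  }
  maps <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_decoys), function(d) {
      pairs <- if (preserve_degree) {
        .edge_swap(reference$pairs, L, min_sep,
                   n_attempts = swaps_per_contact * C)
      } else {
        elig[sample.int(nrow(elig), C), , drop = FALSE]
      }
      contact_map(L, pairs, cutoff = reference$cutoff, min_sep = min_sep)
    })
  })
  structure(list(n_decoys = as.integer(n_decoys), maps = maps, L = L,
                 preserve_degree = preserve_degree),
            class = "decoy_set")
}

#' @noRd
.edge_swap <- function(pairs, L, min_sep, n_attempts) {
  key <- function(i, j) pmin(i, j) * (L + 1) + pmax(i, j)
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(pairs[, 1], pairs[, 2])) assign(as.character(k), TRUE, present)
  C <- nrow(pairs)
  picks <- matrix(sample.int(C, 2L * n_attempts, replace = TRUE),
                  ncol = 2L)
  flips <- stats::runif(n_attempts) < 0.5
  for (t in seq_len(n_attempts)) {
    e1 <- picks[t, 1]
    e2 <- picks[t, 2]
    if (e1 == e2) next
    a <- pairs[e1, 1]; b <- pairs[e1, 2]
    c <- pairs[e2, 1]; d <- pairs[e2, 2]
    ## two swap orientations: (a,d)+(c,b) or (a,c)+(b,d)
    if (flips[t]) { tmp <- c; c <- d; d <- tmp }
    if (a == d || c == b) next
    if (abs(a - d) < min_sep || abs(c - b) < min_sep) next
    k1 <- as.character(key(a, d)); k2 <- as.character(key(c, b))
    if (!is.null(present[[k1]]) || !is.null(present[[k2]]) || k1 == k2) next
    rm(list = c(as.character(key(a, b)), as.character(key(c, d))),
       envir = present)
    assign(k1, TRUE, present)
    assign(k2, TRUE, present)
    pairs[e1, ] <- c(min(a, d), max(a, d))
    pairs[e2, ] <- c(min(c, b), max(c, b))
  }
  pairs
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("decoy_set:", x$n_decoys, "decoys, L =", x$L, "\n")
  invisible(x)
}

#' Weighted contact number per site
#'
#' The standard inverse-square burial measure WCN_i = sum_{j != i} 1/d_ij^2
#' over representative-point distances in Angstrom.
#'
#' @param structure A [protein_structure()].
#' @return Numeric vector of length L.
#' @export
weighted_contact_number <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  d2 <- as.matrix(stats::dist(structure$coords))^2
  if (any(d2[upper.tri(d2)] == 0)) {
    stop("coincident residue coordinates: WCN undefined")
  }
  diag(d2) <- Inf
  unname(rowSums(1 / d2))
}

#' Write / read a contact map as 3-column TSV
#'
#' The header line records L, the cutoff and the minimum separation so a map
#' is self-describing.
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @export
write_contact_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# L=%d cutoff=%s min_sep=%s", map$L,
                     format(map$cutoff), format(map$min_sep)), con)
  writeLines("i\tj\tcontact", con)
  if (nrow(map$pairs) > 0) {
    utils::write.table(cbind(map$pairs, 1L), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "L=([0-9]+) cutoff=([^ ]+) min_sep=([^ ]+)", hdr))[[1]]
  if (length(m) != 4) stop("malformed contact-map header: ", hdr)
  tab <- utils::read.table(path, skip = 1, header = TRUE, sep = "\t")
  contact_map(as.integer(m[2]),
              as.matrix(tab[, 1:2]),
              cutoff = suppressWarnings(as.numeric(m[3])),
              min_sep = suppressWarnings(as.integer(m[4])))
}
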