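## Genetic-code lookup tables shared by the mutation and simulation machinery.
## Built once per session from Biostrings::GENETIC_CODE (standard code).

.stabevol_cache <- new.env(parent = emptyenv())

#' Fixed amino acid ordering used throughout the package
#'
#' All 20-vectors (fitness landscapes, propensities, potential tables) are
#' indexed in this alphabetical one-letter-code order.
#'
#' @return Character vector of the 20 amino acid one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

NUC <- c("A", "C", "G", "T")

## Transition partner of each nucleotide (A<->G, C<->T); index into NUC.
.ts_partner <- c(A = 3L, C = 4L, G = 1L, T = 2L)

#' @noRd
codon_tables <- function() {
  if (!is.null(.stabevol_cache$codon_tables)) {
    return(.stabevol_cache$codon_tables)
  }
  gc_tab <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_tab)
  sense <- all_codons[gc_tab != "*"]
  n <- length(sense)                      # 61 for the standard code
  aa <- aa_alphabet()
  codon_aa <- match(unname(gc_tab[sense]), aa)
  codon_index <- stats::setNames(seq_len(n), sense)

  ## Per-codon nucleotide indices (1..4), n x 3.
  codon_nuc <- t(vapply(strsplit(sense, ""), function(x) match(x, NUC),
                        integer(3)))

  ## Single-nucleotide neighbor tables: 9 neighbors per codon
  ## (3 positions x 3 alternative nucleotides). Stop-codon neighbors get
  ## nbr_codon = NA and are excluded from the substitution process.
  nbr_codon  <- matrix(NA_integer_, n, 9L)
  nbr_newnuc <- matrix(NA_integer_, n, 9L)
  nbr_is_ts  <- matrix(FALSE, n, 9L)
  nbr_aa     <- matrix(NA_integer_, n, 9L)
  nbr_syn    <- matrix(FALSE, n, 9L)
  for (c1 in seq_len(n)) {
    nucs <- codon_nuc[c1, ]
    k <- 0L
    for (pos in 1:3) {
      for (new in seq_len(4L)[-nucs[pos]]) {
        k <- k + 1L
        nn <- nucs
        nn[pos] <- new
        cod <- paste0(NUC[nn], collapse = "")
        idx <- codon_index[cod]
        nbr_newnuc[c1, k] <- new
        nbr_is_ts[c1, k] <- (.ts_partner[[NUC[nucs[pos]]]] == new)
        if (!is.na(idx)) {
          nbr_codon[c1, k] <- idx
          nbr_aa[c1, k] <- codon_aa[idx]
          nbr_syn[c1, k] <- codon_aa[idx] == codon_aa[c1]
        }
      }
    }
  }
  tabs <- list(codons = sense, n = n, codon_aa = codon_aa,
               codon_index = codon_index, codon_nuc = codon_nuc,
               nbr_codon = nbr_codon, nbr_newnuc = nbr_newnuc,
               nbr_is_ts = nbr_is_ts, nbr_aa = nbr_aa, nbr_syn = nbr_syn)
  .stabevol_cache$codon_tables <- tabs
  tabs
}

#' @noRd
aa_index <- function(x) {
  i <- match(x, aa_alphabet())
  if (anyNA(i)) {
    stop("unknown amino acid code(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i
}

#' Translate codon strings to amino acid one-letter codes
#'
#' @param codons Character vector of sense codons (e.g. "ATG").
#' @return Character vector of amino acids.
#' @export
translate_codons <- function(codons) {
  tabs <- codon_tables()
  idx <- tabs$codon_index[codons]
  if (anyNA(idx)) {
    stop("not a sense codon: ", paste(codons[is.na(idx)], collapse = ", "))
  }
  aa_alphabet()[tabs$codon_aa[idx]]
}
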