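## Pairwise contact potentials: the 20x20 symmetric energy table behind the
## folded- and unfolded-state energies. Any symmetric table can be supplied;
## the package ships a hydrophobicity-derived synthetic table on the scale of
## published knowledge-based contact potentials, and the test suite uses
## random symmetric tables so correctness never depends on shipped constants.

#' Construct a contact-potential table
#'
#' @param epsilon Symmetric numeric 20x20 matrix of pairwise contact energies
#'   (kT-scaled, negative = attractive), rows/cols in [aa_alphabet()] order.
#' @param label Free-text provenance label.
#' @return An object of class `contact_potentials`.
#' @export
contact_potentials <- function(epsilon, label = "custom") {
  epsilon <- as.matrix(epsilon)
  stopifnot(nrow(epsilon) == 20, ncol(epsilon) == 20)
  if (!all(is.finite(epsilon))) stop("potential entries must be finite")
  if (max(abs(epsilon - t(epsilon))) > 1e-9) {
    stop("potential table must be symmetric")
  }
  dimnames(epsilon) <- list(aa_alphabet(), aa_alphabet())
  structure(list(epsilon = epsilon, aa_order = aa_alphabet(), label = label),
            class = "contact_potentials")
}

#' @export
print.contact_potentials <- function(x, ...) {
  cat("contact_potentials (", x$label, "): mean ",
      format(mean(x$epsilon), digits = 3), ", range [",
      format(min(x$epsilon), digits = 3), ", ",
      format(max(x$epsilon), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Read / write a potential table as TSV
#'
#' Format: a `#`-comment header, then a header line with the amino acid
#' order, then 20 rows of 20 floats (row label first).
#'
#' @param path File path.
#' @export
read_potentials <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           comment.char = "#", check.names = FALSE)
  if (!identical(rownames(tab), aa_alphabet()) ||
      !identical(colnames(tab), aa_alphabet())) {
    tab <- tab[aa_alphabet(), aa_alphabet()]
  }
  contact_potentials(as.matrix(tab), label = basename(path))
}

#' @rdname read_potentials
#' @param pot A [contact_potentials()].
#' @export
write_potentials <- function(pot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# contact potentials (", pot$label,
                    "); aa order: ", paste(pot$aa_order, collapse = "")), con)
  utils::write.table(
    cbind(aa = rownames(pot$epsilon), as.data.frame(pot$epsilon)),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged synthetic contact-potential table
#'
#' A deterministic hydrophobicity-derived table in the style (sign, scale and
#' hydrophobic-clustering pattern) of knowledge-based contact potentials:
#' with h the Kyte-Doolittle index rescaled to [0, 1],
#' epsilon(a, b) = -(0.5 + 3.0 h_a h_b + 0.8 (h_a + h_b)).
#' It is synthetic: the values are generated by this formula, not taken from
#' any published table.
#'
#' @return A [contact_potentials()].
#' @export
default_potentials <- function() {
  path <- system.file("extdata", "contact_potentials_synthetic.tsv",
                      package = "stabevol")
  if (nzchar(path)) return(read_potentials(path))
  synthetic_mj_style_potentials()
}

#' @rdname default_potentials
#' @export
synthetic_mj_style_potentials <- function() {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  h <- (kd[aa_alphabet()] + 4.5) / 9
  eps <- -(0.5 + 3.0 * outer(h, h) + 0.8 * outer(h, h, `+`))
  contact_potentials(round(eps, 4), label = "synthetic hydrophobicity-derived")
}
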