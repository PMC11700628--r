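# Residue formulas: amino-acid residues (monomer minus water), columns C,H,N,O,S.
.RESIDUE_FORMULA <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

#' Elemental formula of a (modified) tryptic peptide
#'
#' Sums residue formulas plus one water for the neutral peptide.
#' Carbamidomethylation of cysteine (+C2H3NO per C) is applied as a static
#' modification by default; methionine oxidation (+O) is applied to
#' `oxidized_met` methionines when requested, matching the common search
#' configuration (carbamidomethyl-C static, oxidation-M dynamic).
#'
#' @param sequence Peptide string over the 20 standard amino acids
#'   (one-letter, uppercase).
#' @param oxidized_met Number of oxidized methionines in this peptide
#'   instance (default 0); must not exceed the number of M residues.
#' @param carbamidomethyl Apply the static cysteine modification (default TRUE).
#' @return Named numeric vector with atom counts for C, H, N, O, S.
#' @examples
#' peptide_formula("GG")  # C4 H8 N2 O3
#' @export
peptide_formula <- function(sequence, oxidized_met = 0L, carbamidomethyl = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% rownames(.RESIDUE_FORMULA))
  if (length(bad))
    stop("invalid residue '", aa[bad[1]], "' at position ", bad[1],
         " in peptide ", sequence)
  counts <- colSums(.RESIDUE_FORMULA[aa, , drop = FALSE])
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + H2O
  if (carbamidomethyl) {
    ncys <- sum(aa == "C")
    counts <- counts + ncys * c(C = 2, H = 3, N = 1, O = 1, S = 0)
  }
  oxidized_met <- as.integer(oxidized_met)
  if (oxidized_met < 0 || oxidized_met > sum(aa == "M"))
    stop("oxidized_met must be between 0 and the number of methionines")
  counts["O"] <- counts["O"] + oxidized_met
  counts
}

#' Monoisotopic neutral mass of a formula
#'
#' @param formula Named atom-count vector as returned by [peptide_formula()].
#' @param elements An [element_table()].
#' @return Monoisotopic neutral mass in Da.
#' @export
formula_mass <- function(formula, elements = element_table()) {
  els <- intersect(names(formula), names(elements$isotopes))
  sum(vapply(els, function(el) formula[[el]] * elements$isotopes[[el]]$mass[1],
             numeric(1)))
}
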