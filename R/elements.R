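#' @keywords internal
".PROTON_MASS" <- 1.007276466

# Isotope masses (Da) and natural abundances; standard reference values,
# overridable through element_table(isotopes = ...).
.ISOTOPES <- list(
  C = list(mass = c(12, 13.0033548378),
           abundance = c(0.9893, 0.0107),
           offset = c(0L, 1L)),
  H = list(mass = c(1.0078250319, 2.0141017779),
           abundance = c(0.999885, 0.000115),
           offset = c(0L, 1L)),
  N = list(mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99636, 0.00364),
           offset = c(0L, 1L)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205),
           offset = c(0L, 1L, 2L)),
  S = list(mass = c(31.97207069, 32.9714585, 33.96786683, 35.96708088),
           abundance = c(0.9493, 0.0076, 0.0429, 0.0002),
           offset = c(0L, 1L, 2L, 4L))
)

#' Elemental isotope table for isotopologue modeling
#'
#' Bundles isotope masses and natural abundances for C, H, N, O and S together
#' with the identity of the label element used in a stable-isotope-probing
#' experiment (one of 13C, 2H, 18O). The heaviest isotope of the label element
#' is the one whose abundance is raised to the relative isotope abundance (RIA)
#' in labeled peptides; its natural abundance is the "natural RIA" baseline
#' below which a peptide counts as unlabeled.
#'
#' @param label_element One of `"C"`, `"H"`, `"O"`: the element carrying the
#'   isotope label (13C, 2H or 18O respectively).
#' @param isotopes Named list of per-element isotope definitions, each a list
#'   with numeric `mass` (strictly increasing, Da), `abundance` (summing to 1)
#'   and integer `offset` (nominal mass offsets relative to the lightest
#'   isotope). Defaults to standard reference values.
#' @return An object of class `element_table`: a list with the isotope
#'   definitions plus `label_element`, `natural_ria` (natural abundance of the
#'   heavy label isotope), `label_offset` (its nominal offset),
#'   `label_mass_shift` (Da) and `offset_spacing` (Da per nominal offset unit
#'   on the neutral-mass axis for this label).
#' @examples
#' et <- element_table("C")
#' et$natural_ria  # 0.0107
#' @export
element_table <- function(label_element = c("C", "H", "O"), isotopes = .ISOTOPES) {
  label_element <- match.arg(label_element)
  for (el in names(isotopes)) {
    iso <- isotopes[[el]]
    if (abs(sum(iso$abundance) - 1) > 1e-9)
      stop("abundances for element ", el, " do not sum to 1")
    if (is.unsorted(iso$mass, strictly = TRUE))
      stop("isotope masses for element ", el, " must be strictly increasing")
    if (any(iso$abundance < 0))
      stop("negative abundance for element ", el)
  }
  iso <- isotopes[[label_element]]
  hi <- length(iso$mass)
  structure(list(
    isotopes = isotopes,
    label_element = label_element,
    natural_ria = iso$abundance[hi],
    label_offset = iso$offset[hi],
    label_mass_shift = iso$mass[hi] - iso$mass[1],
    offset_spacing = (iso$mass[hi] - iso$mass[1]) / iso$offset[hi]
  ), class = "element_table")
}

#' @export
print.element_table <- function(x, ...) {
  cat("<element_table> label:", x$label_element,
      sprintf("(natural RIA %.6f, +%.5f Da)\n", x$natural_ria, x$label_mass_shift))
  invisible(x)
}
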