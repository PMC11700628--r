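# Theoretical isotopologue distributions over nominal mass offsets.
#
# Per-element distributions: binomial (stats::dbinom) for two-isotope elements,
# convolution powers of the single-atom distribution otherwise; elements are
# combined by linear convolution. Distributions are truncated so the retained
# mass fraction is at least 1 - tail (default 0.999) and renormalized.

.conv <- function(a, b) {
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b)) {
    idx <- j:(j + length(a) - 1L)
    out[idx] <- out[idx] + b[j] * a
  }
  out
}

# drop leading/trailing mass up to tail/2 on each side
.trim <- function(start, dens, tail) {
  if (tail <= 0) {
    keep <- which(dens > 0)
    if (!length(keep)) return(list(start = start, dens = dens))
    i1 <- keep[1]; i2 <- keep[length(keep)]
    return(list(start = start + i1 - 1L, dens = dens[i1:i2]))
  }
  cl <- cumsum(dens)
  cr <- rev(cumsum(rev(dens)))
  i1 <- max(1L, which(cl > tail / 2)[1])
  i2 <- min(length(dens), length(dens) + 1L - which(rev(cr > tail / 2))[1])
  if (is.na(i1)) i1 <- 1L
  if (is.na(i2) || i2 < i1) i2 <- i1
  list(start = start + i1 - 1L, dens = dens[i1:i2])
}

# single-atom offset distribution for an element, optionally with the heaviest
# isotope forced to `ria` (lighter isotopes scaled proportionally)
.elem_single <- function(iso, ria = NULL) {
  ab <- iso$abundance
  if (!is.null(ria)) {
    hi <- length(ab)
    light <- ab[-hi] / sum(ab[-hi])
    ab <- c(light * (1 - ria), ria)
  }
  dens <- numeric(max(iso$offset) + 1L)
  dens[iso$offset + 1L] <- ab
  dens
}

# distribution of the summed offset of n atoms of one element
.elem_dist <- function(n, single, tail) {
  if (n == 0L) return(list(start = 0L, dens = 1))
  if (length(single) == 2L) {
    dens <- stats::dbinom(0:n, n, single[2])
    return(.trim(0L, dens, tail))
  }
  # convolution power by squaring (small n: multi-isotope elements O, S)
  res <- NULL
  base <- single
  m <- n
  while (m > 0L) {
    if (m %% 2L == 1L) res <- if (is.null(res)) base else .conv(res, base)
    m <- m %/% 2L
    if (m > 0L) base <- .conv(base, base)
  }
  .trim(0L, res, tail)
}

.pattern_assemble <- function(dists, mono_mass, tail) {
  start <- 0L
  dens <- 1
  for (d in dists) {
    start <- start + d$start
    dens <- .conv(dens, d$dens)
  }
  tr <- .trim(start, dens, tail)
  dens <- tr$dens / sum(tr$dens)
  structure(list(offset = tr$start + seq_along(dens) - 1L,
                 intensity = dens,
                 mono_mass = mono_mass),
            class = "isotope_pattern")
}

.isotope_pattern <- function(formula, elements, ria = NULL, tail = 1e-3) {
  els <- names(formula)[formula > 0]
  unknown <- setdiff(els, names(elements$isotopes))
  if (length(unknown))
    stop("no isotope definition for element(s): ", paste(unknown, collapse = ", "))
  etail <- tail * 1e-9
  dists <- lapply(els, function(el) {
    r <- if (!is.null(ria) && el == elements$label_element) ria else NULL
    .elem_dist(as.integer(formula[[el]]), .elem_single(elements$isotopes[[el]], r), etail)
  })
  .pattern_assemble(dists, formula_mass(formula, elements), tail)
}

#' Natural isotopologue distribution of a formula
#'
#' Convolution of per-element isotope distributions at natural abundance,
#' expressed as intensity fractions over nominal mass offsets from the
#' monoisotopic peak.
#'
#' @param formula Named atom-count vector (see [peptide_formula()]).
#' @param elements An [element_table()].
#' @param tail Discarded mass fraction; the retained fraction is
#'   at least `1 - tail` (default 0.999) before renormalization.
#' @return An `isotope_pattern`: list with integer `offset`, `intensity`
#'   (non-negative, summing to 1) and `mono_mass` (Da).
#' @examples
#' natural_pattern(c(C = 1))$intensity  # ~ c(0.9893, 0.0107)
#' @export
natural_pattern <- function(formula, elements = element_table(), tail = 1e-3) {
  .isotope_pattern(formula, elements, ria = NULL, tail = tail)
}

#' Label-substituted isotopologue distribution
#'
#' Identical to [natural_pattern()] except that the heavy isotope of the label
#' element (13C, 2H or 18O depending on the element table) is set to the given
#' relative isotope abundance (RIA).
#'
#' @inheritParams natural_pattern
#' @param ria Heavy-isotope abundance of the label element, a fraction in
#'   `[natural, 1]`.
#' @return An `isotope_pattern`.
#' @examples
#' labeled_pattern(c(C = 2), element_table("C"), ria = 0.5)$intensity  # 1/4,1/2,1/4
#' @export
labeled_pattern <- function(formula, elements = element_table(), ria, tail = 1e-3) {
  if (ria < elements$natural_ria - 1e-12 || ria > 1)
    stop("ria must lie between the natural abundance (",
         signif(elements$natural_ria, 4), ") and 1")
  .isotope_pattern(formula, elements, ria = ria, tail = tail)
}

#' Intensity-weighted mean nominal offset of a pattern
#' @param pattern An `isotope_pattern`.
#' @return Mean offset (label-isotope units above monoisotopic).
#' @export
pattern_mean_offset <- function(pattern) {
  sum(pattern$offset * pattern$intensity)
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("<isotope_pattern> mono %.4f Da, offsets %d..%d (%d peaks)\n",
              x$mono_mass, min(x$offset), max(x$offset), length(x$offset)))
  invisible(x)
}
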