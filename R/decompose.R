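# Decomposition of observed MS1 isotope envelopes into an unlabeled component
# plus zero or more label-substituted components, yielding per-peptide RIA and
# labeling ratio (LR).

#' Decomposition settings
#'
#' @param grid_step RIA grid resolution for the template scan (fraction,
#'   default 0.005 = 0.5%).
#' @param min_correlation Minimum Pearson correlation between a template and
#'   the (residual) envelope for a component to be accepted (default 0.7).
#' @param ppm_tol Peak-to-offset assignment tolerance in ppm (default 5).
#' @param merge_window Components whose template centroid masses lie closer
#'   than this window (Da, neutral-mass axis) are merged. `NULL` (default)
#'   selects 1.5 Da for a 2H label and 5.0 Da for 13C/18O.
#' @param refine Refine accepted grid maxima by local correlation
#'   maximization within one grid step (default TRUE).
#' @param tail Pattern truncation mass fraction (see [natural_pattern()]).
#' @return A list of class `decompose_config`.
#' @export
decompose_config <- function(grid_step = 0.005, min_correlation = 0.7,
                             ppm_tol = 5, merge_window = NULL,
                             refine = TRUE, tail = 1e-3) {
  stopifnot(grid_step > 0, grid_step < 1, min_correlation > 0,
            min_correlation <= 1, ppm_tol > 0)
  structure(list(grid_step = grid_step, min_correlation = min_correlation,
                 ppm_tol = ppm_tol, merge_window = merge_window,
                 refine = refine, tail = tail),
            class = "decompose_config")
}

.merge_window_for <- function(elements, config) {
  if (!is.null(config$merge_window)) return(config$merge_window)
  if (elements$label_element == "H") 1.5 else 5.0
}

# Pearson correlation without stats::cor's zero-variance warning
.safe_cor <- function(a, b) {
  if (length(a) < 2L) return(NA_real_)
  va <- a - mean(a); vb <- b - mean(b)
  da <- sqrt(sum(va^2)); db <- sqrt(sum(vb^2))
  if (da == 0 || db == 0) return(NA_real_)
  sum(va * vb) / (da * db)
}

.empty_components <- function(flag, total_intensity) {
  structure(list(
    components = data.frame(ria = numeric(0), weight = numeric(0),
                            correlation = numeric(0), centroid_mass = numeric(0)),
    lr = NA_real_, flag = flag, total_intensity = total_intensity,
    n_unassigned = 0L), class = "sip_components")
}

#' Decompose an observed isotope envelope into unlabeled + labeled components
#'
#' Peaks are deconvoluted to the neutral-mass axis using the stated charge and
#' assigned to nominal offsets from the theoretical monoisotopic mass within a
#' ppm tolerance. The unlabeled (natural-abundance) template must correlate
#' with the envelope over its own support; without this unlabeled anchor no
#' components are reported (flag `"no_unlabeled_anchor"`), mirroring the
#' behavior that isotope-incorporation detection requires the presence of
#' unlabeled peptides. An RIA grid (natural to 1) is then scanned: at each
#' grid point the label-substituted template is correlated against the
#' envelope residual after removing the fitted unlabeled component; local
#' correlation maxima above `min_correlation` become candidate components,
#' optionally refined by local maximization. Candidates whose template
#' centroid masses fall within the label-specific merge window of an accepted
#' component are merged. Final component weights are solved by non-negative
#' least squares of the accepted templates against the envelope.
#'
#' @param envelope Data frame with numeric columns `mz` (strictly increasing)
#'   and `intensity` (non-negative), and optionally a constant `charge`
#'   column.
#' @param formula Elemental formula of the neutral peptide
#'   (see [peptide_formula()]).
#' @param elements An [element_table()] naming the label element.
#' @param config A [decompose_config()].
#' @param charge Precursor charge; overridden by an envelope `charge` column.
#' @return An object of class `sip_components`: list with `components`
#'   (data frame of `ria`, `weight`, `correlation`, `centroid_mass`; the
#'   unlabeled component first, weights summing to 1), `lr` (sum of labeled
#'   weights), `flag` (zero-length or `"no_unlabeled_anchor"`),
#'   `total_intensity` and `n_unassigned`.
#' @export
decompose_envelope <- function(envelope, formula, elements = element_table(),
                               config = decompose_config(), charge = 1L) {
  stopifnot(is.data.frame(envelope), all(c("mz", "intensity") %in% names(envelope)))
  if (nrow(envelope) < 2L) stop("envelope must contain at least 2 peaks")
  if (is.unsorted(envelope$mz, strictly = TRUE)) stop("envelope m/z must be strictly increasing")
  if (any(envelope$intensity < 0)) stop("envelope intensities must be non-negative")
  if ("charge" %in% names(envelope)) charge <- envelope$charge[1]
  z <- as.integer(charge)
  stopifnot(z >= 1L)

  total_int <- sum(envelope$intensity)
  mono <- formula_mass(formula, elements)
  spacing <- elements$offset_spacing
  neutral <- (envelope$mz - .PROTON_MASS) * z

  # peak -> offset assignment within ppm tolerance
  k <- round((neutral - mono) / spacing)
  err <- abs(neutral - (mono + k * spacing))
  ok <- k >= 0 & err <= config$ppm_tol * 1e-6 * neutral
  n_unassigned <- sum(!ok)
  if (n_unassigned > 0)
    warning(n_unassigned, " envelope peak(s) beyond ppm tolerance ignored")
  k <- k[ok]
  if (!length(k)) {
    out <- .empty_components("no_unlabeled_anchor", total_int)
    out$n_unassigned <- n_unassigned
    return(out)
  }
  kmax <- max(k)
  y <- numeric(kmax + 1L)
  # multiple peaks on one offset (should not happen on clean data) are summed
  for (i in seq_along(k)) y[k[i] + 1L] <- y[k[i] + 1L] + envelope$intensity[ok][i]

  y_at <- function(off) ifelse(off <= kmax, y[pmin(off, kmax) + 1L], 0)

  nat <- elements$natural_ria
  label_el <- elements$label_element
  n_label <- if (label_el %in% names(formula)) as.integer(formula[[label_el]]) else 0L

  # background: all elements except the label element, at natural abundance
  bg_formula <- formula[names(formula) != label_el]
  etail <- config$tail * 1e-9
  bg <- list(start = 0L, dens = 1)
  for (el in names(bg_formula)[bg_formula > 0]) {
    d <- .elem_dist(as.integer(bg_formula[[el]]),
                    .elem_single(elements$isotopes[[el]]), etail)
    bg <- list(start = bg$start + d$start, dens = .conv(bg$dens, d$dens))
  }
  label_iso <- elements$isotopes[[label_el]]
  template <- function(ria) {
    d <- .elem_dist(n_label, .elem_single(label_iso, ria), etail)
    .pattern_assemble(list(bg, d), mono, config$tail)
  }

  # --- unlabeled anchor ---
  t0 <- template(nat)
  r0 <- .safe_cor(t0$intensity, y_at(t0$offset))
  if (is.na(r0) || r0 < config$min_correlation) {
    out <- .empty_components("no_unlabeled_anchor", total_int)
    out$n_unassigned <- n_unassigned
    return(out)
  }
  y0 <- y_at(t0$offset)
  w0 <- max(0, sum(y0 * t0$intensity) / sum(t0$intensity^2))
  resid <- y
  idx0 <- t0$offset + 1L
  in0 <- idx0 <= length(resid)
  resid[idx0[in0]] <- pmax(0, resid[idx0[in0]] - w0 * t0$intensity[in0])
  r_at <- function(off) ifelse(off <= kmax, resid[pmin(off, kmax) + 1L], 0)

  corr_at <- function(ria) {
    tt <- template(ria)
    .safe_cor(tt$intensity, r_at(tt$offset))
  }

  comps <- data.frame(ria = nat, correlation = r0,
                      centroid_mass = mono + pattern_mean_offset(t0) * spacing)

  if (n_label > 0L) {
    grid <- seq(nat + config$grid_step, 1, by = config$grid_step)
    if (length(grid)) {
      prof <- vapply(grid, corr_at, numeric(1))
      pv <- ifelse(is.na(prof), -Inf, prof)
      npts <- length(pv)
      is_max <- pv >= config$min_correlation &
        pv >= c(-Inf, pv[-npts]) & pv >= c(pv[-1], -Inf)
      cand <- which(is_max)
      if (length(cand)) {
        cand <- cand[order(pv[cand], decreasing = TRUE)]
        merge_win <- .merge_window_for(elements, config)
        for (i in cand) {
          ria_i <- grid[i]
          corr_i <- prof[i]
          if (isTRUE(config$refine)) {
            lo <- max(nat + 1e-9, ria_i - config$grid_step)
            hi <- min(1, ria_i + config$grid_step)
            opt <- stats::optimize(function(r) {
              v <- corr_at(r); if (is.na(v)) -Inf else v
            }, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
            if (is.finite(opt$objective) && opt$objective >= corr_i) {
              ria_i <- opt$maximum
              corr_i <- opt$objective
            }
          }
          tt <- template(ria_i)
          cm <- mono + pattern_mean_offset(tt) * spacing
          if (all(abs(cm - comps$centroid_mass) > merge_win)) {
            comps <- rbind(comps, data.frame(ria = ria_i, correlation = corr_i,
                                             centroid_mass = cm))
          }
        }
      }
    }
  }

  # --- weights by non-negative least squares ---
  templates <- lapply(comps$ria, template)
  design <- function(templates) {
    L <- max(kmax + 1L, max(vapply(templates, function(t) max(t$offset) + 1L, integer(1))))
    A <- matrix(0, nrow = L, ncol = length(templates))
    for (j in seq_along(templates)) {
      tj <- templates[[j]]
      A[tj$offset + 1L, j] <- tj$intensity
    }
    A
  }
  solve_w <- function(A, b) {
    if (ncol(A) == 1L) max(0, sum(A[, 1] * b) / sum(A[, 1]^2))
    else pracma::lsqnonneg(A, b)$x
  }
  A <- design(templates)
  b <- c(y, numeric(nrow(A) - length(y)))
  w <- solve_w(A, b)

  # re-refine each labeled component's RIA against the residual of the other
  # fitted components, then re-solve: removes the bias from the anchor-only
  # residual when labeled and natural patterns overlap
  if (isTRUE(config$refine) && nrow(comps) > 1L) {
    for (it in 1:2) {
      for (j in 2:nrow(comps)) {
        resid_j <- as.vector(b - A[, -j, drop = FALSE] %*% w[-j])
        res_at <- function(off) ifelse(off + 1L <= length(resid_j),
                                       resid_j[pmin(off, length(resid_j) - 1L) + 1L], 0)
        lo <- max(nat + 1e-9, comps$ria[j] - config$grid_step)
        hi <- min(1, comps$ria[j] + config$grid_step)
        opt <- stats::optimize(function(r) {
          tt <- template(r)
          v <- .safe_cor(tt$intensity, res_at(tt$offset))
          if (is.na(v)) -Inf else v
        }, interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
        if (is.finite(opt$objective)) {
          comps$ria[j] <- opt$maximum
          comps$correlation[j] <- opt$objective
          templates[[j]] <- template(opt$maximum)
          comps$centroid_mass[j] <- mono + pattern_mean_offset(templates[[j]]) * spacing
        }
      }
      A <- design(templates)
      b <- c(y, numeric(nrow(A) - length(y)))
      w <- solve_w(A, b)
    }
  }
  keep <- w > 1e-12 * max(w) | seq_along(w) == 1L  # always keep the anchor
  comps <- comps[keep, , drop = FALSE]
  w <- w[keep]
  w <- w / sum(w)
  comps$weight <- w
  comps <- comps[, c("ria", "weight", "correlation", "centroid_mass")]
  rownames(comps) <- NULL

  lr <- sum(w[comps$ria > nat + 1e-9])
  structure(list(components = comps, lr = lr, flag = character(0),
                 total_intensity = total_int, n_unassigned = n_unassigned),
            class = "sip_components")
}

#' Labeling ratio of a decomposition
#'
#' LR = sum of labeled component weights over the sum of all weights: the
#' abundance of the labeled version of a peptide among the labeled plus
#' unlabeled versions.
#'
#' @param components A `sip_components` object from [decompose_envelope()].
#' @param natural Natural heavy-isotope abundance separating labeled from
#'   unlabeled components.
#' @return LR in `[0, 1]`, or `NA` when no components were accepted.
#' @export
labeling_ratio <- function(components, natural = element_table()$natural_ria) {
  cmp <- components$components
  if (is.null(cmp) || nrow(cmp) == 0L) return(NA_real_)
  sum(cmp$weight[cmp$ria > natural + 1e-9]) / sum(cmp$weight)
}

#' Is a decomposed peptide isotopically labeled?
#'
#' TRUE iff at least one accepted component has an RIA beyond the natural
#' abundance; peptides without an unlabeled anchor are not reported and are
#' therefore not labeled.
#'
#' @inheritParams labeling_ratio
#' @return Logical flag.
#' @export
is_labeled <- function(components, natural = element_table()$natural_ria) {
  cmp <- components$components
  if (is.null(cmp) || nrow(cmp) == 0L) return(FALSE)
  any(cmp$ria > natural + 1e-9)
}

#' @export
print.sip_components <- function(x, ...) {
  if (length(x$flag)) {
    cat("<sip_components> flagged:", x$flag, "\n")
  } else {
    cat(sprintf("<sip_components> %d component(s), LR = %.4f\n",
                nrow(x$components), x$lr))
    print(x$components, digits = 4)
  }
  invisible(x)
}
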