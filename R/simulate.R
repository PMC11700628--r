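# Ground-truthed synthetic fixtures: mini GroEL references with planned
# peptide sharing, community mixtures with controlled labeling, and isotope
# envelopes with a configurable noise model.
#
# Pattern construction here is deliberately independent of the convolution
# code in the isotope model: per-element distributions are built by exact
# enumeration over isotopologue compositions (heavy-atom count vectors with
# multinomial log-weights) and elements are combined by outer-sum
# aggregation, so round-trip tests are non-circular.

.sim_elem_dist <- function(n, iso, ria = NULL) {
  ab <- iso$abundance
  if (!is.null(ria)) {
    hi <- length(ab)
    light <- ab[-hi] / sum(ab[-hi])
    ab <- c(light * (1 - ria), ria)
  }
  off <- iso$offset
  m <- length(ab)
  if (n == 0L) return(c(`0` = 1))
  # enumerate counts of the m-1 heavier isotopes (k2..km), rest is lightest
  heavy <- as.matrix(do.call(expand.grid, rep(list(0:n), m - 1L)))
  keep <- rowSums(heavy) <= n
  heavy <- heavy[keep, , drop = FALSE]
  k1 <- n - rowSums(heavy)
  counts <- cbind(k1, heavy)
  logab <- ifelse(ab > 0, log(ab), -Inf)
  logw <- lfactorial(n) - rowSums(lfactorial(counts)) +
    as.vector(counts %*% ifelse(is.finite(logab), logab, 0))
  logw[apply(counts[, ab == 0, drop = FALSE] > 0, 1, any)] <- -Inf
  w <- exp(logw)
  offs <- as.vector(counts %*% off)
  agg <- rowsum(w, offs)
  stats::setNames(as.vector(agg), rownames(agg))
}

.sim_combine <- function(d1, d2) {
  o1 <- as.integer(names(d1)); o2 <- as.integer(names(d2))
  w <- outer(unname(d1), unname(d2))
  o <- outer(o1, o2, "+")
  agg <- rowsum(as.vector(w), as.vector(o))
  stats::setNames(as.vector(agg), rownames(agg))
}

# enumeration-based isotope pattern; same truncation convention as the
# forward model (retained mass >= 1 - tail, then renormalized)
.sim_pattern <- function(formula, elements, ria = NULL, tail = 1e-3) {
  els <- names(formula)[formula > 0]
  dist <- c(`0` = 1)
  for (el in els) {
    r <- if (!is.null(ria) && el == elements$label_element) ria else NULL
    d <- .sim_elem_dist(as.integer(formula[[el]]), elements$isotopes[[el]], r)
    d <- d[d > 1e-14]
    dist <- .sim_combine(dist, d)
  }
  offs <- as.integer(names(dist))
  o <- order(offs)
  dens <- unname(dist[o]); offs <- offs[o]
  # contiguous support
  full <- numeric(max(offs) - min(offs) + 1L)
  full[offs - min(offs) + 1L] <- dens
  tr <- .trim(min(offs), full, tail)
  dens <- tr$dens / sum(tr$dens)
  structure(list(offset = tr$start + seq_along(dens) - 1L,
                 intensity = dens,
                 mono_mass = formula_mass(formula, elements)),
            class = "isotope_pattern")
}

#' Label specification for alpha-13C-benzoate growth
#'
#' Benzoate carries seven carbons; when the alpha (carboxyl) carbon is 13C
#' and all biomass carbon derives from benzoate, the expected 13C fraction of
#' biomass carbon is `n_labeled / n_carbons` (1/7 = 14.3% for the standard
#' substrate), floored at the natural 13C abundance (an unlabeled substrate
#' leaves the peptide at natural RIA).
#'
#' @param n_labeled Number of 13C positions in the substrate (default 1).
#' @param n_carbons Number of carbons in the substrate (default 7).
#' @param elements An [element_table()] with a carbon label.
#' @return List with `label_element` ("C") and `ria` (fraction).
#' @examples
#' round(100 * benzoate_label_spec()$ria, 1)  # 14.3
#' @export
benzoate_label_spec <- function(n_labeled = 1L, n_carbons = 7L,
                                elements = element_table("C")) {
  stopifnot(n_labeled >= 0, n_carbons >= 1, n_labeled <= n_carbons)
  list(label_element = "C",
       ria = max(n_labeled / n_carbons, elements$natural_ria))
}

.AA_POOL <- strsplit("ADEFGHLMNQSTVWY", "")[[1]]  # no K/R/P (cleavage control), no I/C/X

.random_block <- function(len) {
  paste0(paste(sample(.AA_POOL, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a mini GroEL-like reference with planned peptide sharing
#'
#' Builds `n_taxa` synthetic chaperonin-sized sequences (about 540 residues)
#' as concatenations of unique tryptic blocks (each block an 8-18 residue
#' peptide ending in K/R). Consecutive taxon pairs (1,2), (3,4), ... share
#' `round(overlap_fraction * blocks_per_taxon)` identical blocks, so the
#' shared-peptide fraction is known by construction. A ground-truth ledger
#' records every block peptide with the taxa carrying it.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param overlap_fraction Planned fraction of shared blocks within
#'   designated pairs, in `[0, 1)`.
#' @param seed Integer seed; fixes all randomness.
#' @param blocks_per_taxon Number of tryptic blocks per sequence (default 45).
#' @param dir Optional directory; when given, `reference.fasta` (synthetic
#'   sequences) and `taxonomy.tsv` are written there.
#' @return List with `entries` (a `groel_reference` data frame), `taxonomy`
#'   (data frame), `ledger` (data frame `peptide`, `taxa` list column) and,
#'   when written, `fasta_path` / `taxonomy_path`.
#' @export
make_reference <- function(n_taxa, overlap_fraction = 0, seed = 1L,
                           blocks_per_taxon = 45L, dir = NULL) {
  stopifnot(n_taxa >= 1)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  n_shared <- round(overlap_fraction * blocks_per_taxon)
  if (n_shared >= blocks_per_taxon)
    stop("infeasible overlap request")
  withr::local_seed(seed)

  seen <- new.env(parent = emptyenv())
  new_block <- function() {
    repeat {
      b <- .random_block(sample(8:18, 1L))
      if (is.null(seen[[b]])) { seen[[b]] <- TRUE; return(b) }
    }
  }
  blocks <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) blocks[[i]] <- replicate(blocks_per_taxon, new_block())
  # consecutive pairs share the first n_shared blocks of the odd member
  if (n_shared > 0 && n_taxa >= 2) {
    for (i in seq(1L, n_taxa - 1L, by = 2L)) {
      blocks[[i + 1L]][seq_len(n_shared)] <- blocks[[i]][seq_len(n_shared)]
    }
  }
  acc <- sprintf("SYN%03d", seq_len(n_taxa))
  genus <- sprintf("Genus%02d", seq_len(n_taxa))
  fam <- sprintf("Family%02d", ceiling(seq_len(n_taxa) / 2))
  taxonomy <- data.frame(
    accession = acc, superkingdom = "Bacteria", phylum = "Pseudomonadota",
    class = "Gammaproteobacteria", order = sprintf("Order%02d", ceiling(seq_len(n_taxa) / 2)),
    family = fam, genus = genus, species = paste(genus, "synthetica"),
    stringsAsFactors = FALSE)
  entries <- data.frame(
    accession = acc,
    organism = paste(genus, "synthetica"),
    sequence = vapply(blocks, paste, character(1), collapse = ""),
    stringsAsFactors = FALSE)
  entries$accessions <- as.list(acc)
  for (r in .RANKS) entries[[r]] <- taxonomy[[r]]
  class(entries) <- c("groel_reference", "data.frame")

  pep <- unlist(blocks, use.names = FALSE)
  tax_of <- rep(genus, lengths(blocks))
  ledger <- data.frame(peptide = unique(pep), stringsAsFactors = FALSE)
  ledger$taxa <- lapply(ledger$peptide, function(p) sort(unique(tax_of[pep == p])))

  out <- list(entries = entries, taxonomy = taxonomy, ledger = ledger)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta_path <- file.path(dir, "reference.fasta")
    seqs <- Biostrings::AAStringSet(entries$sequence)
    names(seqs) <- paste(entries$accession, entries$organism)
    Biostrings::writeXStringSet(seqs, fasta_path)
    taxonomy_path <- file.path(dir, "taxonomy.tsv")
    utils::write.table(taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$fasta_path <- fasta_path
    out$taxonomy_path <- taxonomy_path
  }
  out
}

#' Specification of a synthetic labeled community
#'
#' @param taxa Data frame with columns `accession` (entry in the reference),
#'   `abundance` (relative protein amounts, normalized to sum 1), `ria` (true
#'   heavy-isotope abundance in labeled molecules) and `labeled_share`
#'   (fraction of this taxon's molecules that are labeled, i.e. the product
#'   of the labeled fraction and the labeled:unlabeled extract mixing ratio;
#'   a 1:1 mix of fully labeled and unlabeled extract gives 0.5).
#' @param label_element `"C"`, `"H"` or `"O"`.
#' @param peptides_per_taxon Peptides sampled from each taxon's digest.
#' @param intensity_cv Multiplicative Gaussian noise CV on peak intensities
#'   (default 0.05).
#' @param mz_ppm Uniform m/z jitter half-width in ppm (default 2).
#' @param charges Charge states sampled per peptide (default 2:3).
#' @param seed Integer seed; fixes all randomness.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(taxa, label_element = "C", peptides_per_taxon = 30L,
                           intensity_cv = 0.05, mz_ppm = 2, charges = 2:3,
                           seed = 1L) {
  stopifnot(is.data.frame(taxa),
            all(c("accession", "abundance", "ria", "labeled_share") %in% names(taxa)),
            all(taxa$labeled_share >= 0 & taxa$labeled_share <= 1),
            all(taxa$abundance >= 0), sum(taxa$abundance) > 0)
  taxa$abundance <- taxa$abundance / sum(taxa$abundance)
  structure(list(taxa = taxa, label_element = label_element,
                 peptides_per_taxon = as.integer(peptides_per_taxon),
                 intensity_cv = intensity_cv, mz_ppm = mz_ppm,
                 charges = charges, seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate isotope envelopes for a labeled community
#'
#' For each taxon, peptides are sampled from its tryptic digest; each peptide
#' emits one envelope per replicate: a `labeled_share`-weighted sum of its
#' natural and label-substituted isotopologue patterns (built by the
#' enumeration oracle, not the forward-model convolution), scaled by taxon
#' abundance and a lognormal-like peptide intensity factor, with
#' multiplicative Gaussian intensity noise and uniform ppm m/z jitter.
#'
#' @param spec A [community_spec()].
#' @param reference A [make_reference()] result (or a list with `entries`).
#' @param sample Sample label (default `"S1"`).
#' @param replicates Number of replicates (default 1).
#' @param digest A [digest_config()] for peptide sampling.
#' @param elements Optional [element_table()]; defaults to the spec's label
#'   element.
#' @return List with `envelopes` (data frame `sample`, `replicate`,
#'   `peptide`, `charge`, `mz`, `intensity`), `truth_peptides` (per peptide
#'   and replicate: `taxon`, `true_ria`, `true_lr`, `total_intensity`) and
#'   `truth_taxa` (per-taxon abundances).
#' @export
simulate_community <- function(spec, reference, sample = "S1", replicates = 1L,
                               digest = digest_config(), elements = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.null(elements)) elements <- element_table(spec$label_element)
  entries <- reference$entries
  withr::local_seed(spec$seed)

  env_rows <- list()
  truth <- list()
  for (ti in seq_len(nrow(spec$taxa))) {
    tx <- spec$taxa[ti, ]
    ei <- match(tx$accession, entries$accession)
    if (is.na(ei)) stop("accession ", tx$accession, " not in reference")
    peps <- tryptic_digest(entries$sequence[ei], digest)
    peps <- peps[!grepl("[XU]", peps)]
    if (!length(peps)) stop("no usable peptides for ", tx$accession)
    n <- min(spec$peptides_per_taxon, length(peps))
    peps <- sample(peps, n)
    for (p in peps) {
      f <- peptide_formula(p)
      nat <- .sim_pattern(f, elements, ria = NULL)
      mix <- if (tx$labeled_share > 0) {
        lab <- .sim_pattern(f, elements, ria = tx$ria)
        offs <- min(nat$offset, lab$offset):max(nat$offset, lab$offset)
        dens <- numeric(length(offs))
        dens[match(nat$offset, offs)] <- (1 - tx$labeled_share) * nat$intensity
        dens[match(lab$offset, offs)] <- dens[match(lab$offset, offs)] +
          tx$labeled_share * lab$intensity
        list(offset = offs[dens > 0], intensity = dens[dens > 0])
      } else {
        list(offset = nat$offset, intensity = nat$intensity)
      }
      for (rep_i in seq_len(replicates)) {
        z <- sample(spec$charges, 1L)
        base_int <- tx$abundance * exp(stats::rnorm(1, log(1e6), 0.4))
        intens <- base_int * mix$intensity
        if (spec$intensity_cv > 0)
          intens <- pmax(0, intens * (1 + stats::rnorm(length(intens), 0, spec$intensity_cv)))
        mz <- (nat$mono_mass + mix$offset * elements$offset_spacing) / z + .PROTON_MASS
        if (spec$mz_ppm > 0)
          mz <- mz * (1 + stats::runif(length(mz), -spec$mz_ppm, spec$mz_ppm) * 1e-6)
        env_rows[[length(env_rows) + 1L]] <- data.frame(
          sample = sample, replicate = rep_i, peptide = p, charge = z,
          mz = mz, intensity = intens, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          sample = sample, replicate = rep_i, peptide = p,
          taxon = entries$genus[ei], accession = tx$accession,
          true_ria = if (tx$labeled_share > 0) tx$ria else elements$natural_ria,
          true_lr = tx$labeled_share, total_intensity = sum(intens),
          stringsAsFactors = FALSE)
      }
    }
  }
  envelopes <- do.call(rbind, env_rows)
  envelopes <- envelopes[order(envelopes$replicate, envelopes$peptide,
                               envelopes$mz), , drop = FALSE]
  rownames(envelopes) <- NULL
  truth_peptides <- do.call(rbind, truth)
  rownames(truth_peptides) <- NULL
  truth_taxa <- data.frame(taxon = entries$genus[match(spec$taxa$accession,
                                                       entries$accession)],
                           accession = spec$taxa$accession,
                           abundance = spec$taxa$abundance,
                           stringsAsFactors = FALSE)
  list(envelopes = envelopes, truth_peptides = truth_peptides,
       truth_taxa = truth_taxa)
}
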