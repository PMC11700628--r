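# Independent oracles and fixture builders used across the suite.

# Brute-force tryptic digestion: enumerate every substring and apply the
# cleavage / missed-cleavage / length rules directly.
brute_digest <- function(sequence, config = digest_config()) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  is_site <- function(i) {
    i >= 1 && i <= n && aa[i] %in% c("K", "R") && (i == n || aa[i + 1] != "P")
  }
  out <- character(0)
  for (s in 0:(n - 1)) {
    for (e in (s + 1):n) {
      len <- e - s
      if (len < config$min_length || len > config$max_length) next
      if (!(s == 0 || is_site(s))) next
      if (!(e == n || is_site(e))) next
      internal <- if (e - 1 >= s + 1)
        sum(vapply((s + 1):(e - 1), is_site, logical(1))) else 0L
      if (internal > config$max_missed_cleavages) next
      out <- c(out, paste(aa[(s + 1):e], collapse = ""))
    }
  }
  sort(unique(out))
}

# Per-atom exhaustive isotopologue enumeration: every atom's isotope state is
# enumerated individually (feasible only for tiny formulas).
brute_pattern <- function(formula, elements, ria = NULL) {
  atoms <- list()
  for (el in names(formula)[formula > 0]) {
    iso <- elements$isotopes[[el]]
    ab <- iso$abundance
    if (!is.null(ria) && el == elements$label_element) {
      hi <- length(ab)
      light <- ab[-hi] / sum(ab[-hi])
      ab <- c(light * (1 - ria), ria)
    }
    for (a in seq_len(formula[[el]]))
      atoms[[length(atoms) + 1L]] <- list(off = iso$offset, p = ab)
  }
  combos <- as.matrix(do.call(expand.grid, lapply(atoms, function(s) seq_along(s$p))))
  probs <- apply(combos, 1, function(idx)
    prod(mapply(function(s, i) s$p[i], atoms, idx)))
  offs <- apply(combos, 1, function(idx)
    sum(mapply(function(s, i) s$off[i], atoms, idx)))
  agg <- rowsum(probs, offs)
  list(offset = as.integer(rownames(agg)), intensity = as.vector(agg))
}

# compare a truncated pattern against an untruncated oracle on the pattern's
# support (oracle renormalized over that support)
expect_pattern_equals_oracle <- function(pattern, oracle, tol = 1e-9) {
  o <- oracle$intensity[match(pattern$offset, oracle$offset)]
  o[is.na(o)] <- 0
  expect_lt(max(abs(pattern$intensity - o / sum(o))), tol)
}

# Hand-built evidence table (already matched and, optionally, flagged).
toy_evidence <- function(peptide, entries, intensity = 100, labeled = FALSE,
                         ria_top = NA_real_, lr = NA_real_,
                         sample = "S1", replicate = 1L) {
  df <- data.frame(peptide = peptide, intensity = intensity, sample = sample,
                   replicate = replicate, labeled = labeled,
                   ria_top = ria_top, lr = lr, stringsAsFactors = FALSE)
  df$entries <- entries
  df$shared <- rep(NA, nrow(df))
  class(df) <- c("peptide_evidence", "data.frame")
  df
}

# Hand-built evidence with taxa already attached (post flag_shared form).
flagged_evidence <- function(peptide, intensity, labeled, taxa,
                             ria_top = NA_real_, lr = NA_real_,
                             sample = "S1", replicate = 1L) {
  df <- data.frame(peptide = peptide, intensity = intensity, sample = sample,
                   replicate = replicate, labeled = labeled,
                   ria_top = ria_top, lr = lr, stringsAsFactors = FALSE)
  df$taxa <- taxa
  df$n_taxa <- lengths(taxa)
  df$shared <- df$n_taxa > 1L
  df
}

# Hand-built protein_groups table.
toy_groups <- function(trc, taxon = NULL, accessions = NULL, peptides = NULL) {
  n <- length(trc)
  g <- data.frame(group_id = seq_len(n), stringsAsFactors = FALSE)
  g$accessions <- if (is.null(accessions)) as.list(sprintf("E%02d", seq_len(n))) else accessions
  g$peptides <- if (is.null(peptides)) lapply(trc, function(k) sprintf("PEP%02d", seq_len(max(k, 1)))) else peptides
  g$n_peptides <- lengths(g$peptides)
  g$top_rank_count <- as.integer(trc)
  if (!is.null(taxon)) g$taxon <- taxon
  class(g) <- c("protein_groups", "data.frame")
  g
}

# Minimal reference entries data frame for index tests.
toy_reference <- function(sequences, genus = NULL, family = NULL) {
  n <- length(sequences)
  acc <- sprintf("T%03d", seq_len(n))
  if (is.null(genus)) genus <- sprintf("Genus%02d", seq_len(n))
  if (is.null(family)) family <- sprintf("Family%02d", seq_len(n))
  df <- data.frame(accession = acc, organism = paste(genus, "sp."),
                   sequence = sequences, stringsAsFactors = FALSE)
  df$accessions <- as.list(acc)
  df$superkingdom <- "Bacteria"; df$phylum <- "P"; df$class <- "C"
  df$order <- "O"; df$family <- family; df$genus <- genus
  df$species <- paste(genus, "sp.")
  class(df) <- c("groel_reference", "data.frame")
  df
}

# write a small FASTA (wrapped lines) + taxonomy TSV fixture
write_fixture_reference <- function(dir, seqs, accs = NULL, tax_rows = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(accs)) accs <- sprintf("ACC%d", seq_along(seqs))
  fasta <- file.path(dir, "ref.fasta")
  con <- file(fasta, "w")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", accs[i], " organism ", i), con)
    writeLines(substring(seqs[i], seq(1, nchar(seqs[i]), 30),
                         pmin(nchar(seqs[i]), seq(30, nchar(seqs[i]) + 29, 30))), con)
  }
  close(con)
  if (is.null(tax_rows)) {
    tax_rows <- data.frame(accession = accs, superkingdom = "Bacteria",
                           phylum = "P", class = "C", order = "O",
                           family = paste0("Fam", seq_along(accs)),
                           genus = paste0("Gen", seq_along(accs)),
                           species = paste0("Gen", seq_along(accs), " sp."),
                           stringsAsFactors = FALSE)
  }
  tsv <- file.path(dir, "tax.tsv")
  utils::write.table(tax_rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, taxonomy = tsv)
}
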