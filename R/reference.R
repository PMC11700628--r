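# GroEL marker-protein reference: loading, deduplication, in silico tryptic
# digestion and the peptide -> entry index used for all downstream matching.

.RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus", "species")

#' Digestion settings
#'
#' @param min_length,max_length Retained peptide length bounds in residues
#'   (defaults 6 and 40).
#' @param max_missed_cleavages Maximum number of internal (missed) cleavage
#'   sites per peptide (default 2).
#' @param equate_il Treat isoleucine and leucine as equivalent (isobaric
#'   residues indistinguishable by mass); peptides are canonicalized I -> L
#'   before indexing (default TRUE).
#' @return A list of class `digest_config`.
#' @export
digest_config <- function(min_length = 6L, max_length = 40L,
                          max_missed_cleavages = 2L, equate_il = TRUE) {
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (min_length <= 0L || min_length > max_length)
    stop("need 0 < min_length <= max_length")
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  structure(list(min_length = min_length, max_length = max_length,
                 max_missed_cleavages = max_missed_cleavages,
                 equate_il = isTRUE(equate_il)),
            class = "digest_config")
}

#' Canonical peptide form
#'
#' Uppercases and, when `equate_il`, collapses I to L so that isobaric
#' peptides share one key.
#'
#' @param peptide Character vector of peptide sequences.
#' @param equate_il Collapse I to L (default TRUE).
#' @return Canonicalized character vector.
#' @export
canonical_peptide <- function(peptide, equate_il = TRUE) {
  p <- toupper(peptide)
  if (equate_il) p <- gsub("I", "L", p, fixed = TRUE)
  p
}

#' Read a GroEL reference (FASTA + taxonomy TSV)
#'
#' One entry per FASTA record; the accession is the first whitespace-delimited
#' token of the header, the remainder is kept as the organism description.
#' Lineages (superkingdom to species) are attached from the taxonomy table.
#' Accessions missing from the taxonomy receive an all-empty lineage and are
#' later reported as "unclassified" rather than dropped; a warning counts
#' them. Both files may be gzip-compressed.
#'
#' @param fasta_path Path to the reference FASTA.
#' @param taxonomy_path Path to a TSV with header columns `accession`,
#'   `superkingdom`, `phylum`, `class`, `order`, `family`, `genus`, `species`.
#' @return A data frame of class `groel_reference` with columns `accession`,
#'   `accessions` (list column, one or more accessions per entry), `organism`,
#'   `sequence` and the seven rank columns.
#' @export
read_reference <- function(fasta_path, taxonomy_path) {
  if (!file.exists(fasta_path)) stop("cannot read FASTA: ", fasta_path)
  if (!file.exists(taxonomy_path)) stop("cannot read taxonomy: ", taxonomy_path)
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA (", fasta_path,
                                            "): ", conditionMessage(e)))
  tax <- utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!"accession" %in% names(tax))
    stop("taxonomy TSV must have an 'accession' column")
  missing_ranks <- setdiff(.RANKS, names(tax))
  for (r in missing_ranks) tax[[r]] <- ""

  headers <- names(seqs)
  acc <- sub("\\s.*$", "", headers)
  organism <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(acc))
    stop("duplicate accession in FASTA: ", acc[duplicated(acc)][1])
  entries <- data.frame(accession = acc, organism = organism,
                        sequence = toupper(as.character(seqs)),
                        stringsAsFactors = FALSE)
  if (any(!nzchar(entries$sequence)))
    stop("empty sequence for record ", acc[!nzchar(entries$sequence)][1])
  entries$accessions <- as.list(acc)
  m <- match(acc, tax$accession)
  for (r in .RANKS) entries[[r]] <- ifelse(is.na(m), "", tax[[r]][m])
  n_missing <- sum(is.na(m))
  if (n_missing > 0)
    warning(n_missing, " accession(s) absent from taxonomy; assigned empty lineage")
  class(entries) <- c("groel_reference", "data.frame")
  entries
}

#' Collapse entries with identical sequences
#'
#' Entries whose sequences are identical (after I/L collapse when enabled)
#' are merged into one entry carrying the union of accessions; the first
#' entry's organism and lineage are kept. Idempotent.
#'
#' @param entries A `groel_reference` data frame.
#' @param config A [digest_config()] (only `equate_il` is used).
#' @return Deduplicated `groel_reference`.
#' @export
deduplicate_reference <- function(entries, config = digest_config()) {
  key <- canonical_peptide(entries$sequence, config$equate_il)
  first <- !duplicated(key)
  grp <- match(key, key[first])
  out <- entries[first, , drop = FALSE]
  out$accessions <- lapply(seq_len(sum(first)), function(i)
    unique(unlist(entries$accessions[grp == i], use.names = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("groel_reference", "data.frame")
  out
}

#' In silico tryptic digestion
#'
#' Fully tryptic digestion with the trypsin/P rule: cleavage C-terminal to K
#' or R, suppressed when the next residue is proline. All products with at
#' most `max_missed_cleavages` internal cleavage sites and length within the
#' configured bounds are returned.
#'
#' @param sequence Protein sequence (uppercase amino acids).
#' @param config A [digest_config()].
#' @return Character vector of unique peptides (not canonicalized).
#' @examples
#' tryptic_digest("MKAAAKGGGR")  # MKAAAK, AAAKGGGR, MKAAAKGGGR
#' @export
tryptic_digest <- function(sequence, config = digest_config()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  # cleavage after position i: K/R at i, not followed by P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n else NULL)
  bounds <- sort(unique(bounds))
  nb <- length(bounds)
  peps <- character(0)
  for (i in seq_len(nb - 1L)) {
    max_j <- min(nb, i + 1L + config$max_missed_cleavages)
    for (j in (i + 1L):max_j) {
      len <- bounds[j] - bounds[i]
      if (len < config$min_length) next
      if (len > config$max_length) break
      peps <- c(peps, substr(sequence, bounds[i] + 1L, bounds[j]))
    }
  }
  unique(peps)
}

#' Build the peptide -> entry index
#'
#' Digests every (deduplicated) entry and maps each canonical peptide to the
#' accession set of the entries whose digest contains it.
#'
#' @param entries Deduplicated `groel_reference`.
#' @param config A [digest_config()].
#' @return A list of class `reference_index`: `peptide_to_entries` (named list
#'   mapping canonical peptide to character vector of primary accessions),
#'   `entry_to_lineage` (data frame keyed by accession with the rank columns),
#'   and the `config` used.
#' @export
build_index <- function(entries, config = digest_config()) {
  pep_lists <- lapply(entries$sequence, tryptic_digest, config = config)
  peps <- canonical_peptide(unlist(pep_lists, use.names = FALSE), config$equate_il)
  ids <- rep(entries$accession, lengths(pep_lists))
  keep <- !duplicated(paste(peps, ids, sep = "\r"))
  map <- split(ids[keep], peps[keep])
  lineage <- entries[, c("accession", .RANKS), drop = FALSE]
  rownames(lineage) <- NULL
  structure(list(peptide_to_entries = map,
                 entry_to_lineage = as.data.frame(lineage),
                 config = config),
            class = "reference_index")
}

#' Look up entries matching a peptide
#'
#' @param index A [build_index()] result.
#' @param peptide Peptide sequence (canonicalized internally).
#' @return Character vector of matching accessions (empty when unmatched).
#' @export
index_lookup <- function(index, peptide) {
  hit <- index$peptide_to_entries[[canonical_peptide(peptide, index$config$equate_il)]]
  if (is.null(hit)) character(0) else hit
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d peptides over %d entries\n",
              length(x$peptide_to_entries), nrow(x$entry_to_lineage)))
  invisible(x)
}
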