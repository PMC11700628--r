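# Peptide-to-protein-group inference with Top Rank Count filtering and
# taxonomy assignment at a chosen rank.
#
# Protein groups are built from UNLABELED evidence only; labeled evidence is
# afterwards attributed to the retained taxa. Two reference entries fall in
# one group iff their sets of supporting peptides are identical.

#' Match a peptide evidence table against the reference index
#'
#' Canonicalizes each peptide and attaches the matching accessions; peptides
#' without any reference match are dropped with a logged count.
#'
#' @param peptide_table Data frame with at least columns `peptide` and
#'   `intensity`; optional `sample`, `replicate`, `labeled`, `ria_top`, `lr`
#'   are carried through (missing ones get defaults `"S1"`, `1`, `FALSE`,
#'   `NA`, `NA`).
#' @param index A [build_index()] result.
#' @return Data frame of class `peptide_evidence` with an `entries` list
#'   column of matched accessions and a `shared` logical column
#'   (NA until [flag_shared()] runs).
#' @export
match_evidence <- function(peptide_table, index) {
  stopifnot(is.data.frame(peptide_table))
  if (nrow(peptide_table) == 0L)
    return(.as_evidence(data.frame(peptide = character(0), intensity = numeric(0)),
                        list()))
  req <- c("peptide", "intensity")
  if (!all(req %in% names(peptide_table)))
    stop("peptide table needs columns: ", paste(req, collapse = ", "))
  bad <- !nzchar(as.character(peptide_table$peptide)) |
    is.na(peptide_table$intensity) | peptide_table$intensity < 0
  if (any(bad)) {
    if (mean(bad) > 0.5) stop("more than 50% of evidence rows are malformed")
    warning(sum(bad), " malformed evidence row(s) skipped")
    peptide_table <- peptide_table[!bad, , drop = FALSE]
  }
  canon <- canonical_peptide(peptide_table$peptide, index$config$equate_il)
  hits <- lapply(canon, function(p) {
    h <- index$peptide_to_entries[[p]]
    if (is.null(h)) character(0) else h
  })
  matched <- lengths(hits) > 0L
  n_dropped <- sum(!matched)
  if (n_dropped > 0)
    message(n_dropped, " peptide(s) without reference match dropped")
  out <- peptide_table[matched, , drop = FALSE]
  out$peptide <- canon[matched]
  .as_evidence(out, hits[matched])
}

.as_evidence <- function(df, entries) {
  if (!"sample" %in% names(df)) df$sample <- rep("S1", nrow(df))
  if (!"replicate" %in% names(df)) df$replicate <- rep(1L, nrow(df))
  if (!"labeled" %in% names(df)) df$labeled <- rep(FALSE, nrow(df))
  if (!"ria_top" %in% names(df)) df$ria_top <- rep(NA_real_, nrow(df))
  if (!"lr" %in% names(df)) df$lr <- rep(NA_real_, nrow(df))
  df$entries <- entries
  df$shared <- rep(NA, nrow(df))
  rownames(df) <- NULL
  class(df) <- c("peptide_evidence", "data.frame")
  df
}

#' Build protein groups from identified peptides
#'
#' Each reference entry's supporting peptide set is the set of distinct
#' identified peptides matching it; entries with identical sets are merged
#' into one group. Because a labeled peptide can only be identified when its
#' unlabeled version is present (the unlabeled anchor), every identified
#' peptide contributes an identified unlabeled peptide, and by default all
#' evidence builds groups; `unlabeled_only = TRUE` restricts support to
#' evidence without any labeled component.
#'
#' @param evidence A [match_evidence()] result.
#' @param unlabeled_only Use only evidence with `labeled = FALSE` as group
#'   support (default FALSE).
#' @return Data frame of class `protein_groups` with columns `group_id`,
#'   `accessions` (list), `peptides` (list), `n_peptides` and
#'   `top_rank_count` (NA until [top_rank_count()] runs).
#' @export
build_protein_groups <- function(evidence, unlabeled_only = FALSE) {
  unlab <- if (unlabeled_only) evidence[!evidence$labeled, , drop = FALSE] else evidence
  empty <- data.frame(group_id = integer(0), n_peptides = integer(0),
                      top_rank_count = integer(0))
  empty$accessions <- list(); empty$peptides <- list()
  if (nrow(unlab) == 0L) {
    class(empty) <- c("protein_groups", "data.frame")
    return(empty)
  }
  acc <- unlist(unlab$entries, use.names = FALSE)
  pep <- rep(unlab$peptide, lengths(unlab$entries))
  pairs <- unique(data.frame(acc = acc, pep = pep, stringsAsFactors = FALSE))
  pep_sets <- lapply(split(pairs$pep, pairs$acc), function(p) sort(unique(p)))
  keys <- vapply(pep_sets, paste, character(1), collapse = "\r")
  uk <- sort(unique(keys))
  groups <- data.frame(group_id = seq_along(uk), stringsAsFactors = FALSE)
  groups$accessions <- lapply(uk, function(k) sort(names(pep_sets)[keys == k]))
  groups$peptides <- lapply(uk, function(k) pep_sets[[which(keys == k)[1]]])
  groups$n_peptides <- lengths(groups$peptides)
  groups$top_rank_count <- rep(NA_integer_, nrow(groups))
  class(groups) <- c("protein_groups", "data.frame")
  groups
}

#' Compute Top Rank Counts
#'
#' For every distinct peptide, the groups containing it are ranked by their
#' distinct peptide count; every group attaining the maximum receives one
#' increment (ties all score). A group's Top Rank Count is the number of
#' peptides for which it is top-ranked.
#'
#' @param groups A [build_protein_groups()] result.
#' @return The groups with `top_rank_count` filled.
#' @export
top_rank_count <- function(groups) {
  if (nrow(groups) == 0L) return(groups)
  gid <- rep(groups$group_id, lengths(groups$peptides))
  pep <- unlist(groups$peptides, use.names = FALSE)
  size <- groups$n_peptides[match(gid, groups$group_id)]
  trc <- integer(nrow(groups))
  for (chunk in split(seq_along(pep), pep)) {
    top <- chunk[size[chunk] == max(size[chunk])]
    g <- match(gid[top], groups$group_id)
    trc[g] <- trc[g] + 1L
  }
  groups$top_rank_count <- trc
  groups
}

#' Filter groups by Top Rank Count
#'
#' Groups below the threshold (default 5, the false-positive control used in
#' GroEL proteotyping) are dropped with a logged count.
#'
#' @param groups Groups with `top_rank_count` filled.
#' @param threshold Minimum Top Rank Count to retain (default 5).
#' @return Retained groups.
#' @export
filter_groups <- function(groups, threshold = 5L) {
  if (nrow(groups) == 0L) return(groups)
  if (anyNA(groups$top_rank_count)) stop("run top_rank_count() first")
  keep <- groups$top_rank_count >= threshold
  if (any(!keep))
    message(sum(!keep), " group(s) below Top Rank Count ", threshold, " dropped")
  out <- groups[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default genus merge rules
#'
#' Genera indistinguishable by GroEL peptides are merged for reporting;
#' by default Shigella is folded into Escherichia.
#' @return Named list per rank of `c(from = to)` renamings.
#' @export
default_merge_rules <- function() {
  list(genus = c(Shigella = "Escherichia"))
}

#' Infer the taxon of one protein group at a rank
#'
#' Applies the merge rules, then requires all member lineages to agree at the
#' requested rank (empty names count as disagreement unless all are empty, in
#' which case the group is unclassified). On disagreement the assignment at
#' the requested rank is `"unclassified"` and the deepest agreeing coarser
#' rank is reported as a fallback.
#'
#' @param group One row of a `protein_groups` data frame.
#' @param rank Reporting rank, e.g. `"genus"` or `"family"`.
#' @param lineage Data frame keyed by `accession` with the rank columns
#'   (from `index$entry_to_lineage`).
#' @param merge_rules See [default_merge_rules()].
#' @return List with `rank`, `taxon`, `fallback_rank`, `fallback_taxon`.
#' @export
infer_taxon <- function(group, rank = "genus", lineage,
                        merge_rules = default_merge_rules()) {
  stopifnot(rank %in% .RANKS)
  accs <- group$accessions[[1]]
  lin <- lineage[match(accs, lineage$accession), .RANKS, drop = FALSE]
  for (r in names(merge_rules)) {
    map <- merge_rules[[r]]
    hit <- lin[[r]] %in% names(map)
    lin[[r]][hit] <- map[lin[[r]][hit]]
  }
  agree <- function(v) {
    v[is.na(v)] <- ""
    u <- unique(v)
    if (length(u) == 1L && nzchar(u)) u else NA_character_
  }
  ri <- match(rank, .RANKS)
  taxon <- agree(lin[[rank]])
  fallback_rank <- NA_character_
  fallback_taxon <- NA_character_
  if (is.na(taxon)) {
    taxon <- "unclassified"
    for (j in rev(seq_len(ri - 1L))) {
      cand <- agree(lin[[.RANKS[j]]])
      if (!is.na(cand)) {
        fallback_rank <- .RANKS[j]
        fallback_taxon <- cand
        break
      }
    }
  }
  list(rank = rank, taxon = taxon,
       fallback_rank = fallback_rank, fallback_taxon = fallback_taxon)
}

#' Assign taxa to all retained groups
#'
#' @param groups Retained groups.
#' @param lineage Lineage table (`index$entry_to_lineage`).
#' @param rank Reporting rank.
#' @param merge_rules See [default_merge_rules()].
#' @return Groups with `taxon`, `fallback_rank`, `fallback_taxon` columns.
#' @export
assign_taxa <- function(groups, lineage, rank = "genus",
                        merge_rules = default_merge_rules()) {
  if (nrow(groups) == 0L) {
    groups$taxon <- character(0)
    groups$fallback_rank <- character(0)
    groups$fallback_taxon <- character(0)
    return(groups)
  }
  res <- lapply(seq_len(nrow(groups)), function(i)
    infer_taxon(groups[i, , drop = FALSE], rank, lineage, merge_rules))
  groups$taxon <- vapply(res, `[[`, character(1), "taxon")
  groups$fallback_rank <- vapply(res, `[[`, character(1), "fallback_rank")
  groups$fallback_taxon <- vapply(res, `[[`, character(1), "fallback_taxon")
  groups
}

#' Attach taxa to evidence and flag shared peptides
#'
#' Every evidence row (labeled or unlabeled) is assigned the set of retained
#' taxa its matched entries map to; a peptide is `shared` iff it maps to more
#' than one retained taxon at the reporting rank. Evidence matching only
#' entries of filtered-out groups is assigned no taxon and counted
#' "unassigned".
#'
#' @param evidence A [match_evidence()] result.
#' @param groups Retained groups with taxa assigned ([assign_taxa()]).
#' @return Evidence with list column `taxa`, integer `n_taxa` and logical
#'   `shared` filled.
#' @export
flag_shared <- function(evidence, groups) {
  ent2tax <- character(0)
  if (nrow(groups) > 0L) {
    accs <- unlist(groups$accessions, use.names = FALSE)
    ent2tax <- stats::setNames(rep(groups$taxon, lengths(groups$accessions)), accs)
  }
  taxa <- lapply(evidence$entries, function(e)
    sort(unique(unname(ent2tax[intersect(e, names(ent2tax))]))))
  evidence$taxa <- taxa
  evidence$n_taxa <- lengths(taxa)
  evidence$shared <- evidence$n_taxa > 1L
  n_un <- sum(evidence$n_taxa == 0L)
  if (n_un > 0)
    message(n_un, " evidence row(s) not assignable to any retained taxon")
  evidence
}
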