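# End-to-end orchestration: configuration, readers for the two input modes
# (raw isotope envelopes or a peptide-centric table with precomputed RIA/LR),
# batch decomposition, and the run manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the standard GroEL-SIP settings: up to two missed
#' tryptic cleavages, peptide lengths 6-40, +-5 ppm peak assignment, merge
#' windows +-1.5 Da (2H) / +-5.0 Da (13C, 18O), Top Rank Count threshold 5,
#' reporting at genus or family rank.
#'
#' @param reference_fasta,taxonomy Paths to the GroEL reference.
#' @param input Path to the input CSV (envelopes or peptide-centric table).
#' @param mode `"envelopes"` or `"peptide_centric"`.
#' @param label_element `"C"`, `"H"` or `"O"`.
#' @param rank Reporting rank, `"genus"` or `"family"`.
#' @param trc_threshold Top Rank Count threshold (default 5).
#' @param digest A [digest_config()].
#' @param decomposition A [decompose_config()].
#' @param merge_rules See [default_merge_rules()].
#' @param out_dir Output directory (default: no files written).
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `groel_config`.
#' @export
groel_config <- function(reference_fasta, taxonomy, input,
                         mode = c("envelopes", "peptide_centric"),
                         label_element = "C", rank = c("genus", "family"),
                         trc_threshold = 5L, digest = digest_config(),
                         decomposition = decompose_config(),
                         merge_rules = default_merge_rules(),
                         out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  rank <- match.arg(rank)
  cfg <- structure(list(reference_fasta = reference_fasta, taxonomy = taxonomy,
                        input = input, mode = mode,
                        label_element = label_element, rank = rank,
                        trc_threshold = as.integer(trc_threshold),
                        digest = digest, decomposition = decomposition,
                        merge_rules = merge_rules, out_dir = out_dir,
                        seed = as.integer(seed)),
                   class = "groel_config")
  for (p in c("reference_fasta", "taxonomy", "input"))
    if (!file.exists(cfg[[p]])) stop("config error: ", p, " not found: ", cfg[[p]])
  cfg
}

#' Read an envelope CSV
#'
#' Columns `sample`, `replicate`, `peptide`, `charge`, `mz`, `intensity`
#' (one row per peak).
#'
#' @param path CSV path (gzip transparent).
#' @return Data frame of peaks.
#' @export
read_envelopes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "replicate", "peptide", "charge", "mz", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("envelope CSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

# best-effort header mapping for peptide-centric tables (canonical dialect
# plus MetaProSIP-style column names)
.PEPTIDE_CENTRIC_ALIASES <- list(
  peptide = c("peptide", "peptidesequence", "sequence"),
  intensity = c("intensity", "intensities", "globalpeptideintensity"),
  rias = c("rias", "ria", "riavalues"),
  lr = c("lr", "labelingratio", "labelingratios"),
  sample = c("sample", "samplename", "file"),
  replicate = c("replicate", "rep")
)

#' Read a peptide-centric evidence table
#'
#' CSV with one row per identified peptide and sample: peptide sequence,
#' precursor intensity, detected RIAs (percent, semicolon-separated; the
#' first/lowest is typically the natural one) and LR (fraction). Column
#' headers are matched case-insensitively against the canonical dialect and
#' common MetaProSIP-style names. Rows whose RIA list contains no value above
#' the natural RIA are unlabeled and are kept.
#'
#' @param path CSV path.
#' @param elements An [element_table()]; its natural RIA separates labeled
#'   from unlabeled rows.
#' @return Data frame with `peptide`, `intensity`, `sample`, `replicate`,
#'   `rias` (list column, fractions), `ria_top` (highest RIA, fraction),
#'   `lr`, `labeled`.
#' @export
read_peptide_centric <- function(path, elements = element_table()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  norm <- tolower(gsub("[^A-Za-z]", "", names(df)))
  pick <- function(field) {
    hit <- which(norm %in% .PEPTIDE_CENTRIC_ALIASES[[field]])
    if (length(hit)) hit[1] else NA_integer_
  }
  cols <- vapply(names(.PEPTIDE_CENTRIC_ALIASES), pick, integer(1))
  required <- c("peptide", "intensity", "rias")
  if (anyNA(cols[required])) {
    tried <- vapply(required[is.na(cols[required])], function(f)
      paste0(f, " (tried: ", paste(.PEPTIDE_CENTRIC_ALIASES[[f]], collapse = ", "), ")"),
      character(1))
    stop("peptide-centric CSV missing column(s): ", paste(tried, collapse = "; "))
  }
  out <- data.frame(peptide = as.character(df[[cols["peptide"]]]),
                    intensity = as.numeric(df[[cols["intensity"]]]),
                    stringsAsFactors = FALSE)
  out$sample <- if (!is.na(cols["sample"])) as.character(df[[cols["sample"]]]) else "S1"
  out$replicate <- if (!is.na(cols["replicate"])) df[[cols["replicate"]]] else 1L
  rias <- lapply(strsplit(as.character(df[[cols["rias"]]]), ";", fixed = TRUE),
                 function(v) as.numeric(v) / 100)
  out$rias <- rias
  out$ria_top <- vapply(rias, function(v) if (length(v)) max(v, na.rm = TRUE) else NA_real_,
                        numeric(1))
  out$lr <- if (!is.na(cols["lr"])) as.numeric(df[[cols["lr"]]]) else NA_real_
  out$labeled <- !is.na(out$ria_top) & out$ria_top > elements$natural_ria + 1e-6
  out$lr[!out$labeled] <- 0
  out
}

#' Decompose a batch of envelopes into peptide evidence
#'
#' Groups envelope peaks by sample, replicate, peptide and charge, derives
#' each peptide's formula and runs [decompose_envelope()]. Peptides whose
#' decomposition lacks an unlabeled anchor are dropped (not reported), as are
#' peptides containing residues without an elemental formula (X, U), each
#' with a logged count.
#'
#' @param envelopes Data frame as returned by [read_envelopes()] or
#'   [simulate_community()].
#' @param elements An [element_table()].
#' @param config A [decompose_config()].
#' @return Peptide-centric evidence data frame with `peptide`, `intensity`,
#'   `sample`, `replicate`, `labeled`, `ria_top`, `lr`, `n_components`.
#' @export
decompose_envelopes <- function(envelopes, elements = element_table(),
                                config = decompose_config()) {
  key <- paste(envelopes$sample, envelopes$replicate, envelopes$peptide,
               envelopes$charge, sep = "\r")
  out <- list()
  n_anchor_dropped <- 0L
  n_formula_dropped <- 0L
  nat <- elements$natural_ria
  for (grp in split(seq_len(nrow(envelopes)), key)) {
    sub <- envelopes[grp, , drop = FALSE]
    sub <- sub[order(sub$mz), , drop = FALSE]
    f <- tryCatch(peptide_formula(sub$peptide[1]), error = function(e) NULL)
    if (is.null(f)) { n_formula_dropped <- n_formula_dropped + 1L; next }
    cmp <- decompose_envelope(sub[, c("mz", "intensity")], f, elements, config,
                              charge = sub$charge[1])
    if (length(cmp$flag)) { n_anchor_dropped <- n_anchor_dropped + 1L; next }
    labeled <- is_labeled(cmp, nat)
    lab_rias <- cmp$components$ria[cmp$components$ria > nat + 1e-9]
    out[[length(out) + 1L]] <- data.frame(
      peptide = sub$peptide[1], intensity = cmp$total_intensity,
      sample = sub$sample[1], replicate = sub$replicate[1],
      labeled = labeled,
      ria_top = if (labeled) max(lab_rias) else nat,
      lr = if (labeled) cmp$lr else 0,
      n_components = nrow(cmp$components), stringsAsFactors = FALSE)
  }
  if (n_formula_dropped > 0)
    warning(n_formula_dropped,
            " peptide(s) without a computable elemental formula skipped")
  if (n_anchor_dropped > 0)
    message(n_anchor_dropped, " peptide(s) without unlabeled anchor not reported")
  if (!length(out))
    return(data.frame(peptide = character(0), intensity = numeric(0),
                      sample = character(0), replicate = integer(0),
                      labeled = logical(0), ria_top = numeric(0),
                      lr = numeric(0), n_components = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full GroEL-SIP pipeline
#'
#' reference loading -> deduplication -> digestion/indexing -> (envelope
#' decomposition in envelope mode) -> evidence matching -> protein grouping
#' -> Top Rank Count filtering -> taxon inference -> shared-peptide flagging
#' -> taxon summaries. When `out_dir` is set, writes `groups.tsv`,
#' `peptides.tsv`, `taxon_summary.tsv`, `replicate_summary.tsv` and
#' `manifest.json` (per-stage counts, configuration, package version).
#'
#' @param config A [groel_config()].
#' @return Invisibly, a list with `evidence`, `groups`, `retained`,
#'   `summary`, `aggregate`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "groel_config"))
  elements <- element_table(config$label_element)

  entries <- read_reference(config$reference_fasta, config$taxonomy)
  n_entries_raw <- nrow(entries)
  entries <- deduplicate_reference(entries, config$digest)
  index <- build_index(entries, config$digest)

  if (config$mode == "envelopes") {
    envelopes <- read_envelopes(config$input)
    peptide_table <- decompose_envelopes(envelopes, elements, config$decomposition)
  } else {
    peptide_table <- read_peptide_centric(config$input, elements)
  }
  evidence <- match_evidence(peptide_table, index)

  groups <- top_rank_count(build_protein_groups(evidence))
  retained <- filter_groups(groups, config$trc_threshold)
  retained <- assign_taxa(retained, index$entry_to_lineage, config$rank,
                          config$merge_rules)
  evidence <- flag_shared(evidence, retained)
  summ <- taxon_summary(evidence)
  agg <- replicate_aggregate(summ)

  manifest <- list(
    package = "groelsip",
    version = as.character(utils::packageVersion("groelsip")),
    seed = config$seed,
    mode = config$mode, label_element = config$label_element,
    rank = config$rank, trc_threshold = config$trc_threshold,
    counts = list(
      reference_entries = n_entries_raw,
      reference_nonredundant = nrow(entries),
      indexed_peptides = length(index$peptide_to_entries),
      evidence_rows = nrow(peptide_table),
      evidence_matched = nrow(evidence),
      evidence_labeled = sum(evidence$labeled),
      evidence_shared = sum(evidence$shared, na.rm = TRUE),
      groups_built = nrow(groups),
      groups_retained = nrow(retained),
      taxa_reported = length(unique(retained$taxon))
    ))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(d, f) utils::write.table(
      d, file.path(config$out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    gout <- retained
    gout$accessions <- vapply(gout$accessions, paste, character(1), collapse = ";")
    gout$peptides <- vapply(gout$peptides, paste, character(1), collapse = ";")
    wtsv(gout, "groups.tsv")
    pout <- as.data.frame(evidence)
    pout$entries <- vapply(pout$entries, paste, character(1), collapse = ";")
    pout$taxa <- vapply(pout$taxa, paste, character(1), collapse = ";")
    wtsv(pout, "peptides.tsv")
    wtsv(summ, "taxon_summary.tsv")
    wtsv(agg, "replicate_summary.tsv")
    cfg_path <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(.config_as_list(config), cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    manifest$outputs <- c("groups.tsv", "peptides.tsv", "taxon_summary.tsv",
                          "replicate_summary.tsv", "config.yaml")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(evidence = evidence, groups = groups, retained = retained,
                 summary = summ, aggregate = agg, manifest = manifest))
}

.config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$digest <- unclass(cfg$digest)
  cfg$decomposition <- unclass(cfg$decomposition)
  cfg$merge_rules <- lapply(cfg$merge_rules, as.list)
  cfg[!vapply(cfg, is.null, logical(1))]
}

#' Orders of magnitude between two database sizes
#'
#' `round(log10(a / b))`: e.g. a marker-protein database of 72,759 entries is
#' four magnitudes smaller than a broad-spectrum database of 631,584,287.
#'
#' @param a,b Positive sizes.
#' @return Integer order-of-magnitude ratio.
#' @export
magnitude_ratio <- function(a, b) {
  stopifnot(a > 0, b > 0)
  round(log10(a / b))
}
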