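# Taxon-level aggregation: precursor-intensity quantification with
# proportional apportionment of shared peptides, relative abundances,
# relative count of labeled peptides (RA), median RIA/LR and replicate
# statistics with Student's t comparisons.

.by_sample <- function(evidence) {
  interaction(evidence$sample, evidence$replicate, drop = TRUE, lex.order = TRUE)
}

#' Apportion precursor intensities to taxa
#'
#' Non-shared evidence contributes its full intensity to its taxon. The
#' intensity of a shared peptide is split among its taxa proportionally to
#' each taxon's total count of assigned peptides of the same class (labeled
#' or unlabeled, counting shared and non-shared); when all involved taxa have
#' zero same-class peptides the split is equal, with a warning. Total
#' intensity of assigned evidence is conserved exactly.
#'
#' @param evidence Evidence with `taxa` and `shared` filled ([flag_shared()]).
#' @return Data frame with columns `taxon`, `sample`, `replicate`, `INT`.
#' @export
apportion_intensities <- function(evidence) {
  ev <- evidence[lengths(evidence$taxa) > 0L, , drop = FALSE]
  out <- list()
  for (grp in split(seq_len(nrow(ev)), .by_sample(ev))) {
    sub <- ev[grp, , drop = FALSE]
    long <- data.frame(
      taxon = unlist(sub$taxa, use.names = FALSE),
      labeled = rep(sub$labeled, sub$n_taxa),
      stringsAsFactors = FALSE)
    counts <- table(long$taxon, factor(long$labeled, levels = c(FALSE, TRUE)))
    int <- stats::setNames(numeric(nrow(counts)), rownames(counts))
    for (i in seq_len(nrow(sub))) {
      taxa_i <- sub$taxa[[i]]
      if (length(taxa_i) == 1L) {
        int[taxa_i] <- int[taxa_i] + sub$intensity[i]
      } else {
        cls <- if (sub$labeled[i]) "TRUE" else "FALSE"
        n <- counts[taxa_i, cls]
        if (sum(n) == 0) {
          warning("shared peptide among taxa with zero same-class peptides; split equally")
          share <- rep(1 / length(taxa_i), length(taxa_i))
        } else {
          share <- n / sum(n)
        }
        int[taxa_i] <- int[taxa_i] + sub$intensity[i] * share
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      taxon = names(int), sample = sub$sample[1], replicate = sub$replicate[1],
      INT = unname(int), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(taxon = character(0), sample = character(0),
                      replicate = integer(0), INT = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative taxon abundances from apportioned intensities
#'
#' @param int_df Output of [apportion_intensities()].
#' @return The input with a `rel_abundance` column (fractions summing to 1
#'   within each sample/replicate); all-zero samples get NA and a warning.
#' @export
relative_abundance <- function(int_df) {
  key <- interaction(int_df$sample, int_df$replicate, drop = TRUE, lex.order = TRUE)
  tot <- stats::ave(int_df$INT, key, FUN = sum)
  if (any(tot == 0)) warning("sample with zero total intensity flagged NA")
  int_df$rel_abundance <- ifelse(tot > 0, int_df$INT / tot, NA_real_)
  int_df
}

#' Relative count of labeled peptides (RA)
#'
#' Per taxon and sample/replicate: the number of non-shared isotopically
#' labeled peptides over all non-shared (labeled plus unlabeled) peptides.
#' Undefined (NA, not 0) when a taxon has no non-shared peptides.
#'
#' @param evidence Evidence with `taxa` and `shared` filled.
#' @return Data frame with `taxon`, `sample`, `replicate`, `n_labeled`,
#'   `n_unlabeled`, `n_shared_labeled`, `RA`.
#' @export
relative_count_labeled <- function(evidence) {
  ev <- evidence[lengths(evidence$taxa) > 0L, , drop = FALSE]
  out <- list()
  for (grp in split(seq_len(nrow(ev)), .by_sample(ev))) {
    sub <- ev[grp, , drop = FALSE]
    taxa <- sort(unique(unlist(sub$taxa, use.names = FALSE)))
    ns <- !sub$shared
    for (tx in taxa) {
      has <- vapply(sub$taxa, function(t) tx %in% t, logical(1))
      nl <- sum(has & ns & sub$labeled)
      nu <- sum(has & ns & !sub$labeled)
      nsl <- sum(has & !ns & sub$labeled)
      out[[length(out) + 1L]] <- data.frame(
        taxon = tx, sample = sub$sample[1], replicate = sub$replicate[1],
        n_labeled = nl, n_unlabeled = nu, n_shared_labeled = nsl,
        RA = if (nl + nu > 0) nl / (nl + nu) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(taxon = character(0), sample = character(0),
                      replicate = integer(0), n_labeled = integer(0),
                      n_unlabeled = integer(0), n_shared_labeled = integer(0),
                      RA = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median RIA and LR of a taxon's labeled peptides
#'
#' Uses only non-shared labeled peptides; per peptide, the highest detected
#' RIA (and its LR) enters the median. Values are reported in percent. NA
#' when the taxon has no non-shared labeled peptides.
#'
#' @param evidence Evidence with `taxa`, `shared`, `ria_top` (fraction) and
#'   `lr` (fraction) filled.
#' @return Data frame with `taxon`, `sample`, `replicate`,
#'   `median_RIA_pct`, `median_LR_pct`.
#' @export
median_ria_lr <- function(evidence) {
  ev <- evidence[lengths(evidence$taxa) > 0L, , drop = FALSE]
  out <- list()
  for (grp in split(seq_len(nrow(ev)), .by_sample(ev))) {
    sub <- ev[grp, , drop = FALSE]
    taxa <- sort(unique(unlist(sub$taxa, use.names = FALSE)))
    for (tx in taxa) {
      has <- vapply(sub$taxa, function(t) tx %in% t, logical(1))
      lab <- has & !sub$shared & sub$labeled
      out[[length(out) + 1L]] <- data.frame(
        taxon = tx, sample = sub$sample[1], replicate = sub$replicate[1],
        median_RIA_pct = if (any(lab)) 100 * stats::median(sub$ria_top[lab]) else NA_real_,
        median_LR_pct = if (any(lab)) 100 * stats::median(sub$lr[lab]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(taxon = character(0), sample = character(0),
                      replicate = integer(0), median_RIA_pct = numeric(0),
                      median_LR_pct = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full per-taxon summary table
#'
#' Joins intensity quantification, relative abundance, labeled-peptide counts
#' (RA) and median RIA/LR into one table per taxon, sample and replicate.
#'
#' @param evidence Evidence with `taxa` and `shared` filled.
#' @return Data frame with columns `taxon`, `sample`, `replicate`, `INT`,
#'   `rel_abundance`, `n_labeled`, `n_unlabeled`, `n_shared_labeled`, `RA`,
#'   `median_RIA_pct`, `median_LR_pct`.
#' @export
taxon_summary <- function(evidence) {
  int <- relative_abundance(apportion_intensities(evidence))
  ra <- relative_count_labeled(evidence)
  med <- median_ria_lr(evidence)
  key <- function(d) paste(d$taxon, d$sample, d$replicate, sep = "\r")
  res <- int
  res[, c("n_labeled", "n_unlabeled", "n_shared_labeled", "RA")] <-
    ra[match(key(int), key(ra)), c("n_labeled", "n_unlabeled", "n_shared_labeled", "RA")]
  res[, c("median_RIA_pct", "median_LR_pct")] <-
    med[match(key(int), key(med)), c("median_RIA_pct", "median_LR_pct")]
  res[order(res$sample, res$replicate, -res$INT), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Significance stars for p values
#'
#' @param p Numeric vector of p values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `""`.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Compare a metric between two conditions by Student's t test
#'
#' Equal-variance two-sample Student's t test on replicate values (Welch
#' available via `var_equal = FALSE`). Groups that are both constant are
#' handled in closed form: identical means give t = 0, p = 1; different means
#' with zero pooled variance give p = 0.
#'
#' @param values_a,values_b Numeric replicate values per condition (each of
#'   length >= 2, otherwise the comparison is skipped with a warning).
#' @param var_equal Use the pooled-variance Student's t (default TRUE).
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `p`, `stars`.
#' @export
compare_conditions <- function(values_a, values_b, var_equal = TRUE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  base <- list(mean_a = mean(values_a), sd_a = stats::sd(values_a),
               mean_b = mean(values_b), sd_b = stats::sd(values_b))
  if (length(values_a) < 2L || length(values_b) < 2L) {
    warning("fewer than 2 replicates in a condition; comparison skipped")
    return(c(base, list(t = NA_real_, p = NA_real_, stars = "")))
  }
  pooled_var <- (sum((values_a - mean(values_a))^2) +
                   sum((values_b - mean(values_b))^2)) /
    (length(values_a) + length(values_b) - 2L)
  if (pooled_var == 0) {
    if (base$mean_a == base$mean_b) {
      t <- 0; p <- 1
    } else {
      t <- sign(base$mean_a - base$mean_b) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  c(base, list(t = t, p = p, stars = p_stars(p)))
}

#' Mean and standard deviation across replicates
#'
#' @param summaries A [taxon_summary()] result (replicates stacked).
#' @param metrics Metric columns to aggregate.
#' @return Long data frame with `taxon`, `sample`, `metric`, `mean`, `sd`,
#'   `n_replicates`, `single_replicate` (flag; single-replicate SD is
#'   reported as 0).
#' @export
replicate_aggregate <- function(summaries,
                                metrics = c("rel_abundance", "RA",
                                            "median_RIA_pct", "median_LR_pct")) {
  out <- list()
  for (grp in split(seq_len(nrow(summaries)),
                    interaction(summaries$taxon, summaries$sample,
                                drop = TRUE, lex.order = TRUE))) {
    sub <- summaries[grp, , drop = FALSE]
    for (mname in metrics) {
      v <- sub[[mname]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      out[[length(out) + 1L]] <- data.frame(
        taxon = sub$taxon[1], sample = sub$sample[1], metric = mname,
        mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
        n_replicates = length(v), single_replicate = length(v) == 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(taxon = character(0), sample = character(0),
                      metric = character(0), mean = numeric(0), sd = numeric(0),
                      n_replicates = integer(0), single_replicate = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
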