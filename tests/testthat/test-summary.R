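# Taxon-level aggregation: intensity apportionment, RA, medians, statistics.

test_that("shared intensities are apportioned proportionally to same-class counts", {
  # taxon A: 4 unlabeled peptides (incl the shared one), taxon B: 1 (the shared one)
  ev <- flagged_evidence(
    peptide = c(sprintf("AONLY%dK", 1:3), "SHAREDK"),
    intensity = c(10, 10, 10, 100),
    labeled = FALSE,
    taxa = c(rep(list("A"), 3), list(c("A", "B"))))
  int <- apportion_intensities(ev)
  expect_equal(int$INT[int$taxon == "A"], 30 + 80)
  expect_equal(int$INT[int$taxon == "B"], 20)
  # conservation
  expect_equal(sum(int$INT), sum(ev$intensity))
})

test_that("apportionment conserves intensity on random fixtures", {
  set.seed(19)
  taxa_pool <- c("A", "B", "C")
  for (i in 1:10) {
    n <- sample(5:20, 1)
    ev <- flagged_evidence(
      peptide = sprintf("P%02dK", seq_len(n)),
      intensity = runif(n, 1, 100),
      labeled = sample(c(TRUE, FALSE), n, replace = TRUE),
      taxa = lapply(seq_len(n), function(j)
        sort(sample(taxa_pool, sample(1:3, 1)))))
    int <- apportion_intensities(ev)
    expect_equal(sum(int$INT), sum(ev$intensity))
    expect_true(all(int$INT >= 0))
  }
})

test_that("relative abundances are fractions summing to one per sample", {
  int <- data.frame(taxon = c("A", "B"), sample = "S1", replicate = 1L,
                    INT = c(75, 25))
  ra <- relative_abundance(int)
  expect_equal(ra$rel_abundance, c(0.75, 0.25))
  one <- relative_abundance(data.frame(taxon = "A", sample = "S1",
                                       replicate = 1L, INT = 42))
  expect_equal(one$rel_abundance, 1)
  expect_warning(z <- relative_abundance(data.frame(taxon = "A", sample = "S1",
                                                    replicate = 1L, INT = 0)),
                 "zero total")
  expect_true(is.na(z$rel_abundance))
})

test_that("RA is the non-shared labeled fraction, NA when undefined", {
  ev <- flagged_evidence(
    peptide = sprintf("P%dK", 1:4), intensity = 1,
    labeled = c(TRUE, TRUE, TRUE, FALSE),
    taxa = rep(list("A"), 4))
  expect_equal(relative_count_labeled(ev)$RA, 0.75)

  # labeled peptides all shared: RA = 0 from the 5 unlabeled non-shared ones
  ev2 <- flagged_evidence(
    peptide = sprintf("P%dK", 1:7), intensity = 1,
    labeled = c(TRUE, TRUE, rep(FALSE, 5)),
    taxa = c(list(c("A", "B")), list(c("A", "B")), rep(list("A"), 5)))
  ra2 <- relative_count_labeled(ev2)
  expect_equal(ra2$RA[ra2$taxon == "A"], 0)
  expect_equal(ra2$n_shared_labeled[ra2$taxon == "A"], 2L)
  # taxon B has only shared peptides: RA undefined, not 0
  expect_true(is.na(ra2$RA[ra2$taxon == "B"]))
})

test_that("median RIA/LR use the highest RIA per peptide, non-shared labeled only", {
  # one peptide whose components are {natural, 12.5%}: ria_top is 12.5%
  ev <- flagged_evidence("PK", 1, TRUE, list("A"), ria_top = 0.125, lr = 0.5)
  m <- median_ria_lr(ev)
  expect_equal(m$median_RIA_pct, 12.5)
  expect_equal(m$median_LR_pct, 50)

  ev3 <- flagged_evidence(sprintf("P%dK", 1:3), 1, TRUE, rep(list("A"), 3),
                          ria_top = c(0.10, 0.12, 0.14), lr = 0.5)
  expect_equal(median_ria_lr(ev3)$median_RIA_pct, 12)
  # even count: mean of the middle two
  ev4 <- flagged_evidence(sprintf("P%dK", 1:2), 1, TRUE, rep(list("A"), 2),
                          ria_top = c(0.10, 0.14), lr = c(0.4, 0.6))
  expect_equal(median_ria_lr(ev4)$median_RIA_pct, 12)
  # shared labeled peptides are excluded; none non-shared -> NA
  ev5 <- flagged_evidence("PK", 1, TRUE, list(c("A", "B")), ria_top = 0.2, lr = 0.5)
  expect_true(all(is.na(median_ria_lr(ev5)$median_RIA_pct)))
  # permutation invariance
  expect_equal(median_ria_lr(ev3[c(3, 1, 2), ])$median_RIA_pct, 12)
})

test_that("Student's t comparisons map p values to stars", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")

  shift <- compare_conditions(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.001)
  expect_equal(shift$stars, "***")
  # agreement with the closed form: t = diff / (sp * sqrt(1/n + 1/m))
  sp <- 1  # pooled sd of two sd-1 samples
  expect_equal(shift$t, -10 / (sp * sqrt(2 / 3)), tolerance = 1e-12)

  # zero pooled variance with different means
  zv <- compare_conditions(c(5, 5, 5), c(7, 7, 7))
  expect_equal(zv$p, 0)
  expect_equal(zv$stars, "***")

  expect_equal(p_stars(c(0.03, 0.009, 0.0005, 0.2)), c("*", "**", "***", ""))
  expect_warning(skip <- compare_conditions(1, c(1, 2)), "fewer than 2")
  expect_true(is.na(skip$p))
})

test_that("replicate aggregation reports mean +- sd with single-replicate flag", {
  summ <- data.frame(taxon = "A", sample = "S1", replicate = 1:3,
                     rel_abundance = NA, RA = NA, median_RIA_pct = NA,
                     median_LR_pct = c(50, 52, 54))
  agg <- replicate_aggregate(summ)
  expect_equal(agg$mean, 52)
  expect_equal(agg$sd, 2)
  single <- replicate_aggregate(summ[1, ])
  expect_equal(single$sd, 0)
  expect_true(single$single_replicate)
  expect_equal(nrow(replicate_aggregate(summ[0, ])), 0L)
})

test_that("taxon summary joins abundance, RA and medians per taxon", {
  ev <- flagged_evidence(
    peptide = c(sprintf("A%dK", 1:4), sprintf("B%dK", 1:2)),
    intensity = c(10, 10, 20, 20, 30, 10),
    labeled = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    taxa = c(rep(list("GA"), 4), rep(list("GB"), 2)),
    ria_top = c(0.12, 0.14, NA, NA, NA, NA),
    lr = c(0.4, 0.6, NA, NA, NA, NA))
  ts <- taxon_summary(ev)
  expect_equal(nrow(ts), 2L)
  ga <- ts[ts$taxon == "GA", ]
  expect_equal(ga$INT, 60)
  expect_equal(ga$rel_abundance, 0.6)
  expect_equal(ga$RA, 0.5)
  expect_equal(ga$median_RIA_pct, 13)
  expect_equal(ga$median_LR_pct, 50)
  gb <- ts[ts$taxon == "GB", ]
  expect_equal(gb$RA, 0)
  expect_true(is.na(gb$median_RIA_pct))
  expect_equal(sum(ts$rel_abundance), 1)
})
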