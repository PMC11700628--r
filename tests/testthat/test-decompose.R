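# Envelope decomposition: anchor detection, RIA/LR recovery, failure modes.

zero_noise_sim <- function(labeled_share, seed = 11, n_pep = 5,
                           ria = benzoate_label_spec()$ria) {
  ref <- make_reference(1, seed = 7)
  spec <- community_spec(
    taxa = data.frame(accession = "SYN001", abundance = 1, ria = ria,
                      labeled_share = labeled_share),
    peptides_per_taxon = n_pep, intensity_cv = 0, mz_ppm = 0, seed = seed)
  simulate_community(spec, ref)
}

test_that("a purely natural envelope yields one unlabeled component with LR 0", {
  et <- element_table("C")
  f <- peptide_formula("SAMPLEPEPTLDEK")
  p <- natural_pattern(f, et)
  env <- data.frame(mz = (p$mono_mass + p$offset * et$offset_spacing) / 2 + 1.007276466,
                    intensity = 1e6 * p$intensity)
  cmp <- decompose_envelope(env, f, et, charge = 2)
  expect_length(cmp$flag, 0)
  expect_equal(nrow(cmp$components), 1L)
  expect_equal(cmp$components$ria, et$natural_ria)
  expect_equal(cmp$lr, 0)
  expect_false(is_labeled(cmp))
})

test_that("zero-noise 1:1 mixtures are inverted to the true RIA and LR", {
  et <- element_table("C")
  sim <- zero_noise_sim(0.5)
  ev <- decompose_envelopes(sim$envelopes, et)
  expect_equal(nrow(ev), nrow(sim$truth_peptides))
  expect_true(all(ev$labeled))
  # RIA within one grid step of 1/7 (refinement brings it much closer)
  expect_true(all(abs(ev$ria_top - 1 / 7) < 0.005))
  expect_true(all(abs(ev$lr - 0.5) < 1e-6))
})

test_that("fully labeled envelopes have no unlabeled anchor and are not reported", {
  et <- element_table("C")
  sim <- zero_noise_sim(1)
  first <- sim$envelopes[sim$envelopes$peptide == sim$envelopes$peptide[1], ]
  f <- peptide_formula(first$peptide[1])
  cmp <- decompose_envelope(first[, c("mz", "intensity")], f, et,
                            charge = first$charge[1])
  expect_equal(cmp$flag, "no_unlabeled_anchor")
  expect_equal(nrow(cmp$components), 0L)
  expect_false(is_labeled(cmp))
  expect_true(is.na(labeling_ratio(cmp)))
  expect_message(ev <- decompose_envelopes(sim$envelopes, et), "without unlabeled anchor")
  expect_equal(nrow(ev), 0L)
})

test_that("labeling ratio is the labeled weight fraction", {
  nat <- element_table("C")$natural_ria
  mk <- function(ria, weight) {
    structure(list(components = data.frame(ria = ria, weight = weight,
                                           correlation = 1,
                                           centroid_mass = seq_along(ria)),
                   lr = NA, flag = character(0), total_intensity = 1,
                   n_unassigned = 0L), class = "sip_components")
  }
  expect_equal(labeling_ratio(mk(nat, 1)), 0)
  expect_equal(labeling_ratio(mk(c(nat, 0.15), c(0.5, 0.5))), 0.5)
  expect_equal(labeling_ratio(mk(c(nat, 0.1, 0.2), c(0.4, 0.3, 0.3))), 0.6)
  expect_true(is_labeled(mk(c(nat, 0.15), c(0.5, 0.5))))
  expect_false(is_labeled(mk(nat, 1)))
})

test_that("decomposition recovers RIA and LR under the default noise model", {
  et <- element_table("C")
  ref <- make_reference(1, seed = 7)
  spec <- community_spec(
    taxa = data.frame(accession = "SYN001", abundance = 1,
                      ria = benzoate_label_spec()$ria, labeled_share = 0.5),
    peptides_per_taxon = 15, seed = 29)
  sim <- simulate_community(spec, ref)
  ev <- decompose_envelopes(sim$envelopes, et)
  expect_gt(nrow(ev), 10)
  expect_lt(abs(stats::median(ev$lr) - 0.5), 0.05)
  expect_lt(abs(stats::median(ev$ria_top) - 1 / 7), 0.01)
})

test_that("estimated LR is monotone in the labeled share", {
  et <- element_table("C")
  meds <- vapply(c(0.2, 0.4, 0.6, 0.8), function(s) {
    ref <- make_reference(1, seed = 7)
    spec <- community_spec(
      taxa = data.frame(accession = "SYN001", abundance = 1,
                        ria = benzoate_label_spec()$ria, labeled_share = s),
      peptides_per_taxon = 8, seed = 5)
    ev <- decompose_envelopes(simulate_community(spec, ref)$envelopes, et)
    stats::median(ev$lr)
  }, numeric(1))
  expect_false(is.unsorted(meds))
})

test_that("unassignable peaks are ignored with a warning and inputs are validated", {
  et <- element_table("C")
  f <- peptide_formula("SAMPLEPEPTLDEK")
  p <- natural_pattern(f, et)
  mz <- (p$mono_mass + p$offset * et$offset_spacing) / 2 + 1.007276466
  env <- data.frame(mz = c(mz, max(mz) + 0.31), intensity = c(1e6 * p$intensity, 5e4))
  expect_warning(cmp <- decompose_envelope(env, f, et, charge = 2), "ppm tolerance")
  expect_equal(cmp$n_unassigned, 1L)
  expect_equal(nrow(cmp$components), 1L)

  expect_error(decompose_envelope(env[1, ], f, et), "at least 2")
  expect_error(decompose_envelope(data.frame(mz = c(2, 1), intensity = c(1, 1)), f, et),
               "increasing")
})
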