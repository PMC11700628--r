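---
title: "GroEL-SIP: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GroEL-SIP: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groelsip)
```

## The problem

Protein stable isotope probing (protein-SIP) links microbial taxa to the
assimilation of an isotopically labeled substrate: atoms from the substrate
(2H, 13C, 18O) appear in newly synthesized proteins and shift peptide isotope
envelopes in MS1 spectra. Conventional protein-SIP needs a sample-specific
metagenome-derived database. `groelsip` instead reads the signal off a single
near-universal bacterial marker protein, the chaperonin GroEL (~60 kDa):
a sample-independent GroEL reference is digested in silico, identified GroEL
peptides are assigned to taxa, and per-peptide isotope incorporation is
estimated from the envelopes. The output is, per taxon and sample: an
intensity-based relative abundance, the relative count of labeled peptides
(RA, the activity proxy), and median relative isotope abundance (RIA) and
labeling ratio (LR).

## Isotopologue model

A peptide's elemental composition is the sum of its residue formulas plus one
water, with carbamidomethyl-cysteine as a static and oxidized methionine as an
optional per-instance modification. The isotopologue distribution over
nominal mass offsets is the convolution of per-element isotope distributions
(binomial for two-isotope elements, convolution powers of the single-atom
distribution for O and S). A *labeled* peptide is modeled by raising the
heavy-isotope abundance of the label element to the RIA, scaling the lighter
isotopes proportionally; everything else is unchanged. Distributions are
truncated to retain at least `1 - tail` of the mass (default 99.9%) and
renormalized.

Offsets are converted to the neutral-mass axis with a label-specific spacing
(1.00336 Da per offset for 13C, 1.00628 for 2H, 2.00425/2 for 18O). This
nominal-grid treatment ignores isotopic fine structure, which is well below
the ±5 ppm assignment tolerance for tryptic peptides.

## Envelope decomposition

Observed peaks are deconvoluted by charge and assigned to offsets within
±5 ppm. Decomposition then proceeds in the order:

1. **Unlabeled anchor.** The natural-abundance template must correlate with
   the envelope over its own support at Pearson `r >= 0.7`. Without the
   anchor, nothing is reported: a fully labeled sample therefore yields *no*
   identifications, which is a structural property of the method, not a bug —
   labeled/unlabeled extracts are mixed (1:1 by default) precisely to
   guarantee the anchor.
2. **RIA grid scan.** Labeled templates on a grid from the natural abundance
   to 1 (step 0.005) are correlated against the residual after removing the
   fitted anchor. Local maxima with `r >= 0.7` become candidate components;
   each is refined by local correlation maximization within one grid step.
   The 0.5% step resolves the 1–2% RIA differences that matter in diet or
   pathway comparisons while keeping the scan cheap.
3. **Merging.** Candidates whose template centroid masses lie within the
   label-specific merge window (±1.5 Da for 2H, ±5.0 Da for 13C/18O) of an
   accepted component are merged into it.
4. **Weights.** Component weights are solved by non-negative least squares of
   the accepted templates against the envelope and normalized; weights are
   re-estimated after re-refining each labeled component's RIA against the
   residual of the other components (two passes), which removes the bias the
   anchor-only residual carries when labeled and natural patterns overlap.
   `LR = sum of labeled weights`. At zero noise the round trip recovers RIA
   to ~1e-8 and LR to better than 1e-6.

Tunable parameters (all in `decompose_config()`): grid step (fraction,
0.005), minimum correlation (0.7), ppm tolerance (5), merge window (Da,
label-specific default), truncation tail (1e-3).

## Grouping, Top Rank Count and taxa

Entries of the deduplicated reference whose supporting peptide sets are
identical form one protein group. For every peptide, all groups containing it
are ranked by distinct peptide count; each group attaining the maximum gets
one increment (ties all score — the simplest deterministic rule, exposed in
the API), and groups with Top Rank Count < 5 are discarded as likely false
positives. Taxonomy is inferred per group at genus (defined bicultures) or
family (complex communities) rank; members must agree at the rank after
merge rules (Shigella folds into Escherichia, the two being
indistinguishable by GroEL peptides), otherwise the group is reported
"unclassified" at that rank with the deepest agreeing coarser rank as
fallback.

One design point was genuinely open: whether group support should use only
evidence without any labeled component. Since a labeled peptide can only be
identified when its unlabeled version is present, every identified peptide
contributes an identified unlabeled peptide; restricting support to
never-labeled rows would leave heavily labeled (but perfectly identified)
taxa below the Top Rank Count threshold and unreportable. Default grouping
therefore uses all identified evidence; `build_protein_groups(...,
unlabeled_only = TRUE)` gives the restrictive variant.

A peptide is **shared** when its matched entries map to more than one
*retained* taxon (filtered-out groups are treated as false positives and do
not make a peptide shared). Shared intensity is apportioned proportionally to
each taxon's count of same-class (labeled/unlabeled) assigned peptides. RA
and the median RIA/LR are computed over non-shared peptides only; medians use
the highest detected RIA per peptide (and its LR), with the mean-of-middle
convention for even counts. Shared labeled peptides are counted separately
(`n_shared_labeled`) rather than entering the medians, keeping the activity
metrics specific to unambiguous evidence. Replicate means are compared with
the equal-variance Student's t test (Welch switchable); constant groups are
handled in closed form (identical means: t = 0, p = 1). Single-replicate
standard deviations are reported as 0 with an explicit flag so tables stay
rectangular.

## The synthetic-data generator

`make_reference()` builds chaperonin-sized sequences (~540 residues) from
unique tryptic blocks (8–18 residues ending in K/R; no internal K/R/P, no I
so isobaric collapse cannot blur the ground truth); designated taxon pairs
share an exact, planned number of blocks, and a ledger records every block's
true taxa. `simulate_community()` samples peptides from each taxon's digest
and emits envelopes as `labeled_share`-weighted sums of natural and labeled
patterns, scaled by taxon abundance and a lognormal peptide intensity factor.
Default noise is multiplicative Gaussian with 5% CV on intensities and
uniform ±2 ppm m/z jitter; both are configurable and zero-noise runs are
exact. All randomness is fixed by the spec's seed.

Two independence guarantees make round-trip tests non-circular: the
generator builds patterns by exact enumeration over isotopologue
compositions (multinomial log-weights, outer-sum aggregation across
elements), sharing no code with the forward model's convolution; and the test
suite carries a third, per-atom exhaustive enumerator for tiny formulas that
checks both.

What the generator does *not* emulate: chromatography and feature finding,
MS2 identification and FDR, co-eluting interferences, missing peaks at low
signal, or sequences absent from the reference. Passing tests therefore
demonstrate correctness of the inference given identified peptides and clean
envelopes, not robustness to search-engine errors or database incompleteness.

## Problem sizes and numerical choices

The validation suite simulates 200 peptides per mixing condition (25/50/75/
100% labeled protein share) with default noise — enough for stable medians at
a few seconds per condition — and checks that the median estimated LR tracks
the labeled share within the replicate scatter reported for such designs,
and that the 100% condition reports nothing. Degenerate inputs are defined
throughout: empty references and evidence tables propagate as empty results;
envelopes need at least two peaks and strictly increasing m/z; peptides with
residues lacking an elemental formula (X, U) are indexed for matching but
skipped by formula-based operations with a warning; RA with a zero
denominator is missing, not zero.

## Limitations

Taxonomic resolution is bounded by GroEL sequence conservation (genus in
defined cultures, family in communities); perfect-match indexing means
non-sequenced organisms lower the Top Rank Count and can drop below the
filter; only single-element, single-heavy-isotope labels are modeled; and
the natural-abundance baseline is configurable but assumed constant across
taxa.
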