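# Protein grouping, Top Rank Count filtering and taxonomy inference.

test_that("evidence matching canonicalizes peptides and drops unmatched rows", {
  ref <- toy_reference(c("MMMILKAAAR", "VVVEEEKGGGGGR"))
  idx <- build_index(ref)
  tbl <- data.frame(
    peptide = c("MMMILK", "MMMLLK", "VVVEEEK", "GGGGGR", "NOTTHERE"),
    intensity = c(10, 20, 30, 40, 50))
  expect_message(ev <- match_evidence(tbl, idx), "1 peptide")
  expect_equal(nrow(ev), 4L)
  # I/L collapse: both spellings hit the same entry
  expect_equal(ev$entries[[1]], "T001")
  expect_equal(ev$entries[[2]], "T001")
  expect_equal(ev$peptide[1], ev$peptide[2])

  expect_equal(nrow(match_evidence(data.frame(peptide = character(0),
                                              intensity = numeric(0)), idx)), 0L)
})

test_that("malformed evidence rows are skipped, or fatal beyond 50%", {
  ref <- toy_reference("MMMILKAAAR")
  idx <- build_index(ref)
  tbl <- data.frame(peptide = c("MMMLLK", "", "MMMLLK"),
                    intensity = c(10, 5, 20))
  expect_warning(ev <- match_evidence(tbl, idx), "malformed")
  expect_equal(nrow(ev), 2L)
  tbl2 <- data.frame(peptide = c("", ""), intensity = c(NA, 1))
  expect_error(suppressWarnings(match_evidence(tbl2, idx)), "50%")
})

test_that("protein groups merge entries with identical peptide sets only", {
  # identical support -> one group
  ev <- toy_evidence(c("PEPTLDEK", "ELVLSEK"),
                     list(c("A1", "A2"), c("A1", "A2")))
  g <- build_protein_groups(ev)
  expect_equal(nrow(g), 1L)
  expect_setequal(g$accessions[[1]], c("A1", "A2"))

  # nested, not identical -> two groups
  ev2 <- toy_evidence(c("P1AAAK", "P2AAAK", "P3AAAK"),
                      list(c("A", "B"), c("A", "B"), "B"))
  g2 <- build_protein_groups(ev2)
  expect_equal(nrow(g2), 2L)
  expect_equal(sort(g2$n_peptides), c(2L, 3L))

  # labeled evidence builds groups by default (its unlabeled anchor is an
  # identified unlabeled peptide) but not in unlabeled-only mode
  ev3 <- toy_evidence(c("P1AAAK", "P2AAAK"), list("A", "A"),
                      labeled = c(TRUE, TRUE))
  expect_equal(nrow(build_protein_groups(ev3)), 1L)
  expect_equal(nrow(build_protein_groups(ev3, unlabeled_only = TRUE)), 0L)
  # no evidence at all -> zero groups, hence zero taxa
  expect_equal(nrow(build_protein_groups(ev3[0, ])), 0L)
})

test_that("Top Rank Count ranks groups by peptide count with ties all scoring", {
  # single unopposed group: TRC = peptide count
  ev <- toy_evidence(sprintf("PEP%dAAAK", 1:4), rep(list("A"), 4))
  g <- top_rank_count(build_protein_groups(ev))
  expect_equal(g$top_rank_count, 4L)

  # A has 5 peptides incl shared s, B has s plus one more: TRC A=5, B=1
  evA <- toy_evidence(c(sprintf("AONLY%dK", 1:4), "SHAREDK"),
                      c(rep(list("A"), 4), list(c("A", "B"))))
  evB <- toy_evidence("BONLYK", list("B"))
  g2 <- top_rank_count(build_protein_groups(rbind(evA, evB)))
  trc <- setNames(g2$top_rank_count,
                  vapply(g2$accessions, paste, character(1), collapse = ""))
  expect_equal(trc[["A"]], 5L)
  expect_equal(trc[["B"]], 1L)

  # tie: equal-sized groups sharing s are both incremented
  evT <- rbind(
    toy_evidence(c("XONLY1K", "XONLY2K", "SHAREDK"),
                 list("X", "X", c("X", "Y"))),
    toy_evidence(c("YONLY1K", "YONLY2K"), list("Y", "Y")))
  gT <- top_rank_count(build_protein_groups(evT))
  expect_equal(sort(gT$top_rank_count), c(3L, 3L))
  # TRC conservation: sum >= number of distinct peptides
  expect_gte(sum(gT$top_rank_count), length(unique(evT$peptide)))
})

test_that("group filtering keeps Top Rank Count >= threshold", {
  ladder <- toy_groups(1:10)
  kept <- suppressMessages(filter_groups(ladder, 5))
  expect_equal(sort(kept$top_rank_count), 5:10)
  expect_equal(min(kept$top_rank_count), 5L)
  expect_equal(nrow(filter_groups(ladder, 1)), 10L)
  expect_equal(nrow(filter_groups(ladder[0, ], 5)), 0L)
  # monotonicity: raising the threshold never adds a group
  sizes <- vapply(1:11, function(th)
    nrow(suppressMessages(filter_groups(ladder, th))), integer(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("taxon inference agrees at rank, merges Escherichia/Shigella, falls back via LCA", {
  lineage <- data.frame(
    accession = c("E1", "E2", "S1", "T1", "T2", "F1", "F2"),
    superkingdom = "Bacteria", phylum = "P", class = "C",
    order = c(rep("Enterobacterales", 3), "Rhodocyclales", "Rhodocyclales",
              "SameOrder", "SameOrder"),
    family = c(rep("Enterobacteriaceae", 3), "Rhodocyclaceae", "Rhodocyclaceae",
               "FamA", "FamB"),
    genus = c("Escherichia", "Escherichia", "Shigella", "Thauera", "Thauera",
              "GenA", "GenB"),
    species = "sp.", stringsAsFactors = FALSE)
  grp <- function(accs) {
    g <- toy_groups(5, accessions = list(accs))
    g[1, , drop = FALSE]
  }
  expect_equal(infer_taxon(grp(c("T1", "T2")), "genus", lineage)$taxon, "Thauera")
  mrg <- infer_taxon(grp(c("E1", "S1")), "genus", lineage)
  expect_equal(mrg$taxon, "Escherichia")
  # two families at family rank: unclassified, reported at order
  fb <- infer_taxon(grp(c("F1", "F2")), "family", lineage)
  expect_equal(fb$taxon, "unclassified")
  expect_equal(fb$fallback_rank, "order")
  expect_equal(fb$fallback_taxon, "SameOrder")
  # all-empty lineage -> unclassified
  lineage0 <- lineage
  lineage0[lineage0$accession == "T1", groelsip:::.RANKS] <- ""
  expect_equal(infer_taxon(grp("T1"), "genus", lineage0)$taxon, "unclassified")
})

test_that("shared flags count retained taxa only; labeled evidence is attached", {
  retained <- toy_groups(c(6, 7), accessions = list("A", "B"),
                         taxon = c("GenusA", "GenusB"))
  ev <- flag_shared(
    toy_evidence(c("ONETAXONK", "TWOTAXAK", "FILTEREDK", "LABELEDK"),
                 list("A", c("A", "B"), c("A", "Z"), "B"),
                 labeled = c(FALSE, FALSE, FALSE, TRUE)),
    retained)
  expect_equal(ev$shared, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(ev$taxa[[2]], c("GenusA", "GenusB"))
  # entry Z belongs to a filtered-out group: only the retained taxon counts
  expect_equal(ev$taxa[[3]], "GenusA")
  # labeled evidence is attributed to retained taxa
  expect_equal(ev$taxa[[4]], "GenusB")
  # evidence matching no retained entry is unassigned
  expect_message(ev0 <- flag_shared(toy_evidence("LOSTK", list("Z")), retained),
                 "not assignable")
  expect_equal(ev0$n_taxa, 0L)
})

test_that("grouping and ranking are invariant under evidence row order", {
  set.seed(3)
  ev <- rbind(
    toy_evidence(c(sprintf("AONLY%dK", 1:5), "SHAREDK"),
                 c(rep(list("A"), 5), list(c("A", "B")))),
    toy_evidence(c(sprintf("BONLY%dK", 1:3)), rep(list("B"), 3)))
  ref_g <- top_rank_count(build_protein_groups(ev))
  for (i in 1:5) {
    perm <- ev[sample(nrow(ev)), , drop = FALSE]
    g <- top_rank_count(build_protein_groups(perm))
    expect_equal(g$top_rank_count, ref_g$top_rank_count)
    expect_equal(g$peptides, ref_g$peptides)
  }
})
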