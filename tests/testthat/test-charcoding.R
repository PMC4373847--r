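test_that("association characters record units joined on one chromosome", {
  maps <- phyllostomini_maps()
  ks <- phyllostomini_karyotypes()
  tsa <- synteny_partition(maps$TSAxPHA)
  assoc <- derive_association_characters(list(tsa), ks$PHA)
  # PHA-3 and PHA-4 travel together on TSA-1 and TSA-4
  expect_true("A.PHA-3+PHA-4" %in% colnames(assoc$states))
  expect_identical(assoc$states["TSA", "A.PHA-3+PHA-4"], "1")

  # a taxon whose partition is all singletons scores 0 everywhere it is
  # detected: add the reference's identity map
  pha <- synteny_partition(identity_map(ks$PHA))
  assoc2 <- derive_association_characters(list(tsa, pha), ks$PHA)
  pha_row <- assoc2$states["PHA", ]
  expect_true(all(pha_row[pha_row != "?"] == "0"))

  # identical partitions give identical state rows
  tsa2 <- tsa
  tsa2$taxon <- "PDI"
  assoc3 <- derive_association_characters(list(tsa, tsa2))
  expect_identical(unname(assoc3$states["TSA", ]),
                   unname(assoc3$states["PDI", ]))

  # mixed probe panels are rejected
  cbr <- synteny_partition(maps$TSAxCBR)
  expect_error(derive_association_characters(list(tsa, cbr)),
               "mixed probe species")
})

test_that("disruption characters separate split from conserved units", {
  maps <- phyllostomini_maps()
  ks <- phyllostomini_karyotypes()
  use <- list(maps$TSAxPHA, maps$LSIxPHA, identity_map(ks$PHA))
  parts <- lapply(use, synteny_partition)
  disr <- derive_disruption_characters(parts, use, ks$PHA)
  # PHA-13 fissioned in both TSA and LSI, intact in the reference
  expect_identical(disr$states["TSA", "D.PHA-13"], "1")
  expect_identical(disr$states["LSI", "D.PHA-13"], "1")
  expect_identical(disr$states["PHA", "D.PHA-13"], "0")
  # PHA-14 conserved in toto everywhere it was painted
  expect_false("D.PHA-14" %in% colnames(disr$states))
  # PHA-5: one chromosome but two discontiguous blocks in TSA -> disrupted
  expect_identical(disr$states["TSA", "D.PHA-5"], "1")
  expect_identical(disr$states["LSI", "D.PHA-5"], "0")
})

test_that("undetected units score ? rather than 0", {
  maps <- phyllostomini_maps()
  use <- list(maps$TSAxPHA, maps$PDIxPHA)
  parts <- lapply(use, synteny_partition)
  assoc <- derive_association_characters(parts)
  # PDI was only probed with PHA-14/PHA-15: every association among other
  # units is unknown for it, not absent
  expect_true(all(assoc$states["PDI", ] == "?"))
  disr <- derive_disruption_characters(parts, use)
  expect_true(all(disr$states["PDI", !grepl("PHA-14|PHA-15",
                                            colnames(disr$states))] == "?"))
})

test_that("structural characters append after synteny characters in order", {
  maps <- phyllostomini_maps()
  ks <- phyllostomini_karyotypes()
  use <- list(maps$TSAxPHA, maps$LSIxPHA, maps$PDIxPHA, identity_map(ks$PHA))
  parts <- lapply(use, synteny_partition)
  assoc <- derive_association_characters(parts, ks$PHA)
  disr <- derive_disruption_characters(parts, use, ks$PHA)
  ann <- phyllostomini_annotations()
  cm <- merge_structural_characters(ann, assoc, disr)
  kinds <- vapply(cm$defs, `[[`, "", "kind")
  expect_identical(unique(kinds),
                   c("association", "disruption", "structural"))
  ids <- colnames(cm$states)
  for (kd in unique(kinds)) {
    expect_false(is.unsorted(ids[kinds == kd]))
  }
  expect_identical(length(cm$defs), ncol(assoc$states) + ncol(disr$states) +
                     length(unique(ann$character_id)))
  # the pericentric inversion of pair 15 separates PDI from PHA and LSI
  expect_identical(cm$states["PDI", "S.pair15-biarmed"], "1")
  expect_identical(cm$states["PHA", "S.pair15-biarmed"], "0")
  expect_identical(cm$states["LSI", "S.pair15-biarmed"], "0")

  # empty annotation table: derived characters only
  cm0 <- merge_structural_characters(NULL, assoc, disr)
  expect_identical(length(cm0$defs), ncol(assoc$states) + ncol(disr$states))

  # duplicate (taxon, character) rows and bad states are rejected
  dup <- ann[c(1L, 1L), ]
  expect_error(merge_structural_characters(dup, assoc, disr), "duplicate")
  bad <- ann
  bad$state[1L] <- "2"
  expect_error(merge_structural_characters(bad, assoc, disr), "outside")
})

test_that("character derivation is deterministic and taxon-order invariant", {
  maps <- phyllostomini_maps()
  use <- list(maps$TSAxPHA, maps$LSIxPHA)
  parts <- lapply(use, synteny_partition)
  a1 <- derive_association_characters(parts)
  a2 <- derive_association_characters(rev(parts))
  expect_identical(colnames(a1$states), colnames(a2$states))
  expect_identical(a1$states, a2$states[rownames(a1$states), , drop = FALSE])
})

test_that("parsimony-informative characters are counted by the 2+2 rule", {
  st <- matrix(c("1", "1", "0", "0"), 4L, 1L,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_identical(count_informative(toy_matrix(st)), 1L)
  # matrix of autapomorphies only
  st2 <- diag(4L)
  st2 <- ifelse(st2 == 1, "1", "0")
  rownames(st2) <- c("A", "B", "C", "D")
  expect_identical(count_informative(toy_matrix(st2)), 0L)
  # ? does not count toward either side
  st3 <- matrix(c("1", "1", "0", "?"), 4L, 1L,
                dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_identical(count_informative(toy_matrix(st3)), 0L)
})

test_that("NEXUS and TSV round trips preserve taxa, characters and states", {
  maps <- phyllostomini_maps()
  cm <- code_characters(list(maps$TSAxPHA, maps$LSIxPHA),
                        phyllostomini_annotations()[1:3, ])
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(cm, nex)
  cm2 <- read_nexus_matrix(nex)
  expect_identical(cm2$taxa, cm$taxa)
  expect_identical(cm2$states, cm$states)
  # read -> write -> read is byte-stable
  nex2 <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(cm2, nex2)
  expect_identical(readLines(nex2), readLines(nex))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_character_matrix(cm, tsv)
  cm3 <- read_character_matrix(tsv)
  expect_identical(cm3$states, cm$states)
  expect_identical(defs_equal <- vapply(seq_along(cm$defs), function(i)
    identical(cm3$defs[[i]], cm$defs[[i]]), TRUE), rep(TRUE, length(cm$defs)))
})
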