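test_that("shipped painting fixtures reproduce the published segment totals", {
  maps <- phyllostomini_maps()
  expect_identical(count_segments(maps$TSAxPHA), 32L)
  expect_identical(count_segments(maps$TSAxCBR), 31L)
  expect_identical(count_segments(maps$LSIxPHA), 17L)
  # the per-probe enumeration sums to 25, one short of the printed total 26;
  # the map must carry that discrepancy openly
  expect_identical(count_segments(maps$LSIxCBR), 25L)
  expect_match(maps$LSIxCBR$note, "25")
  expect_match(maps$LSIxCBR$note, "26")

  tab <- segment_count_table(maps)
  expect_identical(tab$n_segments[match("LSIxCBR", names(maps))], 25L)
  expect_true(nzchar(tab$note[match("LSIxCBR", names(maps))]))

  # the TSA x PHA panel: 16 probes over 30 (probe, target) records
  expect_identical(nrow(maps$TSAxPHA$signals), 30L)
  expect_identical(length(unique(maps$TSAxPHA$signals$probe)), 16L)
  # PHA-5 contributes two discontiguous blocks on TSA-6
  sig <- maps$TSAxPHA$signals
  expect_identical(sig$n_blocks[sig$probe == "PHA-5" & sig$target == "TSA-6"],
                   2L)
})

test_that("homology-map TSV reading validates structure and names bad rows", {
  header <- c("# probe_species: PHA", "# target_species: TSA",
              "probe\ttarget\tn_blocks\tregion")
  f <- withr::local_tempfile(lines = header)
  empty <- read_homology_map(f)
  expect_identical(nrow(empty$signals), 0L)
  expect_identical(count_segments(empty), 0L)

  f2 <- withr::local_tempfile(lines = c(header,
                                        "PHA-1\tTSA-1\t1\t",
                                        "PHA-2\tTSA-1\t0\t"))
  expect_error(read_homology_map(f2), "row\\(s\\): 2")

  f3 <- withr::local_tempfile(lines = c(header,
                                        "PHA-1\tTSA-1\t1\t",
                                        "PHA-1\tTSA-1\t1\t"))
  expect_error(read_homology_map(f3), "duplicate")

  f4 <- withr::local_tempfile(lines = c("# probe_species: QQZ",
                                        "# target_species: TSA",
                                        "probe\ttarget\tn_blocks\tregion",
                                        "QQZ-1\tTSA-1\t1\t"))
  expect_error(read_homology_map(f4), "unknown species code")

  # labels are checked against complements when karyotypes are supplied
  ks <- phyllostomini_karyotypes()
  f5 <- withr::local_tempfile(lines = c(header, "PHA-99\tTSA-1\t1\t"))
  expect_error(read_homology_map(f5, karyotypes = ks), "PHA-99")
})

test_that("homology maps round-trip through TSV identically", {
  maps <- phyllostomini_maps()
  for (m in maps) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_homology_map(m, f)
    m2 <- read_homology_map(f)
    expect_identical(m2, m)
  }
})

test_that("karyotype arithmetic validates the published complements", {
  ks <- phyllostomini_karyotypes()
  for (k in ks) expect_empty_report(validate_karyotype(k))
  # LSI: 2n = 34, FN = 60 from 28 bi-armed + 4 one-armed autosomes
  expect_identical(ks$LSI$diploid_number, 34L)
  biarm <- c("metacentric", "submetacentric", "bi_armed")
  expect_identical(sum(ks$LSI$autosome_pairs$morphology %in% biarm), 14L)
  # TSA: 2n = 16, FN = 20 from 3 bi-armed + 4 one-armed pairs
  expect_identical(ks$TSA$diploid_number, 16L)

  broken <- karyotype("TSA", 16, 20,
                      data.frame(label = paste0("TSA-", 1:8),
                                 morphology = "bi_armed"),
                      data.frame(label = c("TSA-X", "TSA-Y"),
                                 morphology = c("bi_armed", "one_armed")))
  rep <- validate_karyotype(broken)
  expect_true("2n mismatch" %in% rep$rule)
  expect_true("FN mismatch" %in% rep$rule)
})

test_that("synteny partitions group reference units by target chromosome", {
  maps <- phyllostomini_maps()
  lsi <- synteny_partition(maps$LSIxPHA)
  # PHA-13 is the only split unit: it occurs in the groups of both LSI-13
  # and LSI-15
  with13 <- names(Filter(function(g) "PHA-13" %in% g, lsi$partition))
  expect_setequal(with13, c("LSI-13", "LSI-15"))
  expect_true(all(lengths(lsi$partition) == 1L))

  tsa <- synteny_partition(maps$TSAxPHA)
  expect_identical(tsa$partition[["TSA-X"]], "PHA-X")
  # the union of groups is exactly the set of detected units
  expect_setequal(unlist(tsa$partition), unique(maps$TSAxPHA$signals$probe))

  one <- homology_map("PHA", "TSA",
                      data.frame(probe = "PHA-1", target = "TSA-1",
                                 n_blocks = 1L))
  expect_identical(synteny_partition(one)$partition,
                   list(`TSA-1` = "PHA-1"))
})

test_that("segment counts dominate distinct probe counts", {
  for (m in phyllostomini_maps()) {
    expect_gte(count_segments(m), length(unique(m$signals$probe)))
  }
})
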