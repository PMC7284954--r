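test_that("assign_lineage follows the precedence rules (table-driven)", {
  cases <- list(
    # stated lineage beats geography
    list(args = list("europe", country = "Spain", stated_lineage = "americanus"),
         want = "americanus"),
    list(args = list("north_america", stated_lineage = "gulf"),
         want = "gulf_excluded"),
    # pre-1910 central/western North America is the native lineage
    list(args = list("north_america", region_hint = "Michigan",
                     collection_year = 1905), want = "americanus"),
    list(args = list("north_america", longitude = -95, collection_year = 1900),
         want = "americanus"),
    # post-1910, or eastern, defaults to the invader
    list(args = list("north_america", region_hint = "Michigan",
                     collection_year = 1950), want = "australis"),
    list(args = list("north_america", region_hint = "New Jersey",
                     collection_year = 1900), want = "australis"),
    list(args = list("north_america", longitude = -70, collection_year = 1900),
         want = "australis"),
    # Mediterranean-basin countries
    list(args = list("europe", country = "Spain"), want = "altissimus"),
    list(args = list("europe", country = "Italy"), want = "altissimus"),
    list(args = list("africa", country = "Egypt"), want = "altissimus"),
    list(args = list("africa", country = "Morocco"), want = "altissimus"),
    # hybrid zone
    list(args = list("europe", country = "Romania"), want = "uncertain"),
    # defaults
    list(args = list("europe", country = "Germany"), want = "australis"),
    list(args = list("asia", country = "China"), want = "australis"),
    list(args = list("asia", country = "Saudi Arabia"), want = "australis"),
    list(args = list("australia"), want = "australis"),
    list(args = list("africa", country = "Kenya"), want = "australis")
  )
  for (cs in cases) {
    expect_equal(do.call(assign_lineage, cs$args), cs$want,
                 info = paste(unlist(cs$args), collapse = "/"))
  }
  expect_error(assign_lineage(NA), "continent")
  expect_error(assign_lineage("atlantis"), "unknown continent")
  expect_warning(assign_lineage("south_america", country = "Brazil"),
                 "uncertain")
})

test_that("assign_lineage_table vectorizes over report rows", {
  reports <- data.frame(
    continent = c("europe", "north_america", "asia"),
    country = c("Spain", "USA", "Japan"),
    region_hint = c(NA, "Michigan", NA),
    collection_year = c(2000, 1905, 1990),
    stringsAsFactors = FALSE)
  expect_equal(assign_lineage_table(reports),
               c("altissimus", "americanus", "australis"))
})

test_that("normalize_tissue maps synonyms and rejects unknown terms", {
  expect_equal(normalize_tissue("rhizome"), "root_associated")
  expect_equal(normalize_tissue("leaf blade"), "leaf")
  expect_equal(normalize_tissue("culm"), "stem")
  expect_equal(normalize_tissue(c("Roots", "  PANICLE ")),
               c("root_associated", "inflorescence"))
  expect_error(normalize_tissue("mystery organ"), "mystery organ")
  # custom dictionary as data.frame
  dict <- data.frame(term = "halm", category = "stem")
  expect_equal(normalize_tissue("halm", dict), "stem")
  bad <- data.frame(term = "x", category = "not-a-tissue")
  expect_error(normalize_tissue("x", bad), "unknown categories")
})

test_that("tissue_compartment derives the three compartments", {
  expect_equal(tissue_compartment(c("leaf", "root_associated", "rhizosphere_soil")),
               c("phyllosphere", "rhizosphere", "soil"))
})

test_that("filter_communities applies the culture and size filters", {
  reports <- make_report_fixture()
  comm <- suppressMessages(filter_communities(reports))
  # sizes {12, 10, 9, 15} culture-dependent, {3, 11} not -> 3 survive >= 10
  expect_equal(nrow(comm$abundance), 3)
  expect_setequal(comm$metadata$study_id, c("S1", "S1", "S2"))
  expect_equal(sum(comm$abundance), 12 + 10 + 15)
  # min_isolates is honoured
  comm9 <- filter_communities(reports, min_isolates = 9)
  expect_equal(nrow(comm9$abundance), 4)
  # a culture-independent study never yields a community however large
  expect_false(any(comm9$metadata$study_id == "S3"))
})

test_that("filter_communities is invariant to row order and reproducible", {
  reports <- make_report_fixture()
  a <- filter_communities(reports, min_isolates = 9)
  set.seed(2)
  b <- filter_communities(reports[sample(nrow(reports)), ], min_isolates = 9)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$metadata, b$metadata)
})

test_that("filter_communities allows an empty result", {
  reports <- make_report_fixture()
  expect_message(comm <- filter_communities(reports, min_isolates = 100),
                 "no communities")
  expect_equal(nrow(comm$abundance), 0)
})

test_that("taxon_overlap enumerates Venn regions exactly", {
  ov <- taxon_overlap(list(A = c("a", "b", "c", "d"), B = c("c", "d", "e")))
  expect_equal(ov$pairwise$shared, 2)
  expect_equal(ov$pairwise$frac_a, 2 / 4)
  expect_equal(ov$pairwise$frac_b, 2 / 3)
  expect_equal(unname(ov$regions[c("A", "B", "A&B")]), c(2L, 1L, 2L))
  # identical and disjoint sets
  same <- taxon_overlap(list(X = letters[1:4], Y = letters[1:4]))
  expect_equal(unname(same$regions["X&Y"]), 4L)
  expect_equal(same$n_shared_2plus, 4)
  disj <- taxon_overlap(list(X = letters[1:3], Y = letters[4:6]))
  expect_equal(disj$n_shared_2plus, 0)
  # three sets: regions sum to the union cardinality
  set.seed(21)
  for (i in 1:20) {
    sets <- list(A = sample(letters, 8), B = sample(letters, 10),
                 C = sample(letters, 5))
    ov3 <- taxon_overlap(sets)
    expect_equal(sum(ov3$regions), ov3$n_union)
    expect_equal(ov3$n_union, length(unique(unlist(sets))))
  }
  # > 3 sets: pairwise only
  ov4 <- taxon_overlap(list(A = "a", B = "b", C = "c", D = c("a", "b")))
  expect_null(ov4$regions)
  expect_equal(nrow(ov4$pairwise), 6)
  expect_error(taxon_overlap(list(c("a"), c("b"))), "named")
})

test_that("species_level_subset keeps species ranks and SH-coded reports", {
  # printed worked example: 2829 of 10514 is 27%
  expect_equal(percent_of(2829, 10514), 27)
  df <- data.frame(
    taxonomic_rank = c(rep("species", 3), "genus", rep("genus", 6)),
    sh_code = c(rep(NA, 3), "SH0000001.08FU", rep(NA, 6)),
    stringsAsFactors = FALSE)
  r <- species_level_subset(df)
  expect_equal(r$n_retained, 4)
  expect_equal(r$percent, 40)
  all_sp <- species_level_subset(data.frame(taxonomic_rank = rep("species", 5),
                                            sh_code = NA))
  expect_equal(all_sp$percent, 100)
})

test_that("collection_coverage computes shared fractions per set", {
  r <- collection_coverage(letters[1:5], letters[1:20])
  expect_equal(r$percent, 25)
  expect_equal(collection_coverage(letters[1:4], letters[1:4])$percent, 100)
  expect_equal(collection_coverage(letters[1:3], letters[10:20])$percent, 0)
  multi <- collection_coverage(letters[1:5],
                               list(fungi = letters[1:10], bacteria = letters[4:5]))
  expect_equal(multi$percent, c(50, 100))
  expect_error(collection_coverage(letters[1:3], character(0)), "empty")
})

test_that("report tables round-trip through TSV without label changes", {
  reports <- make_report_fixture()
  reports$lineage <- "australis"
  path <- tempfile(fileext = ".tsv")
  write.table(reports, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_report_table(path)
  expect_equal(back$taxon_name, reports$taxon_name)
  a <- filter_communities(reports, min_isolates = 9)
  b <- filter_communities(back, min_isolates = 9)
  expect_identical(a$abundance, b$abundance)
})
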