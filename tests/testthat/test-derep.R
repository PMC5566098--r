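test_that("basic similarity applies the category and total criteria", {
  a <- base_assemblage()
  r <- basic_similarity(a, a, 300, 300, scheme)
  expect_true(r$passes_basic)
  expect_equal(r$max_category_deviation, 0)
  expect_equal(r$total_count_deviation, 0)

  b <- a
  b["Globigerina_bulloides"] <- a["Globigerina_bulloides"] + 0.02
  expect_false(basic_similarity(a, b, scheme = scheme)$passes_basic)

  # totals 300 vs 310: 10/305 = 0.0328 > 3%
  r <- basic_similarity(a, a, 300, 310, scheme)
  expect_false(r$passes_basic)
  expect_equal(r$total_count_deviation, 10 / 305)

  # unknown totals make the total criterion vacuous
  expect_true(basic_similarity(a, a, 300, NA, scheme)$passes_basic)

  # no shared numeric categories can never pass
  allna <- abvec(default = NA_real_)
  r <- basic_similarity(a, allna, scheme = scheme)
  expect_false(r$passes_basic)
  expect_equal(r$categories_compared, 0)

  # categories with no information in one member are ignored
  c2 <- a; c2["Globorotalia_menardii"] <- NA_real_
  expect_true(basic_similarity(a, c2, scheme = scheme)$passes_basic)
})

test_that("name distance is the Levenshtein edit distance", {
  expect_equal(name_distance("MD95-2042", "MD95-2042"), 0L)
  expect_equal(name_distance("M8_12-1", "M8/12-1"), 1L)
  expect_equal(name_distance("A", ""), 1L)
})

test_that("pair classification is sequential with first match winning", {
  expect_identical(classify_pair(TRUE, 1.0, 0), "plain")
  expect_identical(classify_pair(TRUE, 900, 0), "incorrect_position")
  expect_identical(classify_pair(TRUE, 0.3, 2), "different_name")
  expect_identical(classify_pair(TRUE, 5.0, 2), "none")
  expect_identical(classify_pair(FALSE, 0.1, 0), "none")
  # missing position: only the name criterion remains evaluable
  expect_identical(classify_pair(TRUE, NA, 0), "incorrect_position")
  expect_identical(classify_pair(TRUE, NA, 1), "none")
})

make_pair_corpus <- function() {
  a <- base_assemblage()
  mini_corpus(list(
    list(id = "T-001", name = "AAA-1", lat = 10.000, lon = 20.000,
         rel = a, count = 300, year = 1981),
    list(id = "T-002", name = "AAA-1", lat = 10.005, lon = 20.000,
         rel = a, count = 302, year = 1999),
    list(id = "T-003", name = "BBB-9", lat = -40.0, lon = 5.0,
         rel = abvec(Neogloboquadrina_pachyderma = 0.9,
                     Turborotalita_quinqueloba = 0.1),
         count = 280, year = 1999)))
}

test_that("a planted plain pair forms exactly one cluster of size two", {
  cl <- find_duplicates(make_pair_corpus(), "plain")
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, c("T-001", "T-002"))
  expect_identical(cl[[1]]$type, "plain")
})

test_that("three mutually similar same-name records form one cluster", {
  a <- base_assemblage()
  corp <- mini_corpus(lapply(1:3, function(i) {
    list(id = sprintf("T-%03d", i), name = "AAA-1",
         lat = 10 + i * 0.004, lon = 20, rel = a, count = 300)
  }))
  cl <- find_duplicates(corp, "plain")
  expect_length(cl, 1)
  expect_length(cl[[1]]$members, 3)
})

test_that("dereplication is idempotent on its own output", {
  res <- dereplicate(make_pair_corpus())
  expect_equal(sum(res$counts), 1)
  res2 <- dereplicate(res$corpus)
  expect_equal(sum(res2$counts), 0)
})

test_that("merging carries the richest assemblage and OR'd provenance", {
  a_full <- base_assemblage()
  a_poor <- a_full
  a_poor[taxon_codes(scheme, "species")[30:41]] <- NA_real_
  corp <- mini_corpus(list(
    list(id = "M-001", name = "CCC-1", lat = 10.5, lon = 20.0, prec = 1L,
         rel = a_poor, count = 300, year = 1981, db = 1L, device = "Piston",
         doi = "10.1/x"),
    list(id = "M-002", name = "CCC-1", lat = 10.5000, lon = 20.0000,
         prec = 4L, rel = a_full, count = 300, year = 1999, db = 2L,
         doi = "10.2/y")))
  cl <- find_duplicates(corp, "plain")
  expect_length(cl, 1)
  merged <- merge_cluster(corp, cl[[1]])
  # M-002 has more numeric categories and carries the assemblage
  expect_true(all(!is.na(merged$relative["M-002", counting_codes(scheme)])))
  m2 <- merged$meta["M-002", ]
  expect_equal(m2$Database_flag, 3L)           # bitwise OR of members
  expect_equal(m2$Lat_precision, 4L)           # highest precision position
  expect_identical(m2$Device, "Piston")        # presence beats absence
  expect_equal(m2$Year, 1981L)                 # conflict -> older publication
  expect_true(grepl("10.1/x", m2$Comment, fixed = TRUE))
  # the discarded member stays, flagged as duplicate
  m1 <- merged$meta["M-001", ]
  expect_equal(bitwAnd(m1$Error_flag, 8L), 8L)
  expect_true(grepl("M-002", m1$Comment, fixed = TRUE))
})

test_that("incorrect positions are repaired via the minutes transform", {
  a <- base_assemblage()
  corp <- mini_corpus(list(
    list(id = "P-001", name = "DDD-1", lat = 10.30, lon = 20.0, prec = 2L,
         rel = a, count = 300, year = 1999),
    list(id = "P-002", name = "DDD-1", lat = 10.5, lon = 20.0, prec = 4L,
         rel = a, count = 300, year = 1981)))
  cl <- find_duplicates(corp, "incorrect_position")
  expect_length(cl, 1)
  pos <- resolve_position(corp, cl[[1]]$members)
  expect_identical(pos$method, "transform")
  expect_equal(pos$latitude, 10.5)
  merged <- merge_cluster(corp, cl[[1]])
  carrier <- merged$meta[bitwAnd(merged$meta$Error_flag, 8L) == 0L, ]
  expect_equal(carrier$Latitude, 10.5)
})

test_that("a sub-3.7 km repair is rejected and bathymetry decides", {
  a <- base_assemblage()
  # 2-minute error: repair displaces only ~1.5 km, below the 3.7 km bar
  corp <- mini_corpus(list(
    list(id = "P-001", name = "EEE-1", lat = 10.02, lon = 20.0,
         rel = a, count = 300, depth = 2950, year = 1999),
    list(id = "P-002", name = "EEE-1", lat = 10.0333, lon = 20.0,
         rel = a, count = 300, depth = 120, year = 1981)))
  flat_sea <- function(lat, lon) 3000
  pos <- resolve_position(corp, c("P-001", "P-002"), bathymetry = flat_sea)
  expect_identical(pos$method, "bathymetry")
  expect_identical(pos$source_id, "P-001")  # |2950-3000| < |120-3000|
  # without a provider the older publication's position is kept
  pos2 <- resolve_position(corp, c("P-001", "P-002"))
  expect_identical(pos2$method, "unresolved")
  expect_identical(pos2$source_id, "P-002")
})

test_that("two identical single-record datasets fold into one record", {
  a <- base_assemblage()
  mk <- function(id) mini_corpus(list(
    list(id = id, name = "FFF-1", lat = 5.5, lon = -30.25, rel = a,
         count = 300)))
  sq <- sequential_dereplicate(list(mk("D1-001"), mk("D2-001")),
                               datasets = c("one", "two"))
  expect_length(active_ids(sq$corpus), 1)
  expect_equal(sq$steps$duplicates[2], 1)
  expect_equal(sq$steps$total[2], 2)
})

test_that("manual review lists basic-similar pairs and applies decisions", {
  a <- base_assemblage()
  corp <- mini_corpus(list(
    list(id = "R-001", name = "ELT44.27-PC", lat = 10, lon = 20, rel = a,
         count = 300, year = 1981),
    list(id = "R-002", name = "E44-27B", lat = 10.1, lon = 20.1, rel = a,
         count = 300, year = 1999),
    list(id = "R-003", name = "GGG-3", lat = -60, lon = 100,
         rel = abvec(Neogloboquadrina_pachyderma = 1), count = 300)))
  cand <- manual_review_candidates(corp)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$id_a, "R-001")
  expect_gt(cand$name_dist, 0)
  # automatic stages find nothing here
  expect_length(find_duplicates(corp, "plain"), 0)
  expect_length(find_duplicates(corp, "different_name"), 0)

  decided <- apply_manual_decisions(
    corp, data.frame(id_a = "R-001", id_b = "R-002", action = "merge",
                     stringsAsFactors = FALSE))
  expect_length(active_ids(decided), 2)
  kept <- decided$meta[bitwAnd(decided$meta$Error_flag, 8L) == 0L, ]
  expect_true(any(grepl("manual", kept$Comment)))

  empty_dec <- apply_manual_decisions(
    corp, data.frame(id_a = character(0), id_b = character(0),
                     action = character(0), stringsAsFactors = FALSE))
  expect_length(active_ids(empty_dec), 3)
})

test_that("duplicate detection is invariant to input order", {
  a <- base_assemblage()
  specs <- list(
    list(id = "O-001", name = "HHH-1", lat = 10.000, lon = 20.000, rel = a,
         count = 300),
    list(id = "O-002", name = "HHH-1", lat = 10.004, lon = 20.000, rel = a,
         count = 301),
    list(id = "O-003", name = "III-2", lat = 50, lon = -40,
         rel = abvec(Globigerina_falconensis = 1), count = 250))
  cl_fwd <- find_duplicates(mini_corpus(specs), "plain")
  cl_rev <- find_duplicates(mini_corpus(rev(specs)), "plain")
  expect_identical(lapply(cl_fwd, `[[`, "members"),
                   lapply(cl_rev, `[[`, "members"))
})
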