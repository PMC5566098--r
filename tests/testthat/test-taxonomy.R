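test_that("master scheme has the expected composition", {
  k <- table(scheme$categories$kind)
  expect_equal(unname(k[["species"]]), 47)
  expect_equal(unname(k[["multi_species"]]), 3)
  expect_equal(unname(k[["morphotype"]]), 6)
  expect_false(anyDuplicated(scheme$categories$code) > 0)
  morpho <- scheme$categories[scheme$categories$kind == "morphotype", ]
  expect_true(all(morpho$parent %in%
                    scheme$categories$code[scheme$categories$kind ==
                                             "species"]))
  # six never-counted species are present but unrecorded, keeping the
  # output column layout stable
  expect_equal(sum(!scheme$categories$recorded), 6)
})

table2 <- list(
  c("Globigerina digitata", "Beella_digitata"),
  c("Globigerinella digitata", "Beella_digitata"),
  c("Globigerinita pumilio", "Berggrenia_pumilio"),
  c("Dentagloborotalia anfracta", "Dentigloborotalia_anfracta"),
  c("Globorotalia anfracta", "Dentigloborotalia_anfracta"),
  c("Globigerina calida", "Globigerinella_calida"),
  c("Globigerinella aequilateralis", "Globigerinella_siphonifera"),
  c("Globigerinita bradyi", "Globigerinita_uvula"),
  c("Globoturborotalita tenella", "Globigerinoides_tenellus"),
  c("Globorotalia inflata", "Globoconella_inflata"),
  c("Globorotalia menardii flexuosa", "Globorotalia_menardii"),
  c("Globorotalia tumida flexuosa", "Globorotalia_tumida"),
  c("Globoquadrina hexagona", "Globorotaloides_hexagonus"),
  c("Globigerina rubescens", "Globoturborotalita_rubescens"),
  c("Hastigerina digitata", "Hastigerinella_digitata"),
  c("Globigerina pachyderma", "Neogloboquadrina_pachyderma"),
  c("Neogloboquadrina pachyderma sinistral", "Neogloboquadrina_pachyderma"),
  c("Globoquadrina dutertrei", "Neogloboquadrina_dutertrei"),
  c("Neogloboquadrina pachyderma dextral", "Neogloboquadrina_incompta"),
  c("Globigerinita iota", "Tenuitella_iota"),
  c("Globigerinoides sacculifer", "Trilobatus_sacculifer"),
  c("Globigerinoides trilobus", "Trilobatus_sacculifer"),
  c("Globigerina humilis", "Turborotalita_humilis"),
  c("Turborotalia cristata", "Turborotalita_humilis"),
  c("Turborotalia humilis", "Turborotalita_humilis"),
  c("Globigerina quinqueloba", "Turborotalita_quinqueloba"),
  c("Turborotalia quinqueloba", "Turborotalita_quinqueloba"))

test_that("all 27 documented synonym rows resolve to their category", {
  expect_length(table2, 27)
  for (row in table2) {
    expect_identical(resolve_synonym(row[1], scheme), row[2])
  }
})

test_that("synonym resolution is idempotent and never guesses", {
  expect_identical(resolve_synonym("Trilobatus sacculifer", scheme),
                   "Trilobatus_sacculifer")
  r1 <- resolve_synonym("Globigerinoides sacculifer", scheme)
  expect_identical(resolve_synonym(r1, scheme), r1)
  expect_identical(resolve_synonym("Foo bar", scheme), "unknown")
  # case and whitespace are immaterial
  expect_identical(resolve_synonym("  GLOBIGERINA   QUINQUELOBA ", scheme),
                   "Turborotalita_quinqueloba")
})

test_that("merge rules move abundances into their targets by dataset", {
  v <- c("P/D intergrades" = 0.05, Neogloboquadrina_incompta = 0.10)
  r <- apply_merge_rules(v, "MARGO", scheme)
  expect_equal(unname(r$values[["Neogloboquadrina_incompta"]]), 0.15)
  expect_false("P/D intergrades" %in% names(r$values))
  expect_true(r$modified)

  v <- c("G. flexuosa" = 0.02, Globorotalia_menardii = 0.03)
  r <- apply_merge_rules(v, "BUFD", scheme)
  expect_equal(unname(r$values[["Globorotalia_menardii"]]), 0.05)

  v <- c("G. crassula" = 0.01, unidentified = 0)
  r <- apply_merge_rules(v, "MARGO", scheme)
  expect_equal(unname(r$values[["unidentified"]]), 0.01)

  v <- c("G. puncticulata" = 0.04, Globoconella_inflata = 0.1)
  r <- apply_merge_rules(v, "MUNZ", scheme)
  expect_equal(unname(r$values[["Globoconella_inflata"]]), 0.14)

  # rules are dataset-scoped: the same label is untouched elsewhere
  v <- c("G. puncticulata" = 0.04, Globoconella_inflata = 0.1)
  r <- apply_merge_rules(v, "CLIMAP", scheme)
  expect_true("G. puncticulata" %in% names(r$values))
  expect_false(r$modified)

  # no rule-source categories: a no-op without the modified bit
  v <- c(Globigerina_bulloides = 0.5)
  r <- apply_merge_rules(v, "MARGO", scheme)
  expect_identical(r$values, v)
  expect_false(r$modified)
})

test_that("CLIMAP's G. pachyderma chains through the intergrades rule", {
  v <- c("G. pachyderma" = 0.07, Neogloboquadrina_incompta = 0.02,
         Neogloboquadrina_pachyderma = 0.30)
  r <- apply_merge_rules(v, "CLIMAP", scheme)
  expect_equal(unname(r$values[["Neogloboquadrina_incompta"]]), 0.09)
  expect_equal(unname(r$values[["Neogloboquadrina_pachyderma"]]), 0.30)
})

test_that("merging conserves the numeric abundance sum", {
  set.seed(101)
  for (i in 1:25) {
    v <- stats::runif(6)
    names(v) <- c("P/D intergrades", "G. crassula", "other identified",
                  "Neogloboquadrina_incompta", "unidentified",
                  "Globigerina_bulloides")
    v[sample(6, sample(0:2, 1))] <- NA
    for (ds in c("CLIMAP", "BUFD", "MARGO", "ADDITIONS")) {
      r <- apply_merge_rules(v, ds, scheme)
      expect_equal(sum(r$values, na.rm = TRUE), sum(v, na.rm = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("merging a numeric source into a not-available target is numeric", {
  v <- c("P/D intergrades" = 0.05, Neogloboquadrina_incompta = NA_real_)
  r <- apply_merge_rules(v, "ATL947", scheme)
  expect_equal(unname(r$values[["Neogloboquadrina_incompta"]]), 0.05)
})

test_that("mark_unrecorded assigns not-available without touching values", {
  sp <- taxon_codes(scheme, "species")
  reported <- c(sp[1:23], "unidentified")
  v <- stats::setNames(stats::runif(length(reported)), reported)
  out <- mark_unrecorded(v, reported, scheme)
  expect_length(out, length(codes))
  expect_equal(sum(is.na(out[sp])), 47 - 23)
  expect_equal(unname(out[reported]), unname(v))

  # full reporting leaves nothing not-available among species
  out2 <- mark_unrecorded(
    stats::setNames(rep(0.01, length(sp)), sp), sp, scheme)
  expect_equal(sum(is.na(out2[sp])), 0)

  # a lumped pink+white category holds the value, constituents become NA
  v3 <- c(Globigerinoides_ruber_pw = 0.2)
  out3 <- mark_unrecorded(v3, "Globigerinoides_ruber_pw", scheme)
  expect_equal(unname(out3[["Globigerinoides_ruber_pw"]]), 0.2)
  expect_true(is.na(out3[["Globigerinoides_ruber_pink"]]))
  expect_true(is.na(out3[["Globigerinoides_ruber_white"]]))
})

test_that("totals skip morphotype categories", {
  v <- abvec(Globigerina_bulloides = 0.6, Trilobatus_sacculifer = 0.4,
             Trilobatus_sacculifer_sac = 0.25,
             Trilobatus_sacculifer_wosac = 0.15)
  expect_equal(census_total(v, scheme), 1)
})
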