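test_that("rounding error follows the half-granule formula", {
  expect_equal(rounding_error(40), 0.02)
  expect_equal(rounding_error(1), 0.0005)
  expect_equal(rounding_error(30), 0.015)
  expect_error(rounding_error(0))
})

test_that("stated totals are corrected against the category sum", {
  v <- abvec(Globigerina_bulloides = 200, Globoconella_inflata = 112)
  r <- correct_total_count(v, 300, scheme)
  expect_equal(r$total, 312)
  expect_true(r$modified)
  r2 <- correct_total_count(v, 312, scheme)
  expect_false(r2$modified)
  allna <- abvec(default = NA_real_)
  expect_warning(r3 <- correct_total_count(allna, 300, scheme))
  expect_equal(r3$total, 300)
})

test_that("completion with zeros needs a zero unidentified and a full sum", {
  sp <- taxon_codes(scheme, "species")[1:40]
  v <- abvec(default = NA_real_)
  v[sp] <- 0.995 / 40
  v["unidentified"] <- 0
  r <- complete_with_zeros(v, scheme)  # 41 given, sum 0.995 > 1 - 0.0205
  expect_true(r$modified)
  expect_true(all(!is.na(r$values[counting_codes(scheme)])))
  # morphotype columns are never filled
  expect_true(all(is.na(r$values[taxon_codes(scheme, "morphotype")])))

  v[sp] <- 0.95 / 40
  expect_false(complete_with_zeros(v, scheme)$modified)  # 0.95 <= 0.9795

  v[sp] <- 0.995 / 40
  v["unidentified"] <- 0.01
  expect_false(complete_with_zeros(v, scheme)$modified)
})

test_that("renormalisation rescales within 5% and flags beyond", {
  v <- base_assemblage() * 0.99
  r <- renormalize_or_flag(v, scheme)
  expect_equal(census_total(r$values, scheme), 1, tolerance = 1e-12)
  expect_equal(r$bits, 0L)
  expect_true(r$modified)

  r2 <- renormalize_or_flag(base_assemblage() * 0.90, scheme)
  expect_equal(r2$bits, 64L)
  expect_equal(r2$values, base_assemblage() * 0.90)

  r3 <- renormalize_or_flag(base_assemblage(), scheme)
  expect_equal(r3$bits, 0L)
  expect_false(r3$modified)

  expect_equal(renormalize_or_flag(abvec(), scheme)$bits, 64L)
})

test_that("count and unidentified filters use strict thresholds", {
  expect_equal(filter_low_count(149), 128L)
  expect_equal(filter_low_count(150), 0L)
  expect_equal(filter_low_count(300), 0L)
  expect_equal(filter_low_count(NA), 0L)

  expect_equal(filter_unidentified(abvec(unidentified = 0.051), scheme), 32L)
  expect_equal(filter_unidentified(abvec(unidentified = 0.05), scheme), 0L)
  v <- abvec(); v["unidentified"] <- NA_real_
  expect_equal(filter_unidentified(v, scheme), 0L)
})

test_that("endemism rules flag, merge and resolve by basin", {
  pacific <- assign_ocean_flag(0, -150)
  atlantic <- assign_ocean_flag(30, -40)

  v <- abvec(Globigerinoides_ruber_pink = 0.02, Globigerina_bulloides = 0.98)
  r <- apply_endemism_rules(v, pacific, scheme, ocean_scheme)
  expect_equal(r$bits, 16L)
  expect_equal(r$values, v)  # flagged, not moved

  v <- abvec(Globigerinoides_ruber_pink = 0.005, unidentified = 0.001)
  r <- apply_endemism_rules(v, pacific, scheme, ocean_scheme)
  expect_true(is.na(r$values[["Globigerinoides_ruber_pink"]]))
  expect_equal(unname(r$values[["unidentified"]]), 0.006)
  expect_true(r$modified)

  v <- abvec(Globigerinoides_ruber_pw = 0.15,
             Globigerinoides_ruber_white = 0.05)
  r <- apply_endemism_rules(v, pacific, scheme, ocean_scheme)
  expect_true(is.na(r$values[["Globigerinoides_ruber_pw"]]))
  expect_equal(unname(r$values[["Globigerinoides_ruber_white"]]), 0.20)

  v <- abvec(Globorotaloides_hexagonus = 0.02)
  expect_equal(apply_endemism_rules(v, atlantic, scheme,
                                    ocean_scheme)$bits, 16L)
  v <- abvec(Globoquadrina_conglomerata = 0.004, unidentified = 0)
  r <- apply_endemism_rules(v, atlantic, scheme, ocean_scheme)
  expect_equal(unname(r$values[["unidentified"]]), 0.004)
  expect_true(is.na(r$values[["Globoquadrina_conglomerata"]]))

  expect_warning(r0 <- apply_endemism_rules(v, 0L, scheme, ocean_scheme))
  expect_false(r0$modified)
})

test_that("endemism merging conserves total abundance mass", {
  set.seed(301)
  pacific <- assign_ocean_flag(-5, 170)
  for (i in 1:20) {
    v <- abvec(Globigerinoides_ruber_pink = stats::runif(1, 0, 0.01),
               Globigerinoides_ruber_pw = stats::runif(1, 0, 0.1),
               Globigerina_bulloides = 0.5, unidentified = 0.01)
    r <- apply_endemism_rules(v, pacific, scheme, ocean_scheme)
    expect_equal(census_total(r$values, scheme), census_total(v, scheme),
                 tolerance = 1e-12)
  }
})

test_that("coordinate and device filters flag the documented bits", {
  m <- list(Latitude = 10, Longitude = NA, Device = "Piston")
  expect_equal(filter_other(m), 512L)
  m <- list(Latitude = 10, Longitude = 20, Device = "Dredge")
  expect_equal(filter_other(m), 256L)
  m <- list(Latitude = 10, Longitude = 20, Device = NA)
  expect_equal(filter_other(m), 256L)
  m <- list(Latitude = NA, Longitude = NA, Device = "other")
  expect_equal(filter_other(m), 512L + 256L)
  m <- list(Latitude = 10, Longitude = 20, Device = "Mini")
  expect_equal(filter_other(m), 0L)
})

test_that("filters accumulate by OR and are order-independent", {
  v <- abvec(unidentified = 0.06, Globigerina_bulloides = 0.94)
  meta <- list(Latitude = NA, Longitude = NA, Device = "Dredge")
  orders <- list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3))
  res <- vapply(orders, function(o) {
    bits <- 0L
    for (step in o) {
      bits <- bitwOr(bits, switch(step,
        filter_unidentified(v, scheme),
        filter_low_count(120),
        filter_other(meta)))
    }
    bits
  }, integer(1))
  expect_true(all(res == res[1]))
  expect_equal(res[1], 32L + 128L + 256L + 512L)
})
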