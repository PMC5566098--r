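small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_datasets = 3, samples_per_dataset = 30,
         violations_per_dataset = 2, negative_pairs = 2,
         internal_duplicates = 0, seed = 404),
    list(...))
  do.call(corpus_config, args)
}

test_that("a fixed seed fully determines the corpus", {
  g1 <- generate_corpus(small_cfg(), scheme)
  g2 <- generate_corpus(small_cfg(), scheme)
  for (k in seq_along(g1$datasets)) {
    expect_identical(g1$datasets[[k]]$abundance, g2$datasets[[k]]$abundance)
    expect_identical(g1$datasets[[k]]$meta, g2$datasets[[k]]$meta)
  }
  expect_identical(g1$truth, g2$truth)
})

test_that("zero overlap plants no duplicate clusters", {
  g <- generate_corpus(small_cfg(overlap_fraction = 0), scheme)
  expect_equal(nrow(g$truth$clusters), 0)
})

test_that("overlap with a single dataset is rejected", {
  expect_error(corpus_config(n_datasets = 1, overlap_fraction = 0.1),
               "two datasets")
})

test_that("generated assemblages sum to one before corruption", {
  g <- generate_corpus(small_cfg(), scheme)
  viol <- g$truth$violations$sample_id
  for (ds in g$datasets) {
    keep <- !(ds$meta$Sample_ID %in% viol)
    cc <- intersect(colnames(ds$abundance), counting_codes(scheme))
    sums <- rowSums(ds$abundance[keep, cc, drop = FALSE], na.rm = TRUE)
    if (ds$type == "raw") {
      expect_equal(sums / ds$meta$Count[keep], rep(1, sum(keep)),
                   tolerance = 1e-12)
    } else {
      # relative values are exact up to the 0.1% reporting granularity
      expect_true(all(abs(sums - 1) <= rounding_error(length(cc)) + 1e-9))
    }
  }
})

test_that("uncorrupted clones are exact copies of their base values", {
  g <- generate_corpus(small_cfg(
    granularity = 0, total_count_jitter = 0, position_jitter_km = 0,
    clone_types = c(plain = 1, incorrect_position = 0, different_name = 0)),
    scheme)
  tr <- g$truth$clusters
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$type == "plain"))
  find_row <- function(id) {
    for (ds in g$datasets) {
      i <- match(id, ds$meta$Sample_ID)
      if (!is.na(i)) return(list(ds = ds, i = i))
    }
    stop("id not found: ", id)
  }
  for (r in seq_len(nrow(tr))) {
    b <- find_row(tr$base_id[r]); c <- find_row(tr$clone_id[r])
    shared <- intersect(colnames(b$ds$abundance), colnames(c$ds$abundance))
    vb <- b$ds$abundance[b$i, shared]; vc <- c$ds$abundance[c$i, shared]
    if (b$ds$type == "raw") vb <- vb / b$ds$meta$Count[b$i]
    if (c$ds$type == "raw") vc <- vc / c$ds$meta$Count[c$i]
    expect_equal(vb, vc, tolerance = 1e-12)
    expect_identical(b$ds$meta$Sample_name[b$i], c$ds$meta$Sample_name[c$i])
    expect_equal(b$ds$meta$Latitude[b$i], c$ds$meta$Latitude[c$i])
  }
})

test_that("planted clones satisfy the basic similarity predicate after QC", {
  g <- generate_corpus(small_cfg(), scheme)
  pro <- lapply(g$datasets, process_dataset, scheme = scheme)
  corp <- Reduce(corpus_bind, lapply(pro, `[[`, "corpus"))
  tr <- g$truth$clusters
  expect_gt(nrow(tr), 0)
  for (r in seq_len(nrow(tr))) {
    v <- basic_similarity(corp$relative[tr$base_id[r], ],
                          corp$relative[tr$clone_id[r], ],
                          corp$meta[tr$base_id[r], "Count"],
                          corp$meta[tr$clone_id[r], "Count"], scheme)
    expect_true(v$passes_basic)
  }
})

test_that("negative controls violate a criterion by at least a factor two", {
  g <- generate_corpus(small_cfg(negative_pairs = 6), scheme)
  pro <- lapply(g$datasets, process_dataset, scheme = scheme)
  corp <- Reduce(corpus_bind, lapply(pro, `[[`, "corpus"))
  ng <- g$truth$negatives
  expect_equal(nrow(ng), 6)
  for (r in seq_len(nrow(ng))) {
    a <- ng$id_a[r]; b <- ng$id_b[r]
    v <- basic_similarity(corp$relative[a, ], corp$relative[b, ],
                          corp$meta[a, "Count"], corp$meta[b, "Count"],
                          scheme)
    if (ng$kind[r] == "category_dev") {
      expect_gte(v$max_category_deviation, 0.02)
    } else if (ng$kind[r] == "total_dev") {
      expect_gte(v$total_count_deviation, 0.06)
    } else {  # far_apart: similar fauna but twice the distance limit
      expect_true(v$passes_basic)
      d <- distance_km(corp$meta[a, "Latitude"], corp$meta[a, "Longitude"],
                       corp$meta[b, "Latitude"], corp$meta[b, "Longitude"])
      expect_gte(d, 2 * 0.5242)
      expect_gt(name_distance(corp$meta[a, "Sample_name"],
                              corp$meta[b, "Sample_name"]), 0)
    }
  }
})

test_that("planted coordinate corruptions are recoverable and displacing", {
  g <- generate_corpus(small_cfg(negative_pairs = 0), scheme)
  tr <- g$truth$clusters[g$truth$clusters$type == "incorrect_position", ]
  expect_gt(nrow(tr), 0)
  find_meta <- function(id) {
    for (ds in g$datasets) {
      i <- match(id, ds$meta$Sample_ID)
      if (!is.na(i)) return(ds$meta[i, ])
    }
  }
  for (r in seq_len(nrow(tr))) {
    b <- find_meta(tr$base_id[r]); c <- find_meta(tr$clone_id[r])
    expect_equal(minutes_as_decimal_fix(c$Latitude), b$Latitude,
                 tolerance = 1e-9)
    d <- distance_km(b$Latitude, b$Longitude, c$Latitude, c$Longitude)
    expect_gt(d, 2 * 2.621)   # beyond plain range, so the type is real
    expect_gt(d, 3.7)         # and acceptable as a repair
  }
})

test_that("the corpus can be written to source tables and read back", {
  g <- generate_corpus(corpus_config(
    n_datasets = 2, samples_per_dataset = 10, violations_per_dataset = 0,
    negative_pairs = 0, internal_duplicates = 0, seed = 77), scheme)
  dir <- withr::local_tempdir()
  write_synthetic_corpus(g, dir)
  for (k in seq_along(g$datasets)) {
    id <- tolower(g$datasets[[k]]$id)
    ds <- read_source(file.path(dir, paste0(id, ".tsv")),
                      file.path(dir, paste0(id, ".schema.yml")), scheme)
    expect_equal(nrow(ds$meta), 10)
    # every emitted category resolves back to its master code: no column
    # may be lost to a raw label or a dataset-scoped reinterpretation
    expect_setequal(colnames(ds$abundance),
                    colnames(g$datasets[[k]]$abundance))
    shared <- colnames(g$datasets[[k]]$abundance)
    expect_equal(ds$abundance[, shared],
                 g$datasets[[k]]$abundance[, shared], tolerance = 1e-9)
  }
})
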