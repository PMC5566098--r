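# shared fixtures: the master scheme is immutable, load it once
scheme <- forcens_taxonomy()
codes <- corpus_codes(scheme)
err_scheme <- flag_scheme("Error")
db_scheme <- flag_scheme("Database")
ocean_scheme <- flag_scheme("Ocean")

# a full-length abundance vector with given entries, others zero (or NA)
abvec <- function(..., default = 0) {
  v <- stats::setNames(rep(default, length(codes)), codes)
  given <- list(...)
  for (nm in names(given)) v[nm] <- given[[nm]]
  v
}

# build a small corpus from per-sample specs for dereplication tests
mini_corpus <- function(samples) {
  n <- length(samples)
  meta <- do.call(rbind, lapply(samples, function(s) {
    data.frame(
      Sample_name = s$name, Sample_ID = s$id,
      Error_flag = if (is.null(s$error)) 0L else s$error,
      Device = if (is.null(s$device)) NA_character_ else s$device,
      Latitude = if (is.null(s$lat)) NA_real_ else s$lat,
      Longitude = if (is.null(s$lon)) NA_real_ else s$lon,
      Water_depth = if (is.null(s$depth)) NA_real_ else s$depth,
      Ocean_flag = 0L,
      Sample_depth_upper = NA_real_, Sample_depth_lower = NA_real_,
      Sample_depth_average = NA_real_,
      Author = NA_character_, Journal = NA_character_,
      Year = if (is.null(s$year)) NA_integer_ else s$year,
      Publication_doi = NA_character_,
      Resource_doi = if (is.null(s$doi)) NA_character_ else s$doi,
      Comment = "", Database_flag = if (is.null(s$db)) 0L else s$db,
      Type = 0L, Count_min = 300L,
      Count = if (is.null(s$count)) NA_real_ else s$count,
      Lat_precision = if (is.null(s$prec)) 4L else s$prec,
      Lon_precision = if (is.null(s$prec)) 4L else s$prec,
      Dataset = "TEST", stringsAsFactors = FALSE)
  }))
  mx <- function(field) {
    do.call(rbind, lapply(samples, function(s) {
      if (is.null(s[[field]])) rep(NA_real_, length(codes)) else s[[field]]
    }))
  }
  rel <- do.call(rbind, lapply(samples, `[[`, "rel"))
  colnames(rel) <- codes
  empty <- matrix(NA_real_, n, length(codes), dimnames = list(NULL, codes))
  forcens_corpus(meta, empty, empty, rel, scheme)
}

# a reference assemblage used by many dereplication tests
base_assemblage <- function() {
  abvec(Globigerina_bulloides = 0.4, Globoconella_inflata = 0.3,
        Neogloboquadrina_incompta = 0.2, Orbulina_universa = 0.1)
}
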