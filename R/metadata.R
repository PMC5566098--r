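#' Standard sampling-device categories
#'
#' The devices considered appropriate for surface-sediment census counts.
#' 'Mini' corers are accepted alongside the eight categories used during
#' metadata standardisation because the device quality filter explicitly
#' whitelists them. Unmapped device descriptions become `"other"` and are
#' later caught by [filter_other()]; a missing entry stays `NA`.
#'
#' @format character vector.
#' @export
standard_devices <- c("Piston", "Gravity", "Trigger", "Grab", "Giant Box",
                      "Box", "Multi", "Mini", "CTD")

device_patterns <- list(
  "Giant Box" = "giant[ _-]?box|gkg",
  "Box"       = "\\bbox\\b|boxcorer|box[ _-]?core",
  "Piston"    = "piston|\\bpc\\b|kolbenlot",
  "Gravity"   = "gravity|schwerelot|\\bsl\\b|\\bgc\\b",
  "Trigger"   = "trigger|\\btw\\b|pilot",
  "Grab"      = "grab|van[ _-]?veen|backengreifer",
  "Multi"     = "multi|\\bmuc\\b",
  "Mini"      = "mini|\\bmic\\b",
  "CTD"       = "\\bctd\\b|rosette"
)

standardize_device <- function(x) {
  if (length(x) == 0) return(character(0))
  vapply(x, function(d) {
    if (is.na(d) || !nzchar(trimws(d))) return(NA_character_)
    if (d %in% standard_devices) return(d)
    dl <- tolower(trimws(d))
    for (std in names(device_patterns)) {
      if (grepl(device_patterns[[std]], dl)) return(std)
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Standardise raw sample metadata
#'
#' Applies the metadata conventions used across the synthesis:
#' \itemize{
#'   \item `Sample_name` transformed to uppercase (capitalisation has been
#'     used too inconsistently across compilations to carry meaning);
#'   \item `Device` mapped onto the standard categories
#'     ([standard_devices]); unmapped entries become `"other"`;
#'   \item sediment depths in metres; an entry of zero in
#'     `Sample_depth_lower` with no upper bound is moved to
#'     `Sample_depth_upper` (a zero lower bound can only be the top of the
#'     core);
#'   \item `Sample_depth_average` computed as the midpoint where both
#'     bounds are present;
#'   \item `Count_min` defaulted to the common counting standard of 300
#'     individuals when no information is available.
#' }
#' Unparseable coordinates are kept as missing positions; such records are
#' flagged later by [filter_other()] rather than dropped.
#'
#' The operation is idempotent: standardising standardised metadata is a
#' no-op.
#'
#' @param record named list or one-row data frame of raw metadata fields
#'   (any of the 21 standard fields; missing fields are completed as `NA`).
#' @return named list with the 21 standard metadata fields plus
#'   `Lat_precision`/`Lon_precision` (decimal places of the coordinate
#'   text, used for position-precision precedence during merging).
#' @export
standardize_metadata <- function(record) {
  record <- as.list(record)
  g <- function(field) {
    v <- record[[field]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  lat_txt <- g("Latitude"); lon_txt <- g("Longitude")
  lat <- num(lat_txt); lon <- num(lon_txt)
  if (!is.na(lat) && abs(lat) > 90) lat <- NA_real_
  if (!is.na(lon) && abs(lon) > 180) lon <- NA_real_

  upper <- num(g("Sample_depth_upper"))
  lower <- num(g("Sample_depth_lower"))
  if (!is.na(lower) && lower == 0 && is.na(upper)) {
    upper <- 0
    lower <- NA_real_
  }
  avg <- num(g("Sample_depth_average"))
  if (!is.na(upper) && !is.na(lower)) avg <- (upper + lower) / 2

  count_min <- num(g("Count_min"))
  if (is.na(count_min)) count_min <- 300

  lat_prec <- g("Lat_precision")
  if (is.na(lat_prec)) lat_prec <- coord_precision(lat_txt)
  lon_prec <- g("Lon_precision")
  if (is.na(lon_prec)) lon_prec <- coord_precision(lon_txt)

  list(
    Sample_name = toupper(as.character(g("Sample_name"))),
    Sample_ID = as.character(g("Sample_ID")),
    Error_flag = {e <- num(g("Error_flag")); if (is.na(e)) 0L else as.integer(e)},
    Device = standardize_device(as.character(g("Device"))),
    Latitude = lat,
    Longitude = lon,
    Water_depth = num(g("Water_depth")),
    Ocean_flag = {o <- num(g("Ocean_flag")); if (is.na(o)) 0L else as.integer(o)},
    Sample_depth_upper = upper,
    Sample_depth_lower = lower,
    Sample_depth_average = avg,
    Author = as.character(g("Author")),
    Journal = as.character(g("Journal")),
    Year = {y <- num(g("Year")); if (is.na(y)) NA_integer_ else as.integer(y)},
    Publication_doi = as.character(g("Publication_doi")),
    Resource_doi = as.character(g("Resource_doi")),
    Comment = {cm <- as.character(g("Comment")); if (is.na(cm)) "" else cm},
    Database_flag = {d <- num(g("Database_flag")); if (is.na(d)) 0L else as.integer(d)},
    Type = {t <- num(g("Type")); if (is.na(t)) 0L else as.integer(t)},
    Count_min = as.integer(count_min),
    Count = num(g("Count")),
    Lat_precision = as.integer(lat_prec),
    Lon_precision = as.integer(lon_prec)
  )
}

#' Coarse fallback ocean-basin provider
#'
#' Classifies a position into named basin areas using coarse rectangular
#' longitude/latitude boxes. This fallback is deliberately crude: it has no
#' shoreline-accurate boundaries and exists to support the endemism quality
#' rules, which only need the Atlantic + Mediterranean versus Pacific +
#' Indian + Red Sea dichotomy. For basin-accurate flags supply a gridded
#' mask provider to [assign_ocean_flag()].
#'
#' Marginal seas (Mediterranean, Red Sea) do not set their parent basin
#' bits here; a user-supplied mask is free to use different semantics.
#'
#' @param latitude,longitude decimal degrees (scalars).
#' @return character vector of Ocean-scheme area labels (empty when the
#'   position is missing).
#' @export
basin_fallback <- function(latitude, longitude) {
  if (is.na(latitude) || is.na(longitude)) return(character(0))
  lat <- latitude; lon <- longitude
  if (lon >= -6 && lon <= 36.5 && lat >= 30 && lat <= 47) {
    return(c("All oceans", "Mediterranean Sea"))
  }
  if (lon >= 32 && lon <= 43.5 && lat >= 12 && lat < 30) {
    return(c("All oceans", "Red Sea"))
  }
  if (lat > 66) return(c("All oceans", "Arctic Ocean"))
  if (lat < -50) return(c("All oceans", "Southern Ocean"))
  if (lon >= -70 && lon < 20) {
    sub <- if (lat >= 0) "North Atlantic" else "South Atlantic"
    return(c("All oceans", "Atlantic", sub))
  }
  if (lon >= 20 && lon < 146 && lat < 30) {
    return(c("All oceans", "Indian Ocean"))
  }
  sub <- if (lat >= 0) "North Pacific" else "South Pacific"
  c("All oceans", "Pacific", sub)
}

#' Assign the Ocean flag for a position
#'
#' Combines the basin areas returned by a pluggable provider into the
#' binary Ocean flag. A missing position, or a provider returning no areas,
#' yields flag 0 (with a warning in the latter case).
#'
#' @param latitude,longitude decimal degrees (scalars).
#' @param provider function `(latitude, longitude) -> character vector` of
#'   Ocean-scheme area labels; defaults to [basin_fallback()].
#' @param scheme the Ocean [flag_scheme()] (loaded when omitted).
#' @return integer Ocean flag.
#' @export
assign_ocean_flag <- function(latitude, longitude, provider = basin_fallback,
                              scheme = flag_scheme("Ocean")) {
  if (is.na(latitude) || is.na(longitude)) return(0L)
  areas <- provider(latitude, longitude)
  if (length(areas) == 0) {
    warning("basin provider returned no area for (", latitude, ", ",
            longitude, "); Ocean flag set to 0")
    return(0L)
  }
  encode_flag(areas, scheme)
}

#' Basin group for the endemism rules
#'
#' Reduces an Ocean flag to the dichotomy the endemism quality rules need:
#' `"atlantic"` (Atlantic or Mediterranean bits), `"indopacific"` (Pacific,
#' Indian Ocean or Red Sea bits) or `NA` when neither group is resolvable.
#'
#' @param ocean_flag integer Ocean flag.
#' @param scheme the Ocean [flag_scheme()].
#' @return `"atlantic"`, `"indopacific"` or `NA_character_`.
#' @export
basin_group <- function(ocean_flag, scheme = flag_scheme("Ocean")) {
  labs <- decode_flag(ocean_flag, scheme)
  if (any(c("Pacific", "North Pacific", "South Pacific", "Indian Ocean",
            "Red Sea") %in% labs)) return("indopacific")
  if (any(c("Atlantic", "North Atlantic", "South Atlantic",
            "Mediterranean Sea") %in% labs)) return("atlantic")
  NA_character_
}
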