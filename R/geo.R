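#' Great-circle distance on a spherical Earth
#'
#' Haversine distance on a sphere of radius 6371.0 km. That radius is the
#' one under which the duplicate-detection distance thresholds used
#' throughout the package (2.621 km between 0.5'N 0.5'W and 0.5'S 0.5'E,
#' and 0.5242 km for the corresponding 0.1' pair) are exact to four
#' significant figures; an ellipsoidal geodesic would not reproduce them.
#'
#' Vectorised over all four coordinate arguments.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees; latitudes in \[-90, 90\],
#'   longitudes in \[-180, 180\].
#' @return distance(s) in kilometres.
#' @examples
#' distance_km(0.5 / 60, -0.5 / 60, -0.5 / 60, 0.5 / 60)  # 2.621 km
#' @export
distance_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range")
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Undo a minutes-as-decimals coordinate mis-transformation
#'
#' A recurring corruption in legacy position metadata: a coordinate of D
#' degrees and M minutes was recorded as the number D.M, i.e. the minutes
#' were written into the decimal places untransformed. The repair
#' reinterprets the decimal fraction f as minutes: D + (f*100)/60,
#' preserving sign. The repair is only meaningful when f*100 < 60 (minutes
#' beyond 59 cannot occur); otherwise `NA` is returned as an
#' invalid-transform marker, not an error.
#'
#' The fractional part is extracted after rounding at 6 decimals so that
#' binary floating-point representation cannot manufacture phantom minutes.
#'
#' @param coordinate numeric vector, decimal degrees as recorded.
#' @return repaired coordinate(s) in decimal degrees, `NA` where the
#'   fractional part is not a valid minute value.
#' @examples
#' minutes_as_decimal_fix(10.30)  # 10.5 (30' = 0.5 degrees)
#' minutes_as_decimal_fix(10.75)  # NA   (75' impossible)
#' @export
minutes_as_decimal_fix <- function(coordinate) {
  d <- trunc(coordinate)
  f <- round(abs(coordinate - d), 6)
  minutes <- f * 100
  out <- sign(coordinate + 0.5 * (coordinate == 0)) * (abs(d) + minutes / 60)
  out[minutes >= 60] <- NA_real_
  out
}

#' Displacement caused by a coordinate transformation
#'
#' Great-circle distance between a sample's original and transformed
#' positions. Used to require that an accepted minutes-as-decimals repair
#' moves a sample by more than 3.7 km (the displacement of an
#' ill-transformation of at least 5 minutes at the equator).
#'
#' @param lat0,lon0 original position (decimal degrees).
#' @param lat1,lon1 transformed position (decimal degrees).
#' @return kilometres.
#' @export
transform_displacement_km <- function(lat0, lon0, lat1, lon1) {
  distance_km(lat0, lon0, lat1, lon1)
}

#' Enumerate minutes-as-decimals repair combinations for a sample pair
#'
#' For two samples (four scalar coordinates) lists every combination of
#' repaired/kept coordinates, excluding combinations with more than two
#' repaired coordinates and combinations containing an invalid repair
#' (fractional part not a valid minute value). The identity combination is
#' always included. With all four coordinates repairable this yields
#' C(4,0)+C(4,1)+C(4,2) = 11 combinations.
#'
#' @param a,b numeric `c(lat, lon)` position vectors.
#' @return list of candidate combinations, each a list with elements `a`,
#'   `b` (positions after repair) and `transformed` (logical of length 4:
#'   lat_a, lon_a, lat_b, lon_b).
#' @export
enumerate_transform_combinations <- function(a, b) {
  coords <- c(a[1], a[2], b[1], b[2])
  fixed <- minutes_as_decimal_fix(coords)
  transformable <- which(!is.na(fixed) & fixed != coords)
  out <- list()
  sizes <- 0:min(2L, length(transformable))
  for (k in sizes) {
    combos <- if (k == 0) list(integer(0)) else
      lapply(utils::combn(seq_along(transformable), k, simplify = FALSE),
             function(s) transformable[s])
    for (sel in combos) {
      cc <- coords
      cc[sel] <- fixed[sel]
      tr <- rep(FALSE, 4); tr[sel] <- TRUE
      out[[length(out) + 1L]] <-
        list(a = cc[1:2], b = cc[3:4], transformed = tr)
    }
  }
  out
}

#' Count reliable decimal places of a printed coordinate
#'
#' Position precision is tracked as the number of decimal places in the
#' source text, so that merged records can retain the most precise position
#' and so that exports reproduce the input text exactly.
#'
#' @param text character vector of coordinate strings.
#' @return integer vector of decimal-place counts (0 when none).
#' @export
coord_precision <- function(text) {
  text <- trimws(as.character(text))
  frac <- sub("^[^.]*\\.?", "", text)
  nchar(frac)
}
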