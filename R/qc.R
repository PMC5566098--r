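#' Expected rounding error of a sample's category sum
#'
#' Relative abundances are assumed to be reported at a granularity of 0.1%
#' per category, so the average total rounding error of a sample reporting
#' `n` categories is `n * 0.001 / 2` (each category contributes up to half
#' a granule).
#'
#' @param n number of given (numeric) categories, >= 1.
#' @return fraction of the expected sum of 1.
#' @examples
#' rounding_error(40)  # 0.02
#' @export
rounding_error <- function(n) {
  if (any(n <= 0)) stop("n must be >= 1")
  n * 0.001 / 2
}

#' Correct a stated total count against the category sum
#'
#' For raw-count samples the stated total is replaced by the sum of the
#' numeric counting categories when the two disagree; the correction is
#' logged and the record marked as modified. When every category is not
#' available the total is left untouched with a warning.
#'
#' @param values named numeric vector of absolute counts (master codes;
#'   `NA` = not available).
#' @param total stated total count (may be `NA`).
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return list with `total`, `modified` (logical) and `note`.
#' @export
correct_total_count <- function(values, total, scheme) {
  cc <- intersect(names(values), counting_codes(scheme))
  if (all(is.na(values[cc]))) {
    warning("all counting categories not available; total left unchanged")
    return(list(total = total, modified = FALSE, note = character(0)))
  }
  s <- sum(values[cc], na.rm = TRUE)
  if (!is.na(total) && isTRUE(all.equal(s, total))) {
    return(list(total = total, modified = FALSE, note = character(0)))
  }
  list(total = s, modified = TRUE,
       note = paste0("total count corrected from ",
                     ifelse(is.na(total), "NA", total), " to ", s))
}

#' Complete a relative sample with zeros
#'
#' When a study explicitly reports the 'unidentified' category as zero, and
#' the sum of its given categories is within the expected rounding error of
#' 1 (sum > 1 - [rounding_error()] of the number of given categories), the
#' sample is taken to be complete and every not-available counting category
#' is filled with zero. Otherwise the vector is returned unchanged: a short
#' sum or a non-zero 'unidentified' entry leaves open the possibility that
#' unreported categories were present. Morphotype columns are never filled.
#'
#' @param values named numeric vector of relative abundances over the
#'   master codes (`NA` = not available); must contain an explicit
#'   'unidentified' entry for the rule to apply.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return list with `values` and `modified`.
#' @export
complete_with_zeros <- function(values, scheme) {
  cc <- intersect(names(values), counting_codes(scheme))
  unid <- values[scheme$unidentified]
  given <- cc[!is.na(values[cc])]
  if (is.na(unid) || unid != 0 || length(given) == 0) {
    return(list(values = values, modified = FALSE))
  }
  s <- sum(values[given])
  if (s <= 1 - rounding_error(length(given))) {
    return(list(values = values, modified = FALSE))
  }
  fill <- setdiff(cc, given)
  values[fill] <- 0
  list(values = values, modified = length(fill) > 0)
}

#' Renormalise relative abundances or flag a deviating sum
#'
#' Relative abundances are rescaled to sum exactly to 1 over the counting
#' categories. Samples whose sum deviates from 1 by more than 5% are not
#' rescaled: they receive Error bit 7 ('sum deviates', value 64) and are
#' excluded from further analyses. Morphotype values are rescaled by the
#' same factor so they stay consistent with their parent categories. A
#' degenerate all-zero sum is flagged as deviating.
#'
#' @inheritParams complete_with_zeros
#' @return list with `values`, `bits` (Error flag value contribution, 0 or
#'   64) and `modified`.
#' @export
renormalize_or_flag <- function(values, scheme) {
  cc <- intersect(names(values), counting_codes(scheme))
  s <- sum(values[cc], na.rm = TRUE)
  if (s == 0 || abs(s - 1) > 0.05) {
    return(list(values = values, bits = 64L, modified = FALSE))
  }
  num <- !is.na(values)
  values[num] <- values[num] / s
  list(values = values, bits = 0L, modified = !isTRUE(all.equal(s, 1)))
}

#' Flag samples with too few counted individuals
#'
#' Error bit 8 ('too few counted', value 128) for totals strictly below
#' 150 individuals. Samples with no count information pass vacuously
#' (relative-only records are filtered on their actual counts only; the
#' default minimum-count of 300 implies a pass).
#'
#' @param total total counted individuals (may be `NA`).
#' @return Error flag contribution (0 or 128).
#' @export
filter_low_count <- function(total) {
  if (!is.na(total) && total < 150) 128L else 0L
}

#' Flag samples with too many unidentified specimens
#'
#' Error bit 6 ('too many unidentified', value 32) when the relative
#' 'unidentified' entry exceeds 5% (strictly). A not-available entry does
#' not flag.
#'
#' @inheritParams complete_with_zeros
#' @return Error flag contribution (0 or 32).
#' @export
filter_unidentified <- function(values, scheme) {
  unid <- values[scheme$unidentified]
  if (!is.na(unid) && unid > 0.05) 32L else 0L
}

#' Apply the ocean-basin endemism rules
#'
#' *G. ruber* pink is endemic to the Atlantic, while *G. conglomerata*,
#' *G. hexagonus* and *G. adamsi* are endemic to the Indopacific. Counts
#' reporting these species outside their range are either taxonomically
#' suspect (relative abundance > 1%: Error bit 5, 'taxonomically
#' incorrect', value 16) or treated as misidentifications (abundance <= 1%:
#' the value is moved into 'unidentified' and the source category becomes
#' not available; the record is marked modified). In the Indopacific the
#' lumped *G. ruber* pink + white category is resolved entirely into
#' *G. ruber* white. Total abundance mass is conserved by every move.
#'
#' When the basin cannot be resolved the rules are skipped with a warning.
#'
#' @inheritParams complete_with_zeros
#' @param ocean_flag integer Ocean flag of the sample.
#' @param ocean_scheme the Ocean [flag_scheme()].
#' @return list with `values`, `bits` (0 or 16), `modified`, `notes` and
#'   `moves` (data frame of `from`/`to` codes, so callers can mirror the
#'   same moves on a parallel absolute-count vector).
#' @export
apply_endemism_rules <- function(values, ocean_flag, scheme,
                                 ocean_scheme = flag_scheme("Ocean")) {
  group <- basin_group(ocean_flag, ocean_scheme)
  moves <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(group)) {
    warning("ocean basin unresolvable; endemism rules skipped")
    return(list(values = values, bits = 0L, modified = FALSE,
                notes = character(0), moves = moves))
  }
  bits <- 0L; modified <- FALSE; notes <- character(0)
  unid <- scheme$unidentified
  move_to_unidentified <- function(code) {
    v <- values[code]
    values[unid] <<- if (is.na(values[unid])) v else values[unid] + v
    values[code] <<- NA_real_
    modified <<- TRUE
    moves <<- rbind(moves, data.frame(from = code, to = unid,
                                      stringsAsFactors = FALSE))
    notes <<- c(notes, paste0("out-of-range '", code,
                              "' (", v, ") merged into 'unidentified'"))
  }
  if (group == "indopacific") {
    pink <- "Globigerinoides_ruber_pink"
    pw <- "Globigerinoides_ruber_pw"
    white <- "Globigerinoides_ruber_white"
    v <- values[pink]
    if (!is.na(v) && v > 0.01) {
      bits <- 16L
    } else if (!is.na(v) && v > 0) {
      move_to_unidentified(pink)
    }
    vpw <- values[pw]
    if (!is.na(vpw) && vpw > 0) {
      values[white] <- if (is.na(values[white])) vpw else values[white] + vpw
      values[pw] <- NA_real_
      modified <- TRUE
      moves <- rbind(moves, data.frame(from = pw, to = white,
                                       stringsAsFactors = FALSE))
      notes <- c(notes,
                 "lumped ruber pink+white resolved into G. ruber white")
    }
  } else {
    for (code in c("Globoquadrina_conglomerata", "Globorotaloides_hexagonus",
                   "Globigerinella_adamsi")) {
      v <- values[code]
      if (!is.na(v) && v > 0.01) {
        bits <- 16L
      } else if (!is.na(v) && v > 0) {
        move_to_unidentified(code)
      }
    }
  }
  list(values = values, bits = bits, modified = modified, notes = notes,
       moves = moves)
}

#' Flag records without coordinates or from non-standard devices
#'
#' Error bit 10 ('no geographical coordinates', value 512) when latitude or
#' longitude is missing, and bit 9 ('non-standard device', value 256) when
#' the sampling device is not one of [standard_devices] (a missing device
#' is treated conservatively as non-standard; census counts from, e.g.,
#' plankton tows or dredges do not integrate seasonal deposition the way
#' sediment samples do).
#'
#' @param meta named list or one-row data frame with at least `Latitude`,
#'   `Longitude`, `Device`.
#' @return Error flag contribution (sum of 0, 256, 512).
#' @export
filter_other <- function(meta) {
  meta <- as.list(meta)
  bits <- 0L
  if (is.na(meta$Latitude) || is.na(meta$Longitude)) bits <- bits + 512L
  dev <- meta$Device
  if (is.na(dev) || !dev %in% standard_devices) bits <- bits + 256L
  bits
}
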