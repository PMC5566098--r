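#' Master taxonomic scheme
#'
#' Loads the master category list (47 species, 3 multi-species and 6
#' morphotype categories), the synonym table and the dataset-specific merge
#' rules shipped with the package, or user-supplied replacements in the same
#' format.
#'
#' Six of the 47 species categories have never been counted (four are too
#' small for the >150 um size fraction, two were established only in recent
#' taxonomic revisions); they are kept in the scheme with `recorded = FALSE`
#' so that output column layout is stable. Morphotype categories carry a
#' `parent` species whose totals already contain them; all totalling
#' routines in the package therefore skip morphotypes. The special category
#' `"unidentified"` acts as the sink for merges of taxonomically
#' uninterpretable counts.
#'
#' @param taxonomy,synonyms,merge_rules optional paths to tab-delimited
#'   replacements for the shipped tables.
#' @param extra_merge_rules optional data frame with columns
#'   `source_label`, `target`, `datasets`, `rationale` appended to the
#'   shipped rules (user extension point).
#' @return an object of class `taxonomy_scheme`: a list with elements
#'   `categories` (data frame), `synonyms` (named character vector of
#'   normalised name -> code), `merge_rules` (data frame) and
#'   `unidentified` (the sink code).
#' @export
forcens_taxonomy <- function(taxonomy = NULL, synonyms = NULL,
                             merge_rules = NULL, extra_merge_rules = NULL) {
  path <- function(p, default) {
    if (!is.null(p)) p else
      system.file("extdata", default, package = "forcensr", mustWork = TRUE)
  }
  cats <- utils::read.delim(path(taxonomy, "taxonomy.tsv"),
                            stringsAsFactors = FALSE, na.strings = "")
  syns <- utils::read.delim(path(synonyms, "synonyms.tsv"),
                            stringsAsFactors = FALSE)
  rules <- utils::read.delim(path(merge_rules, "merge_rules.tsv"),
                             stringsAsFactors = FALSE)
  if (!is.null(extra_merge_rules)) rules <- rbind(rules, extra_merge_rules)

  stopifnot(!anyDuplicated(cats$code),
            all(cats$kind %in% c("species", "multi_species", "morphotype")))
  morpho <- cats[cats$kind == "morphotype", ]
  stopifnot(all(!is.na(morpho$parent)),
            all(morpho$parent %in% cats$code[cats$kind == "species"]))
  stopifnot(all(syns$code %in% c(cats$code, "unidentified")))

  # lookup: every display name and every synonym, normalised
  lookup <- c(stats::setNames(cats$code, normalize_taxon_name(cats$display)),
              stats::setNames(syns$code, normalize_taxon_name(syns$synonym)),
              stats::setNames(cats$code, normalize_taxon_name(cats$code)),
              unidentified = "unidentified")
  dup <- duplicated(names(lookup))
  if (any(tapply(lookup, names(lookup), function(x) length(unique(x))) > 1)) {
    stop("a synonym maps to two different categories")
  }
  lookup <- lookup[!dup]

  rules$datasets <- toupper(rules$datasets)
  # rule targets must resolve, possibly through another rule's source label
  ok <- rules$target %in% c(cats$code, "unidentified") |
    normalize_taxon_name(rules$target) %in%
      normalize_taxon_name(rules$source_label)
  if (!all(ok)) {
    stop("merge rule target(s) absent from scheme: ",
         paste(unique(rules$target[!ok]), collapse = ", "))
  }

  structure(list(categories = cats, synonyms = lookup, merge_rules = rules,
                 unidentified = "unidentified"),
            class = "taxonomy_scheme")
}

#' @export
print.taxonomy_scheme <- function(x, ...) {
  k <- table(x$categories$kind)
  cat("taxonomy_scheme:", k[["species"]], "species,",
      k[["multi_species"]], "multi-species,",
      k[["morphotype"]], "morphotype categories;",
      length(x$synonyms), "name lookups;",
      nrow(x$merge_rules), "merge rules\n")
  invisible(x)
}

#' Normalise a taxon name for synonym lookup
#'
#' Case-folds, strips markup asterisks and parentheses, unifies "&" with
#' "and" and collapses internal whitespace. Coiling annotations
#' ("sinistral"/"dextral") are not stripped: they are themselves synonym
#' rows where they occur.
#'
#' @param x character vector of raw labels.
#' @return normalised character vector.
#' @export
normalize_taxon_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[*()]", "", x)
  x <- gsub("&", " and ", x, fixed = TRUE)
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Resolve a raw taxon label to a master category code
#'
#' Returns the master code when the (normalised) label matches a category
#' name or a listed synonym, and the sentinel `"unknown"` otherwise. The
#' function never guesses: an unknown label signals that the synonym table
#' must be extended by the curator.
#'
#' @param raw_label single non-empty character string.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return a category code, `"unidentified"`, or `"unknown"`.
#' @export
resolve_synonym <- function(raw_label, scheme) {
  stopifnot(is.character(raw_label), nzchar(raw_label))
  hit <- unname(scheme$synonyms[normalize_taxon_name(raw_label)])
  ifelse(is.na(hit), "unknown", hit)
}

#' Category code helpers
#'
#' `taxon_codes()` returns category codes filtered by kind;
#' `counting_codes()` returns the codes that enter sample totals and
#' similarity comparisons: all non-morphotype categories plus
#' `"unidentified"` (morphotype counts are already contained in their parent
#' category and are always skipped); `corpus_codes()` returns the fixed
#' abundance-block column order: species, multi-species, unidentified, then
#' the six morphotype columns at the end of the block.
#'
#' @param scheme a [forcens_taxonomy()] scheme.
#' @param kind subset of `c("species","multi_species","morphotype")`.
#' @return character vector of codes.
#' @export
taxon_codes <- function(scheme,
                        kind = c("species", "multi_species", "morphotype")) {
  scheme$categories$code[scheme$categories$kind %in% kind]
}

#' @rdname taxon_codes
#' @export
counting_codes <- function(scheme) {
  c(taxon_codes(scheme, c("species", "multi_species")), scheme$unidentified)
}

#' @rdname taxon_codes
#' @export
corpus_codes <- function(scheme) {
  c(counting_codes(scheme), taxon_codes(scheme, "morphotype"))
}

#' Apply dataset-specific category merge rules
#'
#' Merges historical or dataset-idiosyncratic counting categories into their
#' master targets, e.g. 'P/D intergrades' into *N. incompta* or
#' *G. crassula* into 'unidentified'. Rules are keyed by dataset identifier
#' (or `ALL`) and matched against both unresolved raw labels and resolved
#' codes; rules may chain (a rule target may be another rule's source
#' label, as for CLIMAP's 'G. pachyderma' which is first reinterpreted as
#' 'P/D intergrades'), and chains are iterated to a fixpoint.
#'
#' Merging a numeric source into a not-available target yields the numeric
#' value (not-available carries no information and is not zero); a
#' not-available source is simply dropped. The sum of numeric abundances is
#' conserved exactly.
#'
#' @param values named numeric vector of abundances; names are master codes
#'   or still-raw labels; `NA` means not available.
#' @param dataset_id dataset identifier the rules are matched against.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return list with elements `values` (merged vector), `modified` (logical:
#'   any rule fired) and `notes` (character log of applied rules).
#' @export
apply_merge_rules <- function(values, dataset_id, scheme) {
  rules <- scheme$merge_rules
  ds <- toupper(dataset_id)
  applies <- vapply(strsplit(rules$datasets, ","), function(d) {
    any(trimws(d) %in% c(ds, "ALL"))
  }, logical(1))
  rules <- rules[applies, , drop = FALSE]
  notes <- character(0)
  modified <- FALSE
  if (nrow(rules) == 0L) {
    return(list(values = values, modified = FALSE, notes = notes))
  }
  src_norm <- normalize_taxon_name(rules$source_label)
  guard <- length(values) + nrow(rules) + 2L
  for (pass in seq_len(guard)) {
    nm_norm <- normalize_taxon_name(names(values))
    hit <- match(nm_norm, src_norm)
    if (all(is.na(hit))) break
    i <- which(!is.na(hit))[1L]
    rule <- rules[hit[i], ]
    target <- rule$target
    if (!target %in% c(scheme$categories$code, scheme$unidentified)) {
      # chained rule: target is another rule's source label, keep raw
      if (!normalize_taxon_name(target) %in% src_norm) {
        stop("merge rule target not in scheme: ", target)
      }
    }
    v <- values[i]
    values <- values[-i]
    j <- match(target, names(values))
    if (is.na(j)) {
      values[target] <- v
    } else if (is.na(values[j])) {
      values[j] <- v                       # numeric + NA = numeric
    } else if (!is.na(v)) {
      values[j] <- values[j] + v
    }
    modified <- TRUE
    notes <- c(notes, paste0("merged '", rule$source_label, "' into '",
                             target, "'"))
  }
  list(values = values, modified = modified, notes = notes)
}

#' Mark categories not reported by a study as not available
#'
#' Expands an abundance vector to the full master column set, assigning the
#' not-available sentinel (`NA`) to every category the study did not report.
#' A category that was not included in a study's species list was not
#' necessarily absent from the assemblage, so its abundance is unknown
#' rather than zero; the distinction is preserved throughout. Reported
#' categories keep their values, and a numeric value is never converted to
#' not-available. When a study reported a lumped multi-species category
#' (e.g. *G. ruber* pink + white), its constituents are simply not in the
#' reported list and thus come out as not available.
#'
#' @param values named numeric vector (names are master codes).
#' @param reported character vector of reported category codes.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return named numeric vector over [corpus_codes()] in fixed order.
#' @export
mark_unrecorded <- function(values, reported, scheme) {
  codes <- corpus_codes(scheme)
  bad <- setdiff(reported, codes)
  if (length(bad)) stop("reported categories not in scheme: ",
                        paste(bad, collapse = ", "))
  out <- stats::setNames(rep(NA_real_, length(codes)), codes)
  keep <- intersect(names(values), reported)
  out[keep] <- values[keep]
  out
}

#' Total of numeric abundances over counting categories
#'
#' Sums non-morphotype categories (species, multi-species and
#' 'unidentified'); morphotype columns are never counted towards totals
#' because their sums are already included in their parent category.
#'
#' @inheritParams mark_unrecorded
#' @return numeric scalar (0 when no category is numeric).
#' @export
census_total <- function(values, scheme) {
  cc <- intersect(names(values), counting_codes(scheme))
  sum(values[cc], na.rm = TRUE)
}
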