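#' @keywords internal
meta_fields <- c("Sample_name", "Sample_ID", "Error_flag", "Device",
                 "Latitude", "Longitude", "Water_depth", "Ocean_flag",
                 "Sample_depth_upper", "Sample_depth_lower",
                 "Sample_depth_average", "Author", "Journal", "Year",
                 "Publication_doi", "Resource_doi", "Comment",
                 "Database_flag", "Type", "Count_min", "Count")

meta_units <- c("", "", "", "", "decimal degrees", "decimal degrees",
                "meter", "", "meters", "meters", "meters", "", "", "date",
                "doi", "doi", "", "", "", "individuals", "individuals")

internal_fields <- c("Lat_precision", "Lon_precision", "Dataset")

#' Construct a census corpus
#'
#' The central container of the package: per-sample metadata plus three
#' abundance blocks over the fixed master column order ([corpus_codes()]):
#' `original` (source values, taxonomically reformatted only), `counts`
#' (corrected absolute counts where available) and `relative` (corrected
#' relative proportions, present for every record). `NA` in a block means
#' not available, which is distinct from an explicit zero. An append-only
#' audit log of modifications rides along.
#'
#' @param meta data frame with the standard metadata fields (missing ones
#'   are completed as `NA`), internal precision fields and a `Dataset`
#'   column.
#' @param original,counts,relative numeric matrices, one row per sample,
#'   columns [corpus_codes()].
#' @param scheme a [forcens_taxonomy()] scheme.
#' @param audit optional audit-log data frame.
#' @return object of class `forcens_corpus`.
#' @export
forcens_corpus <- function(meta, original, counts, relative, scheme,
                           audit = NULL) {
  codes <- corpus_codes(scheme)
  fix <- function(m) {
    m <- as.matrix(m)
    stopifnot(identical(colnames(m), codes), nrow(m) == nrow(meta))
    rownames(m) <- meta$Sample_ID
    m
  }
  for (f in c(meta_fields, internal_fields)) {
    if (is.null(meta[[f]])) meta[[f]] <- rep(NA, nrow(meta))
  }
  meta <- meta[, c(meta_fields, internal_fields)]
  stopifnot(!anyDuplicated(meta$Sample_ID))
  rownames(meta) <- meta$Sample_ID
  if (is.null(audit)) audit <- empty_audit()
  structure(list(meta = meta, original = fix(original), counts = fix(counts),
                 relative = fix(relative), audit = audit, scheme = scheme),
            class = "forcens_corpus")
}

empty_audit <- function() {
  data.frame(sample_id = character(0), stage = character(0),
              field = character(0), before = character(0),
              after = character(0), stringsAsFactors = FALSE)
}

audit_entry <- function(sample_id, stage, field, before, after) {
  data.frame(sample_id = sample_id, stage = stage, field = field,
             before = as.character(before), after = as.character(after),
             stringsAsFactors = FALSE)
}

#' @export
print.forcens_corpus <- function(x, ...) {
  act <- sum(x$meta$Error_flag <= 1)
  cat("forcens_corpus:", nrow(x$meta), "records (", act,
      "passing all selection criteria, Error flag <= 1 ),",
      nrow(x$audit), "audit entries\n")
  invisible(x)
}

#' Number of records in a corpus
#' @param x a `forcens_corpus`.
#' @return integer.
#' @export
n_samples <- function(x) nrow(x$meta)

#' Identifiers of records passing all selection criteria (Error flag <= 1)
#' @param x a `forcens_corpus`.
#' @return character vector of `Sample_ID`s.
#' @export
active_ids <- function(x) x$meta$Sample_ID[x$meta$Error_flag <= 1]

#' Bind two corpora sharing a taxonomy scheme
#' @param a,b `forcens_corpus` objects.
#' @return combined `forcens_corpus`.
#' @export
corpus_bind <- function(a, b) {
  forcens_corpus(rbind(a$meta, b$meta),
                 rbind(a$original, b$original),
                 rbind(a$counts, b$counts),
                 rbind(a$relative, b$relative),
                 a$scheme,
                 rbind(a$audit, b$audit))
}

#' Construct a source dataset
#'
#' An ordered collection of raw census samples with provenance, as read
#' from one constituent compilation or study.
#'
#' @param id dataset identifier (e.g. `"CLIMAP"`); matched (uppercased)
#'   against merge-rule dataset lists.
#' @param database Database flag-scheme label for provenance.
#' @param type `"raw"` (absolute counts) or `"relative"`.
#' @param meta data frame of raw per-sample metadata.
#' @param abundance numeric matrix, one row per sample; column names are
#'   resolved master codes or still-raw labels (for merge-rule sources and
#'   unknowns).
#' @param reported character vector of master codes the study reported.
#' @return object of class `source_dataset`.
#' @export
source_dataset <- function(id, database, type = c("raw", "relative"),
                           meta, abundance, reported) {
  type <- match.arg(type)
  stopifnot(nrow(meta) == nrow(abundance))
  structure(list(id = id, database = database, type = type, meta = meta,
                 abundance = as.matrix(abundance), reported = reported),
            class = "source_dataset")
}

#' @export
print.source_dataset <- function(x, ...) {
  cat("source_dataset '", x$id, "' (", x$type, "): ", nrow(x$meta),
      " samples, ", ncol(x$abundance), " abundance columns\n", sep = "")
  invisible(x)
}
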