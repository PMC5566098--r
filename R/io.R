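#' Read a heterogeneous source table via a schema config
#'
#' Source compilations arrive as tab- or comma-delimited tables with one
#' row per sample, arbitrary metadata column names and one column per
#' taxonomic category under the study's own labels. A schema config maps
#' the table onto the shared sample model:
#'
#' \preformatted{
#' dataset: MARGO              # id matched against merge rules
#' database: MARGO Pacific     # Database flag-scheme label
#' type: relative              # or raw
#' columns:                    # metadata mapping (standard -> source)
#'   Sample_name: Core
#'   Latitude: lat
#'   Longitude: long
#' taxa: auto                  # or a map source-column -> master code
#' percent: auto               # divide relative values by 100 (auto: when
#'                             # the median row sum is near 100)
#' }
#'
#' Taxon columns are resolved in this order: a merge-rule source label for
#' the dataset is kept raw (so that dataset-scoped reinterpretations such
#' as CLIMAP's 'G. pachyderma' can fire later), otherwise the label is
#' resolved through the synonym table; unresolvable columns are kept raw
#' with a warning. Non-numeric abundance cells become not available with a
#' warning. Original values are preserved untouched apart from the optional
#' percent-to-fraction scaling.
#'
#' @param path path to the delimited table (`.csv` is read as
#'   comma-separated, anything else as tab-separated).
#' @param schema schema config: a list as above or a path to a YAML file.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return a [source_dataset()].
#' @export
read_source <- function(path, schema, scheme = forcens_taxonomy()) {
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  cols <- schema$columns
  if (is.null(cols$Sample_name) &&
      (is.null(cols$Latitude) || is.null(cols$Longitude))) {
    stop("schema must map at least Sample_name or both coordinates")
  }
  missing_cols <- setdiff(unlist(cols), names(tab))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from table: ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- data.frame(row.names = seq_len(nrow(tab)))
  for (f in names(cols)) meta[[f]] <- tab[[cols[[f]]]]
  # retain coordinate text so precision can be derived
  if (!is.null(cols$Latitude)) {
    meta$Lat_precision <- coord_precision(tab[[cols$Latitude]])
  }
  if (!is.null(cols$Longitude)) {
    meta$Lon_precision <- coord_precision(tab[[cols$Longitude]])
  }

  taxa_cols <- setdiff(names(tab), unlist(cols))
  if (!is.null(schema$taxa) && !identical(schema$taxa, "auto")) {
    taxa_cols <- intersect(taxa_cols, names(schema$taxa))
  }
  ds <- toupper(schema$dataset)
  rule_src <- normalize_taxon_name(scheme$merge_rules$source_label[
    vapply(strsplit(scheme$merge_rules$datasets, ","),
           function(d) any(trimws(d) %in% c(ds, "ALL")), logical(1))])
  resolved <- vapply(taxa_cols, function(lab) {
    if (!is.null(schema$taxa) && !identical(schema$taxa, "auto")) {
      mapped <- schema$taxa[[lab]]
      if (!is.null(mapped)) return(mapped)
    }
    if (normalize_taxon_name(lab) %in% rule_src) return(lab)
    code <- resolve_synonym(lab, scheme)
    if (code == "unknown") {
      warning("unresolved taxon column kept raw: ", lab)
      lab
    } else code
  }, character(1))

  ab <- matrix(NA_real_, nrow(tab), length(taxa_cols),
               dimnames = list(NULL, unname(resolved)))
  for (i in seq_along(taxa_cols)) {
    v <- tab[[taxa_cols[i]]]
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) {
      warning("non-numeric abundance cell(s) in column '", taxa_cols[i],
              "' treated as not available")
    }
    ab[, i] <- num
  }
  # collapse duplicate resolved labels by summing numeric entries
  if (anyDuplicated(colnames(ab))) {
    uniq <- unique(colnames(ab))
    ab2 <- matrix(NA_real_, nrow(ab), length(uniq),
                  dimnames = list(NULL, uniq))
    for (u in uniq) {
      block <- ab[, colnames(ab) == u, drop = FALSE]
      allna <- rowSums(!is.na(block)) == 0
      s <- rowSums(block, na.rm = TRUE)
      s[allna] <- NA_real_
      ab2[, u] <- s
    }
    ab <- ab2
  }

  type <- match.arg(schema$type, c("raw", "relative"))
  pct <- schema$percent
  if (type == "relative") {
    rs <- rowSums(ab, na.rm = TRUE)
    if (isTRUE(pct) ||
        (is.null(pct) || identical(pct, "auto")) &&
          stats::median(rs[rs > 0]) > 2) {
      ab <- ab / 100
    }
  }

  reported <- schema$reported
  if (is.null(reported)) {
    reported <- intersect(colnames(ab), corpus_codes(scheme))
  }
  source_dataset(id = schema$dataset, database = schema$database,
                 type = type, meta = meta, abundance = ab,
                 reported = reported)
}

fmt_num <- function(x, digits = 6) {
  out <- character(length(x))
  ok <- !is.na(x)
  int <- ok & x == round(x) & abs(x) < 1e15
  out[int] <- sprintf("%.0f", x[int])
  rest <- ok & !int
  s <- formatC(x[rest], digits = digits, format = "f")
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  out[rest] <- s
  out
}

fmt_coord <- function(x, prec) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    out[i] <- if (is.na(x[i])) "" else if (is.na(prec[i]))
      fmt_num(x[i], 6) else
      formatC(x[i], format = "f", digits = prec[i])
  }
  out
}

#' Write a corpus in the tab-delimited three-block layout
#'
#' Emits UTF-8 tab-delimited text with two header rows (variable names,
#' then variable units), 21 metadata columns, and abundance blocks in the
#' fixed master column order, each block ending with the six morphotype
#' columns. The `full` variant contains all records (including excluded
#' and merged-away ones, so nothing is ever destroyed) with all three
#' blocks: original values, corrected absolute counts, corrected relative
#' proportions. The `passing_only` variant contains only records passing
#' all selection criteria (Error flag <= 1) and only the relative block.
#'
#' A not-available value is written as an empty cell; an explicit zero is
#' written as `"0"`. Relative values are written at 6 decimal places,
#' which is lossless at the 0.1% granularity the counts carry. Coordinates
#' are written at their recorded precision.
#'
#' @param corpus a [forcens_corpus()].
#' @param path output file path.
#' @param variant `"full"` or `"passing_only"`.
#' @return `path`, invisibly.
#' @export
write_forcens <- function(corpus, path, variant = c("full", "passing_only")) {
  variant <- match.arg(variant)
  meta <- corpus$meta
  keep <- if (variant == "passing_only") meta$Error_flag <= 1 else
    rep(TRUE, nrow(meta))
  meta <- meta[keep, , drop = FALSE]
  codes <- corpus_codes(corpus$scheme)

  blocks <- if (variant == "full") c("original", "counts", "relative") else
    "relative"
  header1 <- c(meta_fields, rep(codes, length(blocks)))
  unit_of <- c(original = "as published", counts = "individuals",
               relative = "fraction")
  header2 <- c(meta_units,
               rep(unit_of[blocks], each = length(codes)))

  rows <- character(nrow(meta))
  mtxt <- matrix("", nrow(meta), length(meta_fields))
  for (j in seq_along(meta_fields)) {
    f <- meta_fields[j]
    v <- meta[[f]]
    mtxt[, j] <- if (f == "Latitude") fmt_coord(v, meta$Lat_precision)
      else if (f == "Longitude") fmt_coord(v, meta$Lon_precision)
      else if (is.numeric(v)) fmt_num(v)
      else ifelse(is.na(v), "", as.character(v))
  }
  btxt <- do.call(cbind, lapply(blocks, function(b) {
    m <- corpus[[b]][keep, , drop = FALSE]
    digits <- if (b == "relative") 6 else 6
    apply(m, 2, fmt_num, digits = digits)
  }))
  if (nrow(meta) == 0) {
    lines <- c(paste(header1, collapse = "\t"),
               paste(header2, collapse = "\t"))
  } else {
    if (is.null(dim(btxt))) btxt <- matrix(btxt, nrow = 1)
    all_txt <- cbind(mtxt, btxt)
    lines <- c(paste(header1, collapse = "\t"),
               paste(header2, collapse = "\t"),
               apply(all_txt, 1, paste, collapse = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a full-variant corpus file back into a corpus
#'
#' Inverse of [write_forcens()] for the `full` variant: metadata, the
#' three abundance blocks and the not-available versus zero distinction
#' are reconstructed exactly; coordinate precision is re-derived from the
#' written text.
#'
#' @param path path to a full-variant file.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return a [forcens_corpus()].
#' @export
read_forcens <- function(path, scheme = forcens_taxonomy()) {
  lines <- readLines(path, encoding = "UTF-8")
  codes <- corpus_codes(scheme)
  nmeta <- length(meta_fields)
  ncat <- length(codes)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  stopifnot(length(header) == nmeta + 3 * ncat)
  body <- cells[-(1:2)]
  n <- length(body)
  get <- function(j) vapply(body, function(r) {
    if (j <= length(r)) r[j] else ""
  }, character(1))
  meta <- data.frame(row.names = seq_len(n))
  numeric_meta <- c("Error_flag", "Latitude", "Longitude", "Water_depth",
                    "Ocean_flag", "Sample_depth_upper", "Sample_depth_lower",
                    "Sample_depth_average", "Year", "Database_flag", "Type",
                    "Count_min", "Count")
  for (j in seq_len(nmeta)) {
    f <- meta_fields[j]
    v <- get(j)
    v[v == ""] <- NA
    meta[[f]] <- if (f %in% numeric_meta)
      suppressWarnings(as.numeric(v)) else v
    if (f == "Latitude") meta$Lat_precision <- coord_precision(get(j))
    if (f == "Longitude") meta$Lon_precision <- coord_precision(get(j))
  }
  meta$Lat_precision[is.na(meta$Latitude)] <- NA_integer_
  meta$Lon_precision[is.na(meta$Longitude)] <- NA_integer_
  meta$Error_flag <- as.integer(meta$Error_flag)
  meta$Ocean_flag <- as.integer(meta$Ocean_flag)
  meta$Database_flag <- as.integer(meta$Database_flag)
  meta$Type <- as.integer(meta$Type)
  meta$Year <- as.integer(meta$Year)
  meta$Count_min <- as.integer(meta$Count_min)
  meta$Comment[is.na(meta$Comment)] <- ""
  block <- function(k) {
    m <- matrix(NA_real_, n, ncat, dimnames = list(NULL, codes))
    off <- nmeta + (k - 1) * ncat
    for (j in seq_len(ncat)) {
      v <- get(off + j)
      v[v == ""] <- NA
      m[, j] <- suppressWarnings(as.numeric(v))
    }
    m
  }
  if (n == 0) {
    empty <- matrix(NA_real_, 0, ncat, dimnames = list(NULL, codes))
    return(forcens_corpus(meta, empty, empty, empty, scheme))
  }
  forcens_corpus(meta, block(1), block(2), block(3), scheme)
}
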