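#' Binary flag schemes
#'
#' The sample metadata carries three binary coded flags: `Error` (treatment
#' of the record), `Database` (membership in the constituent compilations)
#' and `Ocean` (basin of the sampling site). Each scheme is an ordered list
#' of named bits with values that are powers of two, so any combination of
#' states is expressible as a single integer, e.g. a `Database` value of 7
#' encodes simultaneous membership in the first three compilations (1+2+4).
#'
#' The bit tables are shipped as plain tab-delimited files under
#' `inst/extdata/` and loaded verbatim.
#'
#' @param name one of `"Error"`, `"Database"`, `"Ocean"`.
#' @return an object of class `flag_scheme`: a data frame with columns
#'   `bit`, `value`, `label` and attribute `name`.
#' @examples
#' sc <- flag_scheme("Database")
#' encode_flag(c("CLIMAP", "BUFD", "ATL947"), sc)
#' @export
flag_scheme <- function(name = c("Error", "Database", "Ocean")) {
  name <- match.arg(name)
  file <- system.file("extdata",
                      paste0("flags_", tolower(name), ".tsv"),
                      package = "forcensr", mustWork = TRUE)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(tab$value == 2^(tab$bit - 1L)), !anyDuplicated(tab$label))
  structure(tab[, c("bit", "value", "label")],
            name = name, class = c("flag_scheme", "data.frame"))
}

#' Encode a set of bit labels as a flag integer
#'
#' @param labels character vector of bit labels (possibly empty).
#' @param scheme a [flag_scheme()].
#' @return integer: sum of the corresponding power-of-two values; an empty
#'   label set encodes to 0.
#' @export
encode_flag <- function(labels, scheme) {
  stopifnot(inherits(scheme, "flag_scheme"))
  if (length(labels) == 0) return(0L)
  idx <- match(labels, scheme$label)
  if (anyNA(idx)) {
    stop("unknown flag label(s) for scheme ", attr(scheme, "name"), ": ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  as.integer(sum(scheme$value[unique(idx)]))
}

#' Decode a flag integer into its set of bit labels
#'
#' Exact inverse of [encode_flag()]: `decode_flag(encode_flag(S)) == S` for
#' any subset `S` of the scheme's labels.
#'
#' @param value non-negative integer within the scheme's bit range.
#' @param scheme a [flag_scheme()].
#' @return character vector of bit labels in scheme order.
#' @export
decode_flag <- function(value, scheme) {
  stopifnot(inherits(scheme, "flag_scheme"), length(value) == 1L,
            !is.na(value), value >= 0)
  value <- as.integer(value)
  stray <- bitwAnd(value, bitwNot(as.integer(sum(scheme$value))))
  if (stray != 0L) {
    stop("value ", value, " carries bit(s) outside the ",
         attr(scheme, "name"), " scheme: stray value ", stray)
  }
  scheme$label[bitwAnd(value, scheme$value) != 0L]
}

#' Test whether a flag value has a given bit label set
#' @inheritParams decode_flag
#' @param label a single bit label of the scheme.
#' @return logical
#' @export
flag_has <- function(value, label, scheme) {
  v <- scheme$value[match(label, scheme$label)]
  if (is.na(v)) stop("unknown flag label: ", label)
  bitwAnd(as.integer(value), as.integer(v)) != 0L
}
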