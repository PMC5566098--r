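#' Process one source dataset through taxonomy, metadata and count QC
#'
#' Runs the single-dataset half of the curation procedure in its fixed
#' order: synonym-resolved abundances go through the dataset-specific
#' merge rules and not-available marking; metadata is standardised and the
#' Ocean/Database flags assigned; count data is corrected (stated total
#' versus category sum), completed with zeros where a zero 'unidentified'
#' entry and a near-complete sum warrant it, and renormalised or flagged;
#' the single-sample quality filters and endemism rules are applied; and
#' finally the dataset is internally dereplicated (plain, then
#' incorrect-position, then different-name duplicates). Every
#' value-altering step sets Error bit 1 ('modified'), appends to the
#' record's comment and writes an audit entry. A record can be flagged for
#' exclusion for more than one reason, so the by-reason tallies of the
#' processing ledger may exceed the number of excluded records.
#'
#' @param ds a [source_dataset()].
#' @param scheme a [forcens_taxonomy()] scheme.
#' @param ocean_provider basin provider for [assign_ocean_flag()].
#' @param bathymetry optional depth provider for [resolve_position()].
#' @param thresholds optional overrides for the dereplication thresholds.
#' @return list: `corpus` (processed [forcens_corpus()]), `ledger` (one
#'   row: `dataset`, `total`, `included`, `excluded`, `numerical`,
#'   `taxonomic`, `other`, `duplicates`).
#' @export
process_dataset <- function(ds, scheme = forcens_taxonomy(),
                            ocean_provider = basin_fallback,
                            bathymetry = NULL, thresholds = list()) {
  stopifnot(inherits(ds, "source_dataset"))
  n <- nrow(ds$meta)
  codes <- corpus_codes(scheme)
  db_scheme <- flag_scheme("Database")
  ocean_scheme <- flag_scheme("Ocean")
  err_scheme <- flag_scheme("Error")

  original <- counts <- relative <-
    matrix(NA_real_, n, length(codes), dimnames = list(NULL, codes))
  meta_rows <- vector("list", n)
  audit <- list()
  db_flag <- if (!is.null(ds$database) && !is.na(ds$database)) {
    encode_flag(ds$database, db_scheme)
  } else 0L

  for (i in seq_len(n)) {
    raw_meta <- as.list(ds$meta[i, , drop = FALSE])
    meta <- standardize_metadata(raw_meta)
    if (is.na(meta$Sample_ID)) {
      meta$Sample_ID <- sprintf("%s-%04d", toupper(ds$id), i)
    }
    meta$Database_flag <- bitwOr(meta$Database_flag, db_flag)
    meta$Type <- if (ds$type == "raw") 1L else 0L
    id <- meta$Sample_ID
    bits <- meta$Error_flag
    notes <- character(0)

    # taxonomy: merge rules, then not-available marking
    vals <- ds$abundance[i, ]
    mr <- apply_merge_rules(vals, ds$id, scheme)
    if (mr$modified) {
      bits <- bitwOr(bits, 1L)
      notes <- c(notes, mr$notes)
      audit[[length(audit) + 1L]] <-
        audit_entry(id, "merge_rules", "abundance", "",
                    paste(mr$notes, collapse = "; "))
    }
    reported_eff <- union(ds$reported,
                          intersect(names(mr$values), codes))
    orig <- mark_unrecorded(mr$values, reported_eff, scheme)
    original[i, ] <- orig

    meta$Ocean_flag <- assign_ocean_flag(meta$Latitude, meta$Longitude,
                                         ocean_provider, ocean_scheme)

    # count standardisation and correction
    if (ds$type == "raw") {
      cnt <- orig
      tc <- correct_total_count(cnt, meta$Count, scheme)
      if (tc$modified) {
        bits <- bitwOr(bits, 1L)
        notes <- c(notes, tc$note)
        audit[[length(audit) + 1L]] <-
          audit_entry(id, "total_count", "Count", meta$Count, tc$total)
      }
      meta$Count <- tc$total
      rel <- cnt / tc$total
    } else {
      cnt <- rep(NA_real_, length(codes))
      names(cnt) <- codes
      rel <- orig
      cz <- complete_with_zeros(rel, scheme)
      if (cz$modified) {
        bits <- bitwOr(bits, 1L)
        notes <- c(notes, "not-available categories completed with zeros")
        audit[[length(audit) + 1L]] <-
          audit_entry(id, "complete_with_zeros", "abundance", "", "zeros")
      }
      rel <- cz$values
    }
    rn <- renormalize_or_flag(rel, scheme)
    bits <- bitwOr(bits, rn$bits)
    if (rn$modified) {
      bits <- bitwOr(bits, 1L)
      notes <- c(notes, "relative abundances renormalised to sum 1")
    }
    rel <- rn$values

    # quality filters (order-independent bit accumulation, except that
    # the endemism merge precedes the unidentified filter)
    total_for_filter <- if (!is.na(meta$Count)) meta$Count else
      meta$Count_min
    bits <- bitwOr(bits, filter_low_count(total_for_filter))
    if (rn$bits == 0L) {
      en <- suppressWarnings(
        apply_endemism_rules(rel, meta$Ocean_flag, scheme, ocean_scheme))
      bits <- bitwOr(bits, en$bits)
      if (en$modified) {
        bits <- bitwOr(bits, 1L)
        notes <- c(notes, en$notes)
        audit[[length(audit) + 1L]] <-
          audit_entry(id, "endemism", "abundance", "",
                      paste(en$notes, collapse = "; "))
        if (ds$type == "raw" && nrow(en$moves) > 0) {
          for (r in seq_len(nrow(en$moves))) {
            from <- en$moves$from[r]; to <- en$moves$to[r]
            v <- cnt[from]
            if (!is.na(v)) {
              cnt[to] <- if (is.na(cnt[to])) v else cnt[to] + v
              cnt[from] <- NA_real_
            }
          }
        }
      }
      rel <- en$values
    }
    bits <- bitwOr(bits, filter_unidentified(rel, scheme))
    bits <- bitwOr(bits, filter_other(meta))

    counts[i, ] <- cnt
    relative[i, ] <- rel
    meta$Error_flag <- bits
    if (length(notes)) {
      meta$Comment <- paste(c(meta$Comment[nzchar(meta$Comment)], notes),
                            collapse = "; ")
    }
    meta_rows[[i]] <- meta
  }

  meta_df <- do.call(rbind, lapply(meta_rows, function(m) {
    as.data.frame(m, stringsAsFactors = FALSE)
  }))
  meta_df$Dataset <- ds$id
  audit_df <- if (length(audit)) do.call(rbind, audit) else empty_audit()
  corpus <- forcens_corpus(meta_df, original, counts, relative, scheme,
                           audit_df)

  # internal dereplication
  dr <- dereplicate(corpus, bathymetry, thresholds)
  corpus <- dr$corpus

  err <- corpus$meta$Error_flag
  has <- function(v) sum(bitwAnd(err, v) != 0L)
  dup_removed <- sum(dr$counts)
  ledger <- data.frame(
    dataset = ds$id, total = n,
    included = sum(err <= 1),
    excluded = sum(err > 1),
    numerical = has(64L + 128L),
    taxonomic = has(16L + 32L),
    other = has(256L + 512L),
    duplicates = dup_removed, stringsAsFactors = FALSE)
  list(corpus = corpus, ledger = ledger)
}

#' Run the full curation pipeline
#'
#' Orchestrates the whole procedure: per-dataset processing
#' ([process_dataset()]) in the configured cloning order, sequential
#' dereplication across datasets ([sequential_dereplicate()]), emission of
#' the manual-review candidate list, optional application of reviewer
#' decisions, and export of the full and passing-only products. The
#' default dataset order is the known cloning order of the constituent
#' compilations (CLIMAP, BUFD, ATL947, MARGO, additions). All steps are
#' recorded: excluded and merged-away records remain in the full export
#' with their flags, the per-dataset and per-step ledgers mirror the
#' bookkeeping of the synthesis, and the audit log holds one entry per
#' modification. Re-running with identical inputs produces byte-identical
#' outputs.
#'
#' @param datasets list of [source_dataset()] objects, or a list of
#'   `list(path=, schema=)` pairs read via [read_source()]; processed in
#'   list order.
#' @param scheme a [forcens_taxonomy()] scheme.
#' @param ocean_provider basin provider for [assign_ocean_flag()].
#' @param bathymetry optional depth provider for [resolve_position()].
#' @param decisions optional manual-review decisions (data frame or file
#'   path) applied after the automatic stages.
#' @param out_dir optional directory: writes `forcens_full.tsv`,
#'   `forcens_passing.tsv`, `ledger_datasets.tsv`, `ledger_steps.tsv`,
#'   `manual_candidates.tsv` and `audit.jsonl`.
#' @param thresholds optional overrides for dereplication thresholds.
#' @return object of class `forcens_run`: list with `corpus`,
#'   `dataset_ledger`, `step_ledger`, `manual_candidates`, `clusters`.
#' @export
forcens_run <- function(datasets, scheme = forcens_taxonomy(),
                        ocean_provider = basin_fallback, bathymetry = NULL,
                        decisions = NULL, out_dir = NULL,
                        thresholds = list()) {
  datasets <- lapply(datasets, function(d) {
    if (inherits(d, "source_dataset")) return(d)
    if (!file.exists(d$path)) stop("missing input file: ", d$path)
    read_source(d$path, d$schema, scheme)
  })
  processed <- lapply(datasets, process_dataset, scheme = scheme,
                      ocean_provider = ocean_provider,
                      bathymetry = bathymetry, thresholds = thresholds)
  dataset_ledger <- do.call(rbind, lapply(processed, `[[`, "ledger"))
  corpora <- lapply(processed, `[[`, "corpus")
  sq <- sequential_dereplicate(corpora,
                               datasets = vapply(datasets, `[[`,
                                                 character(1), "id"),
                               bathymetry = bathymetry,
                               thresholds = thresholds)
  corpus <- sq$corpus
  manual <- manual_review_candidates(corpus, thresholds)
  if (!is.null(decisions)) {
    corpus <- apply_manual_decisions(corpus, decisions, bathymetry)
  }
  run <- structure(list(corpus = corpus, dataset_ledger = dataset_ledger,
                        step_ledger = sq$steps,
                        manual_candidates = manual,
                        clusters = sq$clusters),
                   class = "forcens_run")
  if (!is.null(out_dir)) export_run(run, out_dir)
  run
}

#' @export
print.forcens_run <- function(x, ...) {
  cat("forcens_run:", n_samples(x$corpus), "records,",
      length(active_ids(x$corpus)), "passing;",
      nrow(x$manual_candidates), "manual-review candidates\n")
  print(x$step_ledger, row.names = FALSE)
  invisible(x)
}

#' Export the products and ledgers of a pipeline run
#'
#' @param run a `forcens_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_forcens(run$corpus, file.path(out_dir, "forcens_full.tsv"), "full")
  write_forcens(run$corpus, file.path(out_dir, "forcens_passing.tsv"),
                "passing_only")
  utils::write.table(run$dataset_ledger,
                     file.path(out_dir, "ledger_datasets.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$step_ledger,
                     file.path(out_dir, "ledger_steps.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$manual_candidates,
                     file.path(out_dir, "manual_candidates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  con <- file(file.path(out_dir, "audit.jsonl"), open = "wt")
  on.exit(close(con))
  aud <- run$corpus$audit
  for (r in seq_len(nrow(aud))) {
    writeLines(jsonlite::toJSON(as.list(aud[r, ]), auto_unbox = TRUE), con)
  }
  invisible(out_dir)
}
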