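#' Faunal similarity between two census records
#'
#' The basic criterion all duplicate types share: a maximum deviation in
#' relative abundance of individual categories below 1% (absolute
#' percentage points, as a fraction: < 0.01), ignoring categories with no
#' information in either sample, and a maximum deviation in total counted
#' individuals of 3% of the pair-average total. The total criterion is
#' vacuously true when either total is unknown. Morphotype categories are
#' excluded from the comparison. A pair sharing zero numeric categories
#' never passes.
#'
#' @param rel_a,rel_b named numeric vectors of corrected relative
#'   abundances over [corpus_codes()].
#' @param total_a,total_b total counted individuals (may be `NA`).
#' @param scheme a [forcens_taxonomy()] scheme.
#' @param max_dev,max_total_dev thresholds (defaults 0.01 and 0.03).
#' @return list (`SimilarityVerdict`): `max_category_deviation`,
#'   `total_count_deviation` (`NA` when vacuous), `categories_compared`,
#'   `passes_basic`.
#' @export
basic_similarity <- function(rel_a, rel_b, total_a = NA, total_b = NA,
                             scheme, max_dev = 0.01, max_total_dev = 0.03) {
  cc <- counting_codes(scheme)
  a <- rel_a[cc]; b <- rel_b[cc]
  shared <- !is.na(a) & !is.na(b)
  ncomp <- sum(shared)
  maxd <- if (ncomp > 0) max(abs(a[shared] - b[shared])) else Inf
  totd <- if (!is.na(total_a) && !is.na(total_b)) {
    abs(total_a - total_b) / mean(c(total_a, total_b))
  } else NA_real_
  passes <- ncomp > 0 && maxd < max_dev &&
    (is.na(totd) || totd <= max_total_dev)
  list(max_category_deviation = maxd, total_count_deviation = totd,
       categories_compared = ncomp, passes_basic = passes)
}

#' Levenshtein distance between sample names
#'
#' Standard edit distance via [utils::adist()]; zero iff identical. Names
#' are expected to be uppercased by metadata standardisation, so case never
#' contributes.
#'
#' @param a,b character scalars (or vectors recycled pairwise).
#' @return integer edit distance(s).
#' @export
name_distance <- function(a, b) {
  as.integer(diag(utils::adist(a, b)))
}

#' Classify a faunally similar pair into a duplicate type
#'
#' Applied only to pairs passing [basic_similarity()]. The additional
#' criteria are evaluated sequentially, first match wins:
#' \enumerate{
#'   \item plain: geographic distance < 2.621 km and identical name;
#'   \item incorrect_position: identical name (any distance);
#'   \item different_name: distance < 0.5242 km (no name ceiling).
#' }
#' Pairs matching none are candidates for the manual review stage. With a
#' missing position the distance-based types are unevaluable but
#' incorrect_position can still fire on the name.
#'
#' @param passes_basic logical from [basic_similarity()].
#' @param dist_km geographic distance in km (`NA` when a position is
#'   missing).
#' @param name_dist Levenshtein distance between the names.
#' @param plain_km,name_km distance thresholds (2.621 and 0.5242 km).
#' @return one of `"plain"`, `"incorrect_position"`, `"different_name"`,
#'   `"none"`.
#' @export
classify_pair <- function(passes_basic, dist_km, name_dist,
                          plain_km = 2.621, name_km = 0.5242) {
  if (!isTRUE(passes_basic)) return("none")
  if (!is.na(dist_km) && dist_km < plain_km && name_dist == 0) return("plain")
  if (name_dist == 0) return("incorrect_position")
  if (!is.na(dist_km) && dist_km < name_km) return("different_name")
  "none"
}

pairwise_km <- function(lat, lon) {
  n <- length(lat)
  la <- matrix(lat, n, n)
  lo <- matrix(lon, n, n)
  matrix(distance_km(as.vector(la), as.vector(lo),
                     as.vector(t(la)), as.vector(t(lo))), n, n)
}

row_max_abs_dev <- function(M, v) {
  # per-row max |M[i,] - v| ignoring NA; NA when no shared category
  D <- abs(sweep(M, 2, v, "-"))
  do.call(pmax, c(as.data.frame(D), na.rm = TRUE))
}

similar_pairs <- function(corpus, ids, max_dev = 0.01,
                          max_total_dev = 0.03) {
  # all unordered pairs among ids passing the basic faunal criteria
  cc <- counting_codes(corpus$scheme)
  R <- corpus$relative[ids, cc, drop = FALSE]
  total <- corpus$meta[ids, "Count"]
  n <- length(ids)
  out <- vector("list", n)
  for (i in seq_len(max(0, n - 1))) {
    j <- (i + 1):n
    Mj <- R[j, , drop = FALSE]
    maxd <- row_max_abs_dev(Mj, R[i, ])
    shared <- rowSums(!is.na(Mj) & !is.na(rep(1, length(j)) %o% R[i, ])) > 0
    totd <- abs(total[j] - total[i]) / ((total[j] + total[i]) / 2)
    pass <- !is.na(maxd) & shared & maxd < max_dev &
      (is.na(totd) | totd <= max_total_dev)
    hit <- which(pass)
    if (length(hit)) {
      out[[i]] <- data.frame(id_a = ids[i], id_b = ids[j[hit]],
                             max_dev = maxd[hit], tot_dev = totd[hit],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(id_a = character(0), id_b = character(0),
                      max_dev = numeric(0), tot_dev = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res
}

cluster_pairs <- function(pairs) {
  # transitive closure of pairwise matches -> list of member-id vectors
  if (nrow(pairs) == 0) return(list())
  g <- igraph::graph_from_data_frame(pairs[, c("id_a", "id_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(m) sort(unique(m)))
  members[order(vapply(members, `[`, character(1), 1))]
}

#' Find duplicate clusters of one type in a corpus
#'
#' Scans all records passing the selection criteria (Error flag <= 1) for
#' pairs satisfying [basic_similarity()] whose [classify_pair()] type
#' equals the requested stage, and collects them into maximal clusters by
#' transitive closure (if a~b and b~c, one cluster \{a,b,c\}). Ordering is
#' deterministic: members and clusters are sorted by sample id.
#'
#' @param corpus a [forcens_corpus()].
#' @param stage `"plain"`, `"incorrect_position"` or `"different_name"`.
#' @param thresholds named list overriding `max_dev`, `max_total_dev`,
#'   `plain_km`, `name_km`.
#' @return list of clusters: each a list with `members` (sorted ids),
#'   `type` and `evidence` (data frame of supporting pairs).
#' @export
find_duplicates <- function(corpus, stage = c("plain", "incorrect_position",
                                              "different_name"),
                            thresholds = list()) {
  stage <- match.arg(stage)
  th <- utils::modifyList(list(max_dev = 0.01, max_total_dev = 0.03,
                               plain_km = 2.621, name_km = 0.5242),
                          thresholds)
  ids <- sort(active_ids(corpus))
  if (length(ids) < 2) return(list())
  meta <- corpus$meta[ids, ]

  if (stage %in% c("plain", "incorrect_position")) {
    groups <- split(ids, meta$Sample_name)
    groups <- groups[lengths(groups) >= 2]
    cand <- do.call(rbind, lapply(unname(groups), function(g) {
      similar_pairs(corpus, g, th$max_dev, th$max_total_dev)
    }))
  } else {
    lat <- meta$Latitude; lon <- meta$Longitude
    pos <- !is.na(lat) & !is.na(lon)
    D <- pairwise_km(ifelse(pos, lat, 0), ifelse(pos, lon, 0))
    D[!pos, ] <- NA; D[, !pos] <- NA
    close_idx <- which(upper.tri(D) & D < th$name_km, arr.ind = TRUE)
    cand <- NULL
    if (nrow(close_idx)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(close_idx)), function(r) {
        pr <- similar_pairs(corpus,
                            ids[c(close_idx[r, 1], close_idx[r, 2])],
                            th$max_dev, th$max_total_dev)
        pr
      }))
    }
  }
  if (is.null(cand) || nrow(cand) == 0) return(list())

  # verify full sequential classification so stages stay disjoint
  keep <- logical(nrow(cand))
  dist_km <- name_dist <- numeric(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$id_a[r]; b <- cand$id_b[r]
    ma <- corpus$meta[a, ]; mb <- corpus$meta[b, ]
    d <- if (!is.na(ma$Latitude) && !is.na(mb$Latitude) &&
             !is.na(ma$Longitude) && !is.na(mb$Longitude)) {
      distance_km(ma$Latitude, ma$Longitude, mb$Latitude, mb$Longitude)
    } else NA_real_
    nd <- name_distance(ma$Sample_name, mb$Sample_name)
    dist_km[r] <- d; name_dist[r] <- nd
    keep[r] <- classify_pair(TRUE, d, nd, th$plain_km, th$name_km) == stage
  }
  cand$dist_km <- dist_km
  cand$name_dist <- name_dist
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(list())

  members <- cluster_pairs(cand)
  lapply(members, function(m) {
    ev <- cand[cand$id_a %in% m & cand$id_b %in% m, , drop = FALSE]
    list(members = m, type = stage, evidence = ev)
  })
}

#' Resolve the position of an incorrect-position duplicate cluster
#'
#' First checks whether the location discrepancy is a minutes-as-decimals
#' mis-transformation: all repair combinations for each member pair
#' (excluding combinations with more than two repaired coordinates) are
#' enumerated, and a repair is accepted iff it moves a member more than
#' 3.7 km from its original position and brings the pair within 2.621 km.
#' If no repair is accepted, the positions are cross-checked against a
#' pluggable bathymetry provider: the member whose stated water depth best
#' matches the provider depth at its position wins. With no provider and a
#' negative repair screen, the position of the older publication is kept
#' and the cluster is logged as unresolved.
#'
#' @param corpus a [forcens_corpus()].
#' @param members sample ids of the cluster.
#' @param bathymetry optional function `(latitude, longitude) -> depth` in
#'   metres, positive down.
#' @param displacement_km,accept_km acceptance thresholds (3.7 and
#'   2.621 km).
#' @return list with `latitude`, `longitude`, `lat_precision`,
#'   `lon_precision`, `source_id`, `method` (`"transform"`, `"bathymetry"`
#'   or `"unresolved"`).
#' @export
resolve_position <- function(corpus, members, bathymetry = NULL,
                             displacement_km = 3.7, accept_km = 2.621) {
  meta <- corpus$meta[members, ]
  prs <- utils::combn(seq_along(members), 2, simplify = FALSE)
  best <- NULL
  for (pr in prs) {
    i <- pr[1]; j <- pr[2]
    if (anyNA(c(meta$Latitude[c(i, j)], meta$Longitude[c(i, j)]))) next
    a0 <- c(meta$Latitude[i], meta$Longitude[i])
    b0 <- c(meta$Latitude[j], meta$Longitude[j])
    for (cmb in enumerate_transform_combinations(a0, b0)) {
      if (!any(cmb$transformed)) next
      disp <- max(transform_displacement_km(a0[1], a0[2],
                                            cmb$a[1], cmb$a[2]),
                  transform_displacement_km(b0[1], b0[2],
                                            cmb$b[1], cmb$b[2]))
      d <- distance_km(cmb$a[1], cmb$a[2], cmb$b[1], cmb$b[2])
      if (disp > displacement_km && d < accept_km) {
        if (is.null(best) || d < best$d) {
          a_fixed <- any(cmb$transformed[1:2])
          b_fixed <- any(cmb$transformed[3:4])
          src <- if (!b_fixed) j else if (!a_fixed) i else i
          pos <- if (!b_fixed) b0 else if (!a_fixed) a0 else cmb$a
          best <- list(d = d, src = src, pos = pos,
                       repaired = b_fixed && a_fixed)
        }
      }
    }
  }
  if (!is.null(best)) {
    k <- best$src
    return(list(latitude = best$pos[1], longitude = best$pos[2],
                lat_precision = meta$Lat_precision[k],
                lon_precision = meta$Lon_precision[k],
                source_id = members[k], method = "transform"))
  }
  depth_known <- !is.na(meta$Water_depth) & !is.na(meta$Latitude) &
    !is.na(meta$Longitude)
  if (!is.null(bathymetry) && any(depth_known)) {
    dd <- rep(Inf, nrow(meta))
    for (k in which(depth_known)) {
      dd[k] <- abs(meta$Water_depth[k] -
                     bathymetry(meta$Latitude[k], meta$Longitude[k]))
    }
    k <- which.min(dd)
    return(list(latitude = meta$Latitude[k], longitude = meta$Longitude[k],
                lat_precision = meta$Lat_precision[k],
                lon_precision = meta$Lon_precision[k],
                source_id = members[k], method = "bathymetry"))
  }
  k <- oldest_first(meta)[1]
  list(latitude = meta$Latitude[k], longitude = meta$Longitude[k],
       lat_precision = meta$Lat_precision[k],
       lon_precision = meta$Lon_precision[k],
       source_id = members[k], method = "unresolved")
}

oldest_first <- function(meta) {
  y <- meta$Year
  y[is.na(y)] <- .Machine$integer.max
  order(y, meta$Sample_ID)
}

#' Merge a duplicate cluster into a single record
#'
#' Information-maximising merge: the assemblage (all three abundance
#' blocks, plus the assemblage-linked fields Type, Count, Count_min) is
#' carried from the member with the highest number of numeric counting
#' categories; the geographic position with the highest precision is
#' assigned (incorrect-position clusters go through [resolve_position()]);
#' for sediment depth the most complete set wins (both bounds and average
#' beat average-only); for all other metadata the existence of information
#' beats absence, and conflicting values resolve to the older publication.
#' The Database flag of the merged record is the bitwise OR over members,
#' so provenance is never lost. Discarded members stay in the corpus with
#' Error bit 4 ('duplicate', value 8) set and a comment naming the merged
#' record; the merged record keeps a comment trail naming all members and
#' their resource DOIs. Ties (equal category counts, equal precision,
#' equal or missing years) break to the lexicographically smaller sample
#' id.
#'
#' @param corpus a [forcens_corpus()].
#' @param cluster a cluster from [find_duplicates()] (list with `members`
#'   and `type`), or any list with those elements.
#' @param bathymetry optional provider for [resolve_position()].
#' @return the updated corpus.
#' @export
merge_cluster <- function(corpus, cluster, bathymetry = NULL) {
  members <- sort(cluster$members)
  type <- cluster$type
  meta <- corpus$meta[members, ]
  cc <- counting_codes(corpus$scheme)

  ntaxa <- rowSums(!is.na(corpus$relative[members, cc, drop = FALSE]))
  y <- meta$Year; y[is.na(y)] <- .Machine$integer.max
  carrier_k <- order(-ntaxa, y, meta$Sample_ID)[1]
  carrier <- members[carrier_k]

  merged <- corpus$meta[carrier, ]

  # position precedence
  if (type == "incorrect_position") {
    pos <- resolve_position(corpus, members, bathymetry)
    merged$Latitude <- pos$latitude
    merged$Longitude <- pos$longitude
    merged$Lat_precision <- pos$lat_precision
    merged$Lon_precision <- pos$lon_precision
    pos_note <- paste0("; position resolved by ", pos$method, " from ",
                       pos$source_id)
  } else {
    prec <- ifelse(is.na(meta$Lat_precision), -1L, meta$Lat_precision) +
      ifelse(is.na(meta$Lon_precision), -1L, meta$Lon_precision)
    prec[is.na(meta$Latitude) | is.na(meta$Longitude)] <- -Inf
    k <- order(-prec, y, meta$Sample_ID)[1]
    merged$Latitude <- meta$Latitude[k]
    merged$Longitude <- meta$Longitude[k]
    merged$Lat_precision <- meta$Lat_precision[k]
    merged$Lon_precision <- meta$Lon_precision[k]
    pos_note <- ""
  }

  # sediment depth: most complete set of information first
  complete <- (!is.na(meta$Sample_depth_upper) &
                 !is.na(meta$Sample_depth_lower)) * 2L +
    (!is.na(meta$Sample_depth_average)) * 1L
  k <- order(-complete, y, meta$Sample_ID)[1]
  for (f in c("Sample_depth_upper", "Sample_depth_lower",
              "Sample_depth_average")) {
    merged[[f]] <- meta[[f]][k]
  }

  # remaining metadata: existence beats absence, conflicts -> older
  ord <- oldest_first(meta)
  for (f in c("Sample_name", "Device", "Water_depth", "Author", "Journal",
              "Year", "Publication_doi", "Resource_doi")) {
    v <- meta[[f]][ord]
    v <- v[!is.na(v)]
    if (length(v)) merged[[f]] <- v[1]
  }
  merged$Database_flag <- Reduce(bitwOr, meta$Database_flag)
  merged$Ocean_flag <- Reduce(bitwOr, meta$Ocean_flag)

  dois <- meta$Resource_doi[!is.na(meta$Resource_doi)]
  merged$Comment <- paste0(
    merged$Comment, "; merged ", type, " duplicates: ",
    paste(members, collapse = ", "),
    if (length(dois)) paste0(" [", paste(unique(dois), collapse = ", "), "]")
    else "", pos_note)

  corpus$meta[carrier, ] <- merged
  discarded <- setdiff(members, carrier)
  err_scheme_val <- 8L
  corpus$meta[discarded, "Error_flag"] <-
    bitwOr(as.integer(corpus$meta[discarded, "Error_flag"]), err_scheme_val)
  corpus$meta[discarded, "Comment"] <- paste0(
    corpus$meta[discarded, "Comment"], "; duplicate of ", carrier)
  corpus$audit <- rbind(corpus$audit,
                        audit_entry(carrier, paste0("merge_", type),
                                    "members", paste(members, collapse = ","),
                                    carrier))
  corpus
}

#' Dereplicate a corpus through the three automatic stages
#'
#' Runs the plain, incorrect-position and different-name stages in that
#' order (a stage is only run after all duplicates of the previous stages
#' have been treated), merging every cluster as found. Running the
#' procedure on its own output finds zero further duplicates.
#'
#' @param corpus a [forcens_corpus()].
#' @param bathymetry optional provider for [resolve_position()].
#' @param thresholds see [find_duplicates()].
#' @return list: `corpus`, `counts` (named integer vector of removed
#'   records per stage), `clusters` (all merged clusters).
#' @export
dereplicate <- function(corpus, bathymetry = NULL, thresholds = list()) {
  stages <- c("plain", "incorrect_position", "different_name")
  counts <- stats::setNames(integer(3), stages)
  clusters <- list()
  for (st in stages) {
    cl <- find_duplicates(corpus, st, thresholds)
    for (cluster in cl) {
      corpus <- merge_cluster(corpus, cluster, bathymetry)
      counts[st] <- counts[st] + length(cluster$members) - 1L
    }
    clusters <- c(clusters, cl)
  }
  list(corpus = corpus, counts = counts, clusters = clusters)
}

#' Sequentially dereplicate an ordered list of datasets
#'
#' Folds the processed datasets in their known order of cloning (the
#' default shipping order of the constituent compilations is CLIMAP, BUFD,
#' ATL947, MARGO, additions): at each step the next dataset is appended to
#' the accumulated corpus and the plain, incorrect-position and
#' different-name stages are run against it. A per-step ledger records
#' cumulative totals and stepwise duplicate counts by type.
#'
#' @param corpora ordered list of processed [forcens_corpus()] objects
#'   (each already internally dereplicated by [process_dataset()]).
#' @param datasets optional character vector of step labels.
#' @param bathymetry optional provider for [resolve_position()].
#' @param thresholds see [find_duplicates()].
#' @return list: `corpus` (merged), `steps` (ledger data frame with
#'   columns `step`, `total`, `included`, `excluded`, `duplicates`,
#'   `plain`, `position`, `name`), `clusters`.
#' @export
sequential_dereplicate <- function(corpora, datasets = NULL,
                                   bathymetry = NULL, thresholds = list()) {
  stopifnot(length(corpora) >= 1)
  if (is.null(datasets)) datasets <- paste0("step", seq_along(corpora))
  acc <- corpora[[1]]
  steps <- data.frame(step = datasets[1], total = n_samples(acc),
                      included = length(active_ids(acc)),
                      excluded = n_samples(acc) - length(active_ids(acc)),
                      duplicates = NA_integer_, plain = NA_integer_,
                      position = NA_integer_, name = NA_integer_,
                      stringsAsFactors = FALSE)
  clusters <- list()
  for (k in seq_along(corpora)[-1]) {
    acc <- corpus_bind(acc, corpora[[k]])
    res <- dereplicate(acc, bathymetry, thresholds)
    acc <- res$corpus
    clusters <- c(clusters, res$clusters)
    steps <- rbind(steps, data.frame(
      step = datasets[k], total = n_samples(acc),
      included = length(active_ids(acc)),
      excluded = n_samples(acc) - length(active_ids(acc)),
      duplicates = sum(res$counts), plain = res$counts[["plain"]],
      position = res$counts[["incorrect_position"]],
      name = res$counts[["different_name"]], stringsAsFactors = FALSE))
  }
  list(corpus = acc, steps = steps, clusters = clusters)
}

#' List remaining candidate duplicates for manual review
#'
#' After the automatic stages, all remaining record pairs satisfying only
#' the basic faunal-similarity criteria are emitted for inspection by the
#' compiler, with their name and geographic distances, sorted by
#' similarity (most similar first). Nothing is merged automatically; a
#' decisions table produced by the reviewer can be applied with
#' [apply_manual_decisions()].
#'
#' @param corpus a [forcens_corpus()].
#' @param thresholds see [find_duplicates()].
#' @return data frame: `id_a`, `id_b`, `max_dev`, `tot_dev`, `name_dist`,
#'   `dist_km`.
#' @export
manual_review_candidates <- function(corpus, thresholds = list()) {
  th <- utils::modifyList(list(max_dev = 0.01, max_total_dev = 0.03),
                          thresholds)
  ids <- sort(active_ids(corpus))
  if (length(ids) < 2) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      max_dev = numeric(0), tot_dev = numeric(0),
                      name_dist = integer(0), dist_km = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- similar_pairs(corpus, ids, th$max_dev, th$max_total_dev)
  if (nrow(pairs) == 0) {
    pairs$name_dist <- integer(0)
    pairs$dist_km <- numeric(0)
    return(pairs)
  }
  ma <- corpus$meta[pairs$id_a, ]; mb <- corpus$meta[pairs$id_b, ]
  pairs$name_dist <- name_distance(ma$Sample_name, mb$Sample_name)
  pairs$dist_km <- ifelse(
    !is.na(ma$Latitude) & !is.na(mb$Latitude) &
      !is.na(ma$Longitude) & !is.na(mb$Longitude),
    distance_km(ma$Latitude, ma$Longitude, mb$Latitude, mb$Longitude),
    NA_real_)
  pairs[order(pairs$max_dev, pairs$id_a, pairs$id_b), , drop = FALSE]
}

#' Apply reviewer decisions to manual duplicate candidates
#'
#' Consumes a decisions table (columns `id_a`, `id_b`, `action` with
#' `action` one of `"merge"`/`"keep"`) as produced by annotating the
#' output of [manual_review_candidates()]. Pairs marked `merge` are
#' clustered by transitive closure and merged with type `manual`.
#'
#' @param corpus a [forcens_corpus()].
#' @param decisions data frame or path to a tab-delimited decisions file.
#' @param bathymetry optional provider passed to [merge_cluster()].
#' @return the updated corpus.
#' @export
apply_manual_decisions <- function(corpus, decisions, bathymetry = NULL) {
  if (is.character(decisions)) {
    decisions <- utils::read.delim(decisions, stringsAsFactors = FALSE)
  }
  mg <- decisions[decisions$action == "merge", , drop = FALSE]
  if (nrow(mg) == 0) return(corpus)
  for (m in cluster_pairs(mg)) {
    corpus <- merge_cluster(corpus, list(members = m, type = "manual"),
                            bathymetry)
  }
  corpus
}
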