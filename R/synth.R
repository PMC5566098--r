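#' Synthetic analytic seafloor
#'
#' A smooth deterministic bathymetry used as the pluggable depth provider
#' in synthetic corpora and tests: a stand-in for a gridded bathymetry
#' product, not derived from one.
#'
#' @param latitude,longitude decimal degrees.
#' @return depth in metres, positive down.
#' @export
synthetic_seafloor <- function(latitude, longitude) {
  2500 + 1500 * sin(3 * latitude * pi / 180) * cos(2 * longitude * pi / 180)
}

#' Configuration for a synthetic multi-dataset corpus
#'
#' The generator emulates the statistical shape of overlapping census
#' compilations: cloned samples recur across datasets under rounding
#' errors, name mutations and coordinate mis-transformations, while
#' planted quality violations and beyond-threshold negative controls give
#' every pipeline stage a ground truth to be checked against.
#'
#' Defaults describe the reference study conditions used by the package's
#' own validation: 5 datasets of 200 samples with 15% overlap, skewed
#' Dirichlet assemblages (concentration 0.3) over the 41 recordable
#' species, values at the 0.1% reporting granularity, total-count jitter
#' within 1%, and position jitter well inside the duplicate-stage distance
#' limits.
#'
#' @param n_datasets number of source datasets (cloning order = list
#'   order; ids follow the constituent compilations).
#' @param samples_per_dataset records per dataset.
#' @param overlap_fraction fraction of each later dataset cloned from
#'   earlier datasets.
#' @param richness number of recordable species categories drawn on.
#' @param concentration Dirichlet concentration of assemblage composition.
#' @param granularity reporting granularity of relative values (0 = exact).
#' @param total_count_jitter relative jitter of clone total counts (0-1).
#' @param position_jitter_km position jitter of plain clones (km).
#' @param clone_types named weights for duplicate types among clones
#'   (`plain`, `incorrect_position`, `different_name`).
#' @param violations_per_dataset planted QC violations per dataset (max 5:
#'   one each of sum-deviation/low-count, unidentified, endemic, missing
#'   coordinates, non-standard device).
#' @param negative_pairs beyond-threshold near-duplicate pairs planted as
#'   negative controls in the last dataset.
#' @param internal_duplicates within-dataset plain clones planted in the
#'   fourth dataset (0 when fewer datasets).
#' @param seed integer seed; fully determines the corpus.
#' @return object of class `corpus_config`.
#' @export
corpus_config <- function(n_datasets = 5, samples_per_dataset = 200,
                          overlap_fraction = 0.15, richness = 41,
                          concentration = 0.3, granularity = 0.001,
                          total_count_jitter = 0.01,
                          position_jitter_km = 0.4,
                          clone_types = c(plain = 0.4,
                                          incorrect_position = 0.3,
                                          different_name = 0.3),
                          violations_per_dataset = 5, negative_pairs = 6,
                          internal_duplicates = 2, seed = 1) {
  cfg <- list(n_datasets = n_datasets,
              samples_per_dataset = samples_per_dataset,
              overlap_fraction = overlap_fraction, richness = richness,
              concentration = concentration, granularity = granularity,
              total_count_jitter = total_count_jitter,
              position_jitter_km = position_jitter_km,
              clone_types = clone_types,
              violations_per_dataset = violations_per_dataset,
              negative_pairs = negative_pairs,
              internal_duplicates = internal_duplicates, seed = seed)
  stopifnot(cfg$overlap_fraction >= 0, cfg$overlap_fraction <= 1,
            cfg$granularity >= 0, cfg$total_count_jitter >= 0)
  if (cfg$overlap_fraction > 0 && cfg$n_datasets < 2) {
    stop("overlap requires at least two datasets")
  }
  structure(cfg, class = "corpus_config")
}

endemic_codes <- c("Globigerinoides_ruber_pink", "Globoquadrina_conglomerata",
                   "Globorotaloides_hexagonus", "Globigerinella_adamsi")

synth_dataset_ids <- c("CLIMAP", "BUFD", "ATL947", "MARGO", "ADDITIONS",
                       paste0("EXTRA", 1:20))
synth_database_labels <- c("CLIMAP", "BUFD", "ATL947",
                           "MARGO North Atlantic", NA, rep(NA, 20))

km_per_deg <- pi * 6371 / 180  # 111.1949 km per degree of latitude

#' Generate a synthetic multi-dataset corpus with a truth ledger
#'
#' Base samples are drawn with Dirichlet-distributed assemblages over the
#' master taxonomy and positions on a jittered half-degree grid
#' (guaranteeing tens of kilometres of separation between distinct
#' samples and unique names, so no unplanted pair can satisfy the
#' automatic duplicate criteria). Later datasets receive clones of earlier
#' bases with, by type: value rounding to the reporting granularity and
#' sub-threshold position jitter (plain), a minutes-as-decimals corruption
#' of the latitude displacing the record beyond twice the plain-duplicate
#' distance (incorrect_position; the minute value is chosen at planning
#' time so the displaced point stays isolated from all other samples), or
#' a punctuation mutation of the name with a jitter inside the
#' different-name distance limit (different_name). Within-threshold clones
#' are validated against the basic faunal-similarity predicate at
#' generation time. Planted QC violations (relative sum deviating > 5%,
#' total count < 150, unidentified > 5%, *G. ruber* pink in the Pacific,
#' missing coordinates, dredge sampling) and beyond-threshold
#' negative-control pairs (each violated criterion exceeded by at least a
#' factor of two) are recorded in the ledger. Out-of-basin endemic
#' categories are zero in all non-violation samples so the ledger accounts
#' for every exclusion.
#'
#' @param config a [corpus_config()].
#' @param scheme a [forcens_taxonomy()] scheme.
#' @return list with `datasets` (list of [source_dataset()]), `truth`
#'   (list of data frames: `origins`, `clusters` with one row per planted
#'   duplicate pair, `violations`, `negatives`), `config` and `scheme`.
#' @export
generate_corpus <- function(config = corpus_config(),
                            scheme = forcens_taxonomy()) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  nds <- config$n_datasets
  S <- config$samples_per_dataset
  ds_ids <- synth_dataset_ids[seq_len(nds)]
  ds_db <- synth_database_labels[seq_len(nds)]
  ds_type <- ifelse(seq_len(nds) %% 2 == 1, "raw", "relative")
  ds_year <- 1980 + 5 * seq_len(nds)

  species <- taxon_codes(scheme, "species")
  species <- species[scheme$categories$recorded[
    match(species, scheme$categories$code)]]
  species <- species[seq_len(min(config$richness, length(species)))]
  unid <- scheme$unidentified
  morpho <- c("Trilobatus_sacculifer_sac", "Trilobatus_sacculifer_wosac")

  # per-dataset reported category lists (later regional studies report less)
  reported <- vector("list", nds)
  for (k in seq_len(nds)) {
    drop_n <- if (k == 3) 4 else if (k == 5) 8 else 0
    rep_k <- if (drop_n > 0) species[seq_len(length(species) - drop_n)]
      else species
    reported[[k]] <- c(rep_k, unid, if (k == 1) morpho)
  }

  n_clone <- c(0, rep(round(config$overlap_fraction * S), max(0, nds - 1)))
  n_int <- if (nds >= 4) config$internal_duplicates else 0
  n_negm <- 2 * config$negative_pairs
  neg_ds <- nds
  n_viol <- pmin(config$violations_per_dataset, 5)

  # ---- plan sample counts -------------------------------------------
  n_new <- integer(nds)
  for (k in seq_len(nds)) {
    n_new[k] <- S - n_clone[k] - (if (k == 4) n_int else 0) -
      (if (k == neg_ds) config$negative_pairs else 0)
    if (n_new[k] < n_viol + 1) stop("dataset too small for requested plants")
  }
  n_base <- sum(n_new)
  base_ds <- rep(seq_len(nds), n_new)
  # row index of each base within its dataset (bases are emitted first)
  base_row <- unlist(lapply(n_new, seq_len))

  # ---- physical base samples ----------------------------------------
  lat_grid <- seq(-57.75, 57.75, by = 0.5)
  lon_grid <- seq(-179.75, 179.75, by = 0.5)
  cells <- sample(length(lat_grid) * length(lon_grid), n_base)
  lat <- lat_grid[(cells - 1) %% length(lat_grid) + 1] +
    stats::runif(n_base, -0.05, 0.05)
  lon <- lon_grid[(cells - 1) %/% length(lat_grid) + 1] +
    stats::runif(n_base, -0.05, 0.05)

  bases <- vector("list", n_base)
  for (i in seq_len(n_base)) {
    w <- stats::rgamma(length(species), config$concentration)
    p <- w / sum(w)
    N <- sample(250:350, 1)
    counts <- stats::setNames(as.numeric(stats::rmultinom(1, N, p)), species)
    nu <- stats::rbinom(1, 4, 0.5)
    bases[[i]] <- list(
      name = sprintf("SYN-%04d", i), lat = lat[i], lon = lon[i],
      prec = 4L, counts = counts, unid = nu, total = N + nu,
      device = sample(c("Gravity", "Piston", "Box", "Multi"), 1),
      water_depth = round(synthetic_seafloor(lat[i], lon[i])))
  }

  zero_category <- function(b, codes) {
    codes <- intersect(codes, names(b$counts))
    mass <- sum(b$counts[codes])
    if (mass > 0) {
      big <- names(which.max(b$counts[setdiff(names(b$counts), codes)]))
      b$counts[big] <- b$counts[big] + mass
      b$counts[codes] <- 0
    }
    b
  }
  for (i in seq_len(n_base)) {
    bases[[i]] <- zero_category(bases[[i]], endemic_codes)
    # a dataset never holds values it does not report
    bases[[i]] <- zero_category(bases[[i]],
                                setdiff(species, reported[[base_ds[i]]]))
  }

  # ---- role planning -------------------------------------------------
  is_violation <- logical(n_base)
  for (k in seq_len(nds)) {
    idx <- which(base_ds == k)
    is_violation[idx[seq_len(n_viol)]] <- TRUE
  }
  reserved <- is_violation

  internal_pick <- integer(0)
  if (n_int > 0) {
    internal_pick <- sort(sample(which(base_ds == 4 & !reserved), n_int))
    reserved[internal_pick] <- TRUE
  }
  negative_pick <- integer(0)
  neg_kinds <- character(0)
  if (config$negative_pairs > 0) {
    negative_pick <- sort(sample(which(base_ds == neg_ds & !reserved),
                                 config$negative_pairs))
    reserved[negative_pick] <- TRUE
    neg_kinds <- rep_len(c("category_dev", "far_apart", "total_dev"),
                         config$negative_pairs)
    if (ds_type[neg_ds] != "raw") {
      neg_kinds[neg_kinds == "total_dev"] <- "category_dev"
    }
  }

  tw <- config$clone_types / sum(config$clone_types)
  clone_plan <- NULL
  for (k in seq_len(nds)[-1]) {
    if (n_clone[k] == 0) next
    elig <- which(base_ds < k & !reserved)
    pick <- sort(sample(elig, n_clone[k]))
    reserved[pick] <- TRUE
    counts_by_type <- diff(round(cumsum(c(0, tw)) * n_clone[k]))
    types <- rep(names(tw), counts_by_type)
    clone_plan <- rbind(clone_plan,
                        data.frame(base = pick, step = k, type = types,
                                   stringsAsFactors = FALSE))
  }

  # host sets determine which categories must be zero at truth level
  if (!is.null(clone_plan)) {
    for (r in seq_len(nrow(clone_plan))) {
      i <- clone_plan$base[r]
      hosts <- c(base_ds[i], clone_plan$step[r])
      missing <- setdiff(species, Reduce(intersect, reported[hosts]))
      if (length(missing)) bases[[i]] <- zero_category(bases[[i]], missing)
    }
  }

  # minutes-form latitude for incorrect-position bases: pick a minute
  # value whose corruption displaces beyond twice the plain threshold and
  # lands away from every other sample
  all_lat <- vapply(bases, `[[`, numeric(1), "lat")
  all_lon <- vapply(bases, `[[`, numeric(1), "lon")
  if (!is.null(clone_plan)) {
    for (r in which(clone_plan$type == "incorrect_position")) {
      i <- clone_plan$base[r]
      b <- bases[[i]]
      d0 <- trunc(abs(b$lat))
      m0 <- min(max(round((abs(b$lat) - d0) * 60), 8L), 52L)
      found <- FALSE
      for (m in unique(c(m0, 8:52))) {
        lat_true <- sign(b$lat) * (d0 + m / 60)
        lat_bad <- sign(b$lat) * (d0 + m / 100)
        disp <- distance_km(lat_true, b$lon, lat_bad, b$lon)
        others <- distance_km(lat_bad, b$lon, all_lat[-i], all_lon[-i])
        if (disp > 2 * 2.621 && disp > 3.7 && min(others) > 4) {
          bases[[i]]$lat <- lat_true
          bases[[i]]$prec <- 6L
          bases[[i]]$minutes <- m
          all_lat[i] <- lat_true
          found <- TRUE
          break
        }
      }
      if (!found) clone_plan$type[r] <- "plain"  # give up the corruption
    }
  }

  # ---- emission ------------------------------------------------------
  origins <- clusters <- violations <- negatives <- NULL
  datasets <- vector("list", nds)
  cluster_id <- 0L
  jitter_deg <- function(km) stats::runif(2, -1, 1) * km / km_per_deg

  emit_values <- function(b, rep_k) {
    vals <- c(b$counts, stats::setNames(b$unid, unid))
    if (all(morpho %in% rep_k)) {
      sac <- round(0.6 * b$counts[["Trilobatus_sacculifer"]])
      vals <- c(vals, stats::setNames(
        c(sac, b$counts[["Trilobatus_sacculifer"]] - sac), morpho))
    }
    vals[intersect(names(vals), rep_k)]
  }

  for (k in seq_len(nds)) {
    rep_k <- reported[[k]]
    meta_k <- NULL
    vals_k <- list()

    add_row <- function(b, values, lat, lon, prec_lat, prec_lon, name,
                        device = b$device, count = NULL,
                        scale_sum = NULL) {
      if (ds_type[k] == "relative") {
        tot <- sum(values[intersect(names(values), c(species, unid))])
        values <- values / tot
        if (config$granularity > 0) {
          values <- round(values / config$granularity) * config$granularity
        }
        if (!is.null(scale_sum)) {
          values <- values * scale_sum /
            sum(values[intersect(names(values), c(species, unid))])
        }
        count <- NA_real_
      } else if (is.null(count)) {
        count <- sum(values[intersect(names(values), c(species, unid))])
      }
      row <- data.frame(
        Sample_name = name, Latitude = lat, Longitude = lon,
        Lat_precision = prec_lat, Lon_precision = prec_lon,
        Water_depth = b$water_depth, Device = device,
        Sample_depth_upper = 0, Sample_depth_lower = 5,
        Author = "Synthetic compiler", Journal = "Synthetic Data Journal",
        Year = ds_year[k],
        Publication_doi = sprintf("10.5555/%s", tolower(ds_ids[k])),
        Resource_doi = sprintf("10.5555/res-%s", tolower(ds_ids[k])),
        Count = count, Count_min = 300, stringsAsFactors = FALSE)
      meta_k <<- rbind(meta_k, row)
      vals_k[[length(vals_k) + 1L]] <<- values
      length(vals_k)
    }

    idx_new <- which(base_ds == k)
    viol_idx <- idx_new[seq_len(n_viol)]
    viol_kinds <- c(if (ds_type[k] == "raw") "low_count" else "sum_deviation",
                    "unidentified", "endemic", "no_coords",
                    "device")[seq_len(n_viol)]

    for (i in idx_new) {
      b <- bases[[i]]
      values <- emit_values(b, rep_k)
      lat_i <- b$lat; lon_i <- b$lon
      dev_i <- b$device
      count_i <- NULL
      scale_sum <- NULL
      bit <- NA_integer_
      kind <- NA_character_
      if (i %in% viol_idx) {
        kind <- viol_kinds[match(i, viol_idx)]
        bit <- switch(kind, low_count = 128L, sum_deviation = 64L,
                      unidentified = 32L, endemic = 16L, no_coords = 512L,
                      device = 256L)
        tot_v <- sum(values[intersect(names(values), c(species, unid))])
        if (kind == "low_count") {
          values <- round(values * 120 / tot_v)
          count_i <- sum(values[intersect(names(values), c(species, unid))])
        } else if (kind == "sum_deviation") {
          scale_sum <- 0.9
        } else if (kind == "unidentified") {
          sp <- setdiff(intersect(names(values), species), unid)
          big <- names(which.max(values[sp]))
          add <- round(0.08 * tot_v)
          values[unid] <- values[unid] + add
          values[big] <- max(0, values[big] - add)
        } else if (kind == "endemic") {
          repeat {
            lat_i <- stats::runif(1, -35, 20)
            lon_i <- stats::runif(1, -160, -110)
            if (min(distance_km(lat_i, lon_i, all_lat, all_lon)) > 5) break
          }
          pink <- "Globigerinoides_ruber_pink"
          sp <- setdiff(intersect(names(values), species), pink)
          big <- names(which.max(values[sp]))
          add <- max(4, round(0.02 * tot_v))
          values[pink] <- values[pink] + add
          values[big] <- max(0, values[big] - add)
        } else if (kind == "no_coords") {
          lat_i <- NA_real_; lon_i <- NA_real_
        } else if (kind == "device") {
          dev_i <- "Dredge"
        }
      }
      ri <- add_row(b, values, lat_i, lon_i, b$prec, b$prec, b$name,
                    device = dev_i, count = count_i, scale_sum = scale_sum)
      if (!is.na(bit)) {
        violations <- rbind(violations, data.frame(
          sample_id = sprintf("%s-%04d", ds_ids[k], ri), dataset = ds_ids[k],
          kind = kind, bits = bit, stringsAsFactors = FALSE))
      }
    }

    plant_clone <- function(i, type) {
      b <- bases[[i]]
      for (try in 1:20) {
        values <- emit_values(b, rep_k)
        if (config$total_count_jitter > 0 && try <= 10) {
          f <- stats::runif(1, 1 - config$total_count_jitter,
                            1 + config$total_count_jitter)
          values <- round(values * f)
        }
        lat_c <- b$lat; lon_c <- b$lon
        prec_lat <- b$prec; prec_lon <- b$prec
        name_c <- b$name
        if (type == "plain" && config$position_jitter_km > 0 && try <= 10) {
          j <- jitter_deg(config$position_jitter_km / 2)
          lat_c <- lat_c + j[1]; lon_c <- lon_c + j[2]
        } else if (type == "different_name") {
          name_c <- sub("-", "_", b$name)
          if (try <= 10) {
            j <- jitter_deg(0.15)
            lat_c <- lat_c + j[1]; lon_c <- lon_c + j[2]
          }
        } else if (type == "incorrect_position") {
          m <- b$minutes
          d0 <- trunc(abs(b$lat))
          lat_c <- sign(b$lat) * (d0 + m / 100)
          prec_lat <- 2L
        }
        # validate the planted pair against the basic similarity predicate
        sp_b <- intersect(names(b$counts), reported[[base_ds[i]]])
        rel_b <- b$counts[sp_b] / b$total
        v_sp <- intersect(names(values), species)
        rel_c <- values[v_sp] /
          sum(values[intersect(names(values), c(species, unid))])
        shared <- intersect(sp_b, v_sp)
        if (length(shared) > 0 &&
            max(abs(rel_b[shared] - rel_c[shared])) < 0.009) break
      }
      add_row(b, values, lat_c, lon_c, prec_lat, prec_lon, name_c)
    }

    if (!is.null(clone_plan)) {
      for (r in which(clone_plan$step == k)) {
        i <- clone_plan$base[r]
        ri <- plant_clone(i, clone_plan$type[r])
        cluster_id <- cluster_id + 1L
        clusters <- rbind(clusters, data.frame(
          cluster_id = cluster_id, type = clone_plan$type[r],
          base_id = sprintf("%s-%04d", ds_ids[base_ds[i]], base_row[i]),
          clone_id = sprintf("%s-%04d", ds_ids[k], ri),
          step = k, internal = FALSE, stringsAsFactors = FALSE))
      }
    }

    if (k == 4 && length(internal_pick) > 0) {
      for (i in internal_pick) {
        ri <- plant_clone(i, "plain")
        cluster_id <- cluster_id + 1L
        clusters <- rbind(clusters, data.frame(
          cluster_id = cluster_id, type = "plain",
          base_id = sprintf("%s-%04d", ds_ids[k], base_row[i]),
          clone_id = sprintf("%s-%04d", ds_ids[k], ri),
          step = k, internal = TRUE, stringsAsFactors = FALSE))
      }
    }

    if (k == neg_ds && length(negative_pick) > 0) {
      for (q in seq_along(negative_pick)) {
        i <- negative_pick[q]
        b <- bases[[i]]
        kind <- neg_kinds[q]
        values <- emit_values(b, rep_k)
        lat_c <- b$lat; lon_c <- b$lon; name_c <- b$name
        if (kind == "category_dev") {
          sp <- intersect(names(values), species)
          o <- order(-values[sp])
          hi <- sp[o[1]]; lo <- sp[o[2]]
          shift <- max(2, round(0.025 * sum(values[intersect(
            names(values), c(species, unid))])))
          values[hi] <- values[hi] - shift
          values[lo] <- values[lo] + shift
        } else if (kind == "far_apart") {
          name_c <- paste0(b$name, "X")
          lat_c <- b$lat + 1.2 / km_per_deg
        } else {  # total_dev: inflate the total by a full 7%
          cc <- intersect(names(values), c(species, unid))
          target <- round(sum(values[cc]) * 1.07)
          values <- round(values * 1.07)
          big <- names(which.max(values[cc]))
          values[big] <- values[big] + max(0, target - sum(values[cc]))
        }
        ri <- add_row(b, values, lat_c, lon_c, b$prec, b$prec, name_c)
        negatives <- rbind(negatives, data.frame(
          pair_id = q,
          id_a = sprintf("%s-%04d", ds_ids[k], base_row[i]),
          id_b = sprintf("%s-%04d", ds_ids[k], ri),
          kind = kind, stringsAsFactors = FALSE))
      }
    }

    n_k <- length(vals_k)
    ids_k <- sprintf("%s-%04d", ds_ids[k], seq_len(n_k))
    meta_k$Sample_ID <- ids_k
    ab <- matrix(NA_real_, n_k, length(rep_k), dimnames = list(NULL, rep_k))
    for (ri in seq_len(n_k)) {
      v <- vals_k[[ri]]
      keep <- intersect(names(v), rep_k)
      ab[ri, keep] <- v[keep]
    }
    datasets[[k]] <- source_dataset(
      id = ds_ids[k], database = ds_db[k], type = ds_type[k],
      meta = meta_k, abundance = ab, reported = rep_k)
    origins <- rbind(origins, data.frame(
      sample_id = ids_k, dataset = ds_ids[k], stringsAsFactors = FALSE))
  }

  empty_df <- function(...) as.data.frame(list(...), stringsAsFactors = FALSE)
  if (is.null(clusters)) {
    clusters <- empty_df(cluster_id = integer(0), type = character(0),
                         base_id = character(0), clone_id = character(0),
                         step = integer(0), internal = logical(0))
  }
  if (is.null(violations)) {
    violations <- empty_df(sample_id = character(0), dataset = character(0),
                           kind = character(0), bits = integer(0))
  }
  if (is.null(negatives)) {
    negatives <- empty_df(pair_id = integer(0), id_a = character(0),
                          id_b = character(0), kind = character(0))
  }
  list(datasets = datasets,
       truth = list(origins = origins, clusters = clusters,
                    violations = violations, negatives = negatives),
       config = config, scheme = scheme)
}

#' Write a synthetic corpus to delimited source tables
#'
#' Emits one tab-delimited table and one YAML schema per dataset plus the
#' truth-ledger tables, so the file-based ingest path ([read_source()])
#' can be exercised end to end. Taxon columns are labelled with historical
#' synonyms where the synonym table offers one, emulating heterogeneous
#' source vocabularies.
#'
#' @param gen result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cats <- gen$scheme$categories
  syn <- utils::read.delim(system.file("extdata", "synonyms.tsv",
                                       package = "forcensr"),
                           stringsAsFactors = FALSE)
  syn <- syn[syn$source == "table", ]
  rules <- gen$scheme$merge_rules
  label_of <- function(code, ds_id) {
    if (code == "unidentified") return("unidentified")
    hit <- syn$synonym[match(code, syn$code)]
    if (is.na(hit)) return(cats$display[match(code, cats$code)])
    # never use a synonym that is a merge-rule source for this dataset:
    # the rule would reinterpret the whole column on re-reading
    applies <- vapply(strsplit(rules$datasets, ","), function(d) {
      any(trimws(d) %in% c(toupper(ds_id), "ALL"))
    }, logical(1))
    if (normalize_taxon_name(hit) %in%
          normalize_taxon_name(rules$source_label[applies])) {
      return(cats$display[match(code, cats$code)])
    }
    hit
  }
  for (ds in gen$datasets) {
    labs <- vapply(colnames(ds$abundance), label_of, character(1),
                   ds_id = ds$id)
    tab <- cbind(ds$meta,
                 stats::setNames(as.data.frame(ds$abundance), labs))
    f <- file.path(dir, paste0(tolower(ds$id), ".tsv"))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "")
    schema <- list(dataset = ds$id,
                   database = if (is.na(ds$database)) NULL else ds$database,
                   type = ds$type,
                   columns = as.list(stats::setNames(names(ds$meta),
                                                     names(ds$meta))),
                   taxa = "auto")
    yaml::write_yaml(schema,
                     file.path(dir, paste0(tolower(ds$id), ".schema.yml")))
  }
  for (nm in names(gen$truth)) {
    utils::write.table(gen$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
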