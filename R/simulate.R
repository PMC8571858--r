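#' Study-system species names
#'
#' The twelve species of the study system, used as default labels by the
#' synthetic generator so that site codes follow the conventional letter
#' scheme.
#' @return Character vector of twelve binomials.
#' @export
phalaris_species <- function() {
  c("Phalaris angusta", "Phalaris aquatica", "Phalaris arundinacea",
    "Phalaris brachystachys", "Phalaris californica",
    "Phalaris canariensis", "Phalaris caroliniana",
    "Phalaris coerulescens", "Phalaris lemmonii", "Phalaris minor",
    "Phalaris paradoxa", "Phalaris truncata")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic ITS collection generator. The
#' defaults emulate the study system: twelve species, five accessions per
#' species, a 220/160/220 nt ITS1/5.8S/ITS2 template (600 nt total, inside
#' the 588-602 nt span of the genus), low within-species polymorphism, and
#' herbarium metadata in which DNA concentration is age-independent while
#' amplification success decays with specimen age.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_species Number of species.
#' @param members_per_species Accessions per species (scalar or per-species
#'   vector).
#' @param its1_len,r58s_len,its2_len Region lengths in nt.
#' @param planted_sites List of diagnostic sites to plant; each element is
#'   `list(species = <character vector>, region = "its1"|"its2", offset =
#'   <int within region>, state = "A"|"C"|"G"|"T"|"DEL")`. Multi-species
#'   entries plant clade-shared sites.
#' @param inter_species_divergence Per-site probability that a column
#'   carries a background substitution shared by a random subset of 2 to
#'   (units - 2) species units, so background divergence never fabricates a
#'   single-species diagnostic site.
#' @param within_species_polymorphism Per-member, per-site substitution
#'   probability (planted columns are exempt).
#' @param mislabel_count Number of accessions whose species label is
#'   switched to a uniformly random other species (truth records them).
#' @param missing_data_rate Per-member, per-site probability of an `N`.
#' @param indistinguishable_pairs List of species pairs evolved identically
#'   (they share every background substitution), emulating sibling species
#'   that ITS cannot separate.
#' @param species_names Labels to use (defaults to [phalaris_species()],
#'   recycled/extended as needed).
#' @param metadata List of metadata-generator settings: `n_specimens`,
#'   `year_range`, `amplification_logistic` (`intercept`, `slope` per year
#'   since the range start), `conc_lognormal` (`meanlog`, `sdlog`),
#'   `od_mean`, `od_sd`, `outlier_rate`, `full_seq_given_amplified`,
#'   `undated` (inject one undated record), `reference_year`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_species = 12L,
                       members_per_species = 5L,
                       its1_len = 220L, r58s_len = 160L, its2_len = 220L,
                       planted_sites = list(),
                       inter_species_divergence = 0.03,
                       within_species_polymorphism = 0.002,
                       mislabel_count = 0L,
                       missing_data_rate = 0,
                       indistinguishable_pairs = list(),
                       species_names = NULL,
                       metadata = list()) {
  if (missing(seed)) stop("an explicit `seed` is required")
  stopifnot(n_species >= 2L, its1_len >= 1L, r58s_len >= 1L, its2_len >= 1L,
            inter_species_divergence >= 0, inter_species_divergence <= 1,
            within_species_polymorphism >= 0,
            within_species_polymorphism <= 1,
            missing_data_rate >= 0, missing_data_rate <= 1)
  if (is.null(species_names)) {
    base <- phalaris_species()
    species_names <- if (n_species <= length(base)) base[seq_len(n_species)]
      else c(base, sprintf("Species %02d", seq_len(n_species -
                                                   length(base)) +
                             length(base)))
  }
  stopifnot(length(species_names) == n_species)
  members <- if (length(members_per_species) == 1L)
    setNames(rep(as.integer(members_per_species), n_species),
             species_names)
  else setNames(as.integer(members_per_species), species_names)
  md <- utils::modifyList(list(
    n_specimens = 52L, year_range = c(1882L, 2001L),
    amplification_logistic = c(intercept = -1.4, slope = 0.05),
    conc_lognormal = c(meanlog = log(15), sdlog = 0.8),
    od_mean = 1.95, od_sd = 0.2, outlier_rate = 0.02,
    full_seq_given_amplified = 0.756, undated = TRUE,
    reference_year = 2019L), metadata)
  structure(list(seed = as.integer(seed), n_species = n_species,
                 members_per_species = members,
                 its1_len = as.integer(its1_len),
                 r58s_len = as.integer(r58s_len),
                 its2_len = as.integer(its2_len),
                 planted_sites = planted_sites,
                 inter_species_divergence = inter_species_divergence,
                 within_species_polymorphism = within_species_polymorphism,
                 mislabel_count = as.integer(mislabel_count),
                 missing_data_rate = missing_data_rate,
                 indistinguishable_pairs = indistinguishable_pairs,
                 species_names = species_names,
                 metadata = md), class = "sim_config")
}

.region_column <- function(config, region, offset) {
  base <- switch(region, its1 = 0L, r58s = config$its1_len,
                 its2 = config$its1_len + config$r58s_len,
                 stop("unknown region: ", region))
  len <- config[[paste0(region, "_len")]]
  if (offset < 1L || offset > len)
    stop("planted offset ", offset, " outside region ", region)
  base + as.integer(offset)
}

# Masked (ITS1+ITS2) position of an alignment column under the generator's
# fixed annotation.
.masked_position <- function(config, column) {
  ifelse(column <= config$its1_len, column, column - config$r58s_len)
}

#' Simulate a labeled ITS alignment with known truth
#'
#' Builds a random root ITS sequence, evolves one template per species by
#' subset-shared background substitutions, plants the configured diagnostic
#' sites (substitutions or deletions) with a guarantee that the planted
#' state is fixed in the target species and absent elsewhere, samples
#' members with within-species polymorphism off the planted columns, then
#' applies mislabeling and missing data. Gap columns arise only from planted
#' DEL sites. The emitted alignment's mask already excludes the 5.8S
#' columns; the truth object carries the generator's annotation for the
#' annotation-transfer workflow.
#'
#' @param config A [sim_config()].
#' @return A list with elements `alignment` (a [labeled_alignment()]) and
#'   `truth`: `true_sites` (data frame in [find_diagnostic_sites()] site
#'   layout), `true_labels` (named by accession), `mislabeled` (accessions),
#'   `reference` (ungapped root sequence), `reference_annotation`
#'   (an [its_annotation()]), and `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed)

  L <- config$its1_len + config$r58s_len + config$its2_len
  sp <- config$species_names
  root <- sample(.BASES, L, replace = TRUE)

  # species units: indistinguishable pairs evolve as one unit
  unit_of <- setNames(seq_along(sp), sp)
  for (pair in config$indistinguishable_pairs) {
    stopifnot(length(pair) == 2L, all(pair %in% sp))
    unit_of[pair[2L]] <- unit_of[pair[1L]]
  }
  units <- unique(unit_of)

  planted_col <- vapply(config$planted_sites, function(ps)
    .region_column(config, ps$region, ps$offset), 0L)
  if (anyDuplicated(planted_col))
    stop("planted site collision: two entries target the same column")

  templates <- matrix(rep(root, each = length(sp)), nrow = length(sp),
                      dimnames = list(sp, NULL))

  # background divergence: subset-shared substitutions only (subset sizes
  # 2..units-2), so no column becomes diagnostic for a single unit
  valid_k <- if (length(units) >= 4L) 2:(length(units) - 2L) else integer()
  if (length(valid_k) > 0L && config$inter_species_divergence > 0) {
    div_cols <- setdiff(which(runif(L) < config$inter_species_divergence),
                        planted_col)
    for (cc in div_cols) {
      derived <- sample(setdiff(.BASES, root[cc]), 1L)
      k <- if (length(valid_k) == 1L) valid_k else sample(valid_k, 1L)
      chosen <- if (length(units) == k) units else sample(units, k)
      rows <- which(unit_of %in% chosen)
      templates[rows, cc] <- derived
    }
  }

  # plant diagnostic sites
  for (ps in config$planted_sites) {
    stopifnot(all(ps$species %in% sp))
    cc <- .region_column(config, ps$region, ps$offset)
    st <- toupper(ps$state)
    ch <- if (st == "DEL") "-" else st
    targ <- sp %in% ps$species
    templates[targ, cc] <- ch
    if (st != "DEL") {
      clash <- !targ & templates[, cc] == ch
      if (any(clash)) {
        alt <- sample(setdiff(.BASES, st), 1L)
        templates[clash, cc] <- alt
      }
    }
  }

  # sample members
  n_members <- config$members_per_species
  total <- sum(n_members)
  accession <- sprintf("SYN%04d", seq_len(total))
  true_species <- rep(sp, times = n_members[sp])
  seqm <- templates[true_species, , drop = FALSE]
  rownames(seqm) <- accession

  if (config$within_species_polymorphism > 0) {
    hits <- which(matrix(runif(total * L), total, L) <
                    config$within_species_polymorphism, arr.ind = TRUE)
    hits <- hits[!(hits[, 2L] %in% planted_col), , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      i <- hits[r, 1L]; j <- hits[r, 2L]
      if (seqm[i, j] != "-")
        seqm[i, j] <- sample(setdiff(.BASES, seqm[i, j]), 1L)
    }
  }

  labels <- true_species
  mislabeled <- character(0)
  if (config$mislabel_count > 0L) {
    pick <- sample(total, config$mislabel_count)
    for (i in pick)
      labels[i] <- sample(setdiff(sp, true_species[i]), 1L)
    mislabeled <- accession[pick]
  }

  if (config$missing_data_rate > 0) {
    nn <- which(matrix(runif(total * L), total, L) <
                  config$missing_data_rate & seqm != "-")
    seqm[nn] <- "N"
  }

  mask <- rep(TRUE, L)
  mask[(config$its1_len + 1L):(config$its1_len + config$r58s_len)] <- FALSE
  aln <- labeled_alignment(apply(seqm, 1L, paste, collapse = ""),
                           accession, labels, mask = mask)

  # truth table in the detector's site layout
  prefixes <- .species_prefixes(sp)
  entries <- config$planted_sites
  if (length(entries) > 0L) {
    cols <- vapply(entries, function(ps)
      .region_column(config, ps$region, ps$offset), 0L)
    tg_key <- vapply(entries, function(ps)
      paste(sort(ps$species), collapse = ";"), "")
    ord <- order(match(tg_key, unique(tg_key)), cols)
    entries <- entries[ord]; cols <- cols[ord]; tg_key <- tg_key[ord]
    target_state <- vapply(entries, function(ps) toupper(ps$state), "")
    other_states <- vapply(seq_along(entries), function(k) {
      cc <- cols[k]
      outside <- !(sp %in% entries[[k]]$species)
      paste(sort(unique(ifelse(templates[outside, cc] == "-", "DEL",
                               templates[outside, cc]))), collapse = "|")
    }, "")
    code <- unlist(lapply(split(seq_along(entries), tg_key)[unique(tg_key)],
                          function(idx) {
      pref <- paste(prefixes[entries[[idx[1L]]]$species], collapse = "-")
      paste0(pref, seq_along(idx))
    }), use.names = FALSE)
    true_sites <- data.frame(
      code = code,
      species = vapply(entries, function(ps)
        paste(ps$species, collapse = ";"), ""),
      column = cols,
      position = .masked_position(config, cols),
      target_state = target_state, other_states = other_states,
      stringsAsFactors = FALSE)
  } else {
    true_sites <- data.frame(code = character(), species = character(),
                             column = integer(), position = integer(),
                             target_state = character(),
                             other_states = character(),
                             stringsAsFactors = FALSE)
  }

  annotation <- its_annotation(
    c(1L, config$its1_len),
    c(config$its1_len + 1L, config$its1_len + config$r58s_len),
    c(config$its1_len + config$r58s_len + 1L, L))

  list(alignment = aln,
       truth = list(true_sites = true_sites,
                    true_labels = setNames(true_species, accession),
                    mislabeled = mislabeled,
                    reference = paste(root, collapse = ""),
                    reference_annotation = annotation,
                    config = config))
}

#' Simulate a specimen metadata table
#'
#' Generates herbarium-style QC metadata under the structural assumptions of
#' the analysis: DNA concentration lognormal and independent of collection
#' year (so the true age-regression slope is zero), amplification success a
#' logistic function of collection year (older specimens fail more), purity
#' ratios normal with occasional injected outliers, and optionally one
#' undated record.
#'
#' @param config A [sim_config()]; the `metadata` element holds the knobs.
#' @return A `specimen_records` data frame in the layout produced by
#'   [load_specimen_table()].
#' @export
simulate_specimen_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  md <- config$metadata
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed + 1L)  # decoupled from the alignment stream

  n <- md$n_specimens
  year <- sample(md$year_range[1L]:md$year_range[2L], n, replace = TRUE)
  conc <- rlnorm(n, md$conc_lognormal[["meanlog"]],
                 md$conc_lognormal[["sdlog"]])
  p_amp <- plogis(md$amplification_logistic[["intercept"]] +
                    md$amplification_logistic[["slope"]] *
                    (year - md$year_range[1L]))
  amplified <- runif(n) < p_amp
  full <- amplified & runif(n) < md$full_seq_given_amplified
  od280 <- rnorm(n, md$od_mean, md$od_sd)
  od230 <- rnorm(n, md$od_mean, md$od_sd)
  out_idx <- which(runif(n) < md$outlier_rate)
  od230[out_idx] <- runif(length(out_idx), -5, 8)
  date <- sprintf("%04d", year)
  yr <- year
  if (isTRUE(md$undated)) {
    u <- sample(n, 1L)
    date[u] <- NA_character_
    yr[u] <- NA_integer_
  }
  rec <- data.frame(
    specimen_id = sprintf("SIM-%04d", seq_len(n)),
    species = sample(config$species_names, n, replace = TRUE),
    collection_date = date,
    collection_year = yr,
    dna_conc = conc,
    od_260_280 = od280,
    od_260_230 = od230,
    amplified = amplified,
    full_sequence = full,
    genbank_accession = ifelse(full, sprintf("SYN%06d.1", seq_len(n)),
                               NA_character_),
    source_class = "herbarium",
    stringsAsFactors = FALSE)
  class(rec) <- c("specimen_records", "data.frame")
  rec
}

#' Write / read a self-describing synthetic fixture bundle
#'
#' Writes the aligned FASTA, truth JSON (including the embedded
#' configuration and seed, so the bundle can be regenerated byte-identically
#' from itself), specimen metadata CSV, and the annotation JSON consumed by
#' the masking and pipeline stages.
#'
#' @param sim Output of [simulate_alignment()].
#' @param metadata Output of [simulate_specimen_metadata()] (or `NULL`).
#' @param dir Output directory.
#' @param overwrite Overwrite an existing directory? Default `FALSE`.
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(sim, metadata, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("directory exists and overwrite = FALSE: ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             truth = file.path(dir, "truth.json"),
             metadata = file.path(dir, "metadata.csv"),
             annotation = file.path(dir, "annotation.json"))
  write_labeled_fasta(sim$alignment, paths[["alignment"]])
  truth <- sim$truth
  jsonlite::write_json(list(
    true_sites = truth$true_sites,
    true_labels = as.list(truth$true_labels),
    mislabeled = truth$mislabeled,
    reference = truth$reference,
    reference_annotation = unclass(truth$reference_annotation),
    config = .config_to_list(truth$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(metadata)) {
    out <- data.frame(
      specimen_id = metadata$specimen_id, species = metadata$species,
      collection_date = ifelse(is.na(metadata$collection_date), "ND",
                               metadata$collection_date),
      dna_conc_ng_ul = metadata$dna_conc,
      od_260_280 = metadata$od_260_280,
      od_260_230 = metadata$od_260_230,
      amplified = ifelse(metadata$amplified, "+", "-"),
      full_sequence = ifelse(metadata$full_sequence, "+", "-"),
      genbank_accession = ifelse(is.na(metadata$genbank_accession), "",
                                 metadata$genbank_accession),
      source_class = metadata$source_class, stringsAsFactors = FALSE)
    utils::write.csv(out, paths[["metadata"]], row.names = FALSE,
                     quote = FALSE)
  } else paths <- paths[names(paths) != "metadata"]
  write_annotation_json(list(columns = truth$reference_annotation),
                        paths[["annotation"]])
  invisible(paths)
}

.config_to_list <- function(config) {
  out <- unclass(config)
  out$members_per_species <- as.list(out$members_per_species)
  out$metadata <- lapply(out$metadata, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  out
}

.config_from_list <- function(lst) {
  members <- unlist(lst$members_per_species)
  md <- lapply(lst$metadata, unlist)
  planted <- lapply(lst$planted_sites, function(ps)
    list(species = as.character(unlist(ps$species)), region = ps$region,
         offset = as.integer(ps$offset), state = ps$state))
  pairs <- lapply(lst$indistinguishable_pairs, function(p)
    as.character(unlist(p)))
  lst$planted_sites <- planted
  lst$indistinguishable_pairs <- pairs
  lst$species_names <- as.character(unlist(lst$species_names))
  sim_config(seed = lst$seed, n_species = lst$n_species,
             members_per_species = members,
             its1_len = lst$its1_len, r58s_len = lst$r58s_len,
             its2_len = lst$its2_len,
             planted_sites = lst$planted_sites,
             inter_species_divergence = lst$inter_species_divergence,
             within_species_polymorphism =
               lst$within_species_polymorphism,
             mislabel_count = lst$mislabel_count,
             missing_data_rate = lst$missing_data_rate,
             indistinguishable_pairs = lst$indistinguishable_pairs,
             species_names = lst$species_names,
             metadata = md)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(dir) {
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = FALSE)
  config <- .config_from_list(truth_raw$config)
  aln <- read_labeled_fasta(file.path(dir, "alignment.fasta"))
  ann <- read_annotation_json(file.path(dir, "annotation.json"))
  aln <- mask_58s(aln, ann)
  meta_path <- file.path(dir, "metadata.csv")
  metadata <- if (file.exists(meta_path))
    load_specimen_table(meta_path) else NULL
  ts <- truth_raw$true_sites
  true_sites <- if (length(ts) == 0L)
    data.frame(code = character(), species = character(),
               column = integer(), position = integer(),
               target_state = character(), other_states = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, lapply(ts, function(r)
    data.frame(code = r$code, species = r$species,
               column = as.integer(r$column),
               position = as.integer(r$position),
               target_state = r$target_state,
               other_states = r$other_states, stringsAsFactors = FALSE)))
  list(alignment = aln,
       truth = list(
         true_sites = true_sites,
         true_labels = unlist(truth_raw$true_labels),
         mislabeled = as.character(unlist(truth_raw$mislabeled)),
         reference = truth_raw$reference,
         reference_annotation = its_annotation(
           unlist(truth_raw$reference_annotation$its1),
           unlist(truth_raw$reference_annotation$r58s),
           unlist(truth_raw$reference_annotation$its2)),
         config = config),
       metadata = metadata, config = config)
}

#' A ready-made configuration mirroring the study's barcode structure
#'
#' Twelve species with per-species planted diagnostic-site counts matching
#' the published barcode table's structure: five sites for *P. truncata*,
#' nine clade-shared sites for the indistinguishable
#' *P. brachystachys*/*P. canariensis* pair, five for *P. aquatica*, three
#' for *P. coerulescens* (one a DEL site), three for *P. minor*, one for
#' *P. paradoxa*, two for *P. californica*, three for *P. caroliniana*, six
#' for *P. arundinacea*, and none for *P. lemmonii* or *P. angusta*.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
study_barcode_config <- function(seed, ...) {
  counts <- list(
    "Phalaris truncata" = 5L,
    "Phalaris aquatica" = 5L,
    "Phalaris coerulescens" = 3L,
    "Phalaris minor" = 3L,
    "Phalaris paradoxa" = 1L,
    "Phalaris californica" = 2L,
    "Phalaris caroliniana" = 3L,
    "Phalaris arundinacea" = 6L)
  planted <- list()
  offset <- 5L
  for (spn in names(counts)) for (k in seq_len(counts[[spn]])) {
    region <- if (offset %% 2L == 0L) "its2" else "its1"
    state <- if (spn == "Phalaris coerulescens" && k == 1L) "DEL" else
      c("A", "C", "G", "T")[1L + (offset %% 4L)]
    planted[[length(planted) + 1L]] <-
      list(species = spn, region = region, offset = offset, state = state)
    offset <- offset + 7L
  }
  pair <- c("Phalaris brachystachys", "Phalaris canariensis")
  for (k in seq_len(9L)) {
    planted[[length(planted) + 1L]] <-
      list(species = pair, region = if (k <= 5L) "its1" else "its2",
           offset = 150L + 6L * k, state = c("C", "G", "T", "A")[1L + k %% 4L])
  }
  # within-species polymorphism defaults to zero here: the sibling pair is
  # indistinguishable only while the two species' state sets stay identical
  args <- list(seed = seed, n_species = 12L, planted_sites = planted,
               within_species_polymorphism = 0,
               indistinguishable_pairs = list(pair))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
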