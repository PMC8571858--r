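# State encoding: each residue maps to a bitmask over the five determinate
# states A, C, G, T, DEL. Under the default "indeterminate" policy IUPAC
# ambiguity codes and N carry no bits (the member is excluded from both the
# fixation and the exclusion test at that column); under "expand" an
# ambiguity code contributes every base it denotes, so e.g. an R makes its
# species polymorphic {A, G} at the column.
.STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, DEL = 16L)

.state_lookup <- function(ambiguity = c("indeterminate", "expand")) {
  ambiguity <- match.arg(ambiguity)
  lut <- setNames(integer(length(.ALPHABET)), .ALPHABET)
  lut[c("A", "C", "G", "T")] <- .STATE_BITS[c("A", "C", "G", "T")]
  lut["U"] <- .STATE_BITS[["T"]]
  lut["-"] <- .STATE_BITS[["DEL"]]
  if (ambiguity == "expand") {
    expansions <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                       W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                       B = c("C", "G", "T"), D = c("A", "G", "T"),
                       H = c("A", "C", "T"), V = c("A", "C", "G"))
    for (nm in names(expansions))
      lut[nm] <- sum(.STATE_BITS[expansions[[nm]]])
  }
  lut
}

.bits_to_states <- function(bits) {
  names(.STATE_BITS)[bitwAnd(bits, .STATE_BITS) > 0L]
}

# Per-species state-union and effective-coverage matrices (species x columns).
.species_profiles <- function(alignment, ambiguity = "indeterminate") {
  lut <- .state_lookup(ambiguity)
  B <- matrix(lut[alignment$seq], nrow = nrow(alignment$seq))
  sp <- unique(alignment$species)
  L <- ncol(B)
  U <- matrix(0L, length(sp), L, dimnames = list(sp, NULL))
  Neff <- matrix(0L, length(sp), L, dimnames = list(sp, NULL))
  for (s in sp) {
    rows <- which(alignment$species == s)
    u <- integer(L)
    for (r in rows) u <- bitwOr(u, B[r, ])
    U[s, ] <- u
    Neff[s, ] <- colSums(matrix(B[rows, , drop = FALSE] != 0L,
                                nrow = length(rows)))
  }
  list(union = U, n_eff = Neff, species = sp, bits = B)
}

#' Per-column state profiles of a labeled alignment
#'
#' Tallies, for every mask-true column, the determinate states (A, C, G, T,
#' DEL) carried by each species' members. Gap characters count as the DEL
#' state; N is always indeterminate; IUPAC ambiguity codes are indeterminate
#' under the default policy or contribute each denoted base under
#' `ambiguity = "expand"`.
#'
#' @param alignment A [labeled_alignment()].
#' @param ambiguity `"indeterminate"` (default) or `"expand"`.
#' @return A list with one element per masked column: `column` (alignment
#'   column), `position` (1-based rank among masked columns), `counts` (a
#'   species x state integer matrix), `n_effective` (named integer vector of
#'   determinate members per species).
#' @export
profile_columns <- function(alignment,
                            ambiguity = c("indeterminate", "expand")) {
  ambiguity <- match.arg(ambiguity)
  lut <- .state_lookup(ambiguity)
  sp <- unique(alignment$species)
  cols <- which(alignment$mask)
  lapply(seq_along(cols), function(k) {
    cc <- cols[k]
    counts <- matrix(0L, length(sp), length(.STATE_BITS),
                     dimnames = list(sp, names(.STATE_BITS)))
    n_eff <- setNames(integer(length(sp)), sp)
    for (s in sp) {
      chars <- alignment$seq[alignment$species == s, cc]
      bits <- lut[chars]
      n_eff[s] <- sum(bits != 0L)
      for (st in names(.STATE_BITS))
        counts[s, st] <- sum(bitwAnd(bits, .STATE_BITS[[st]]) > 0L)
    }
    list(column = cc, position = k, counts = counts, n_effective = n_eff)
  })
}

# Species letter codes following the conventional scheme for the twelve
# Phalaris species of the study system; other species fall back to the
# capitalised leading letters of the specific epithet, lengthened until
# unique among the requested targets.
.KNOWN_PREFIX <- c(
  "Phalaris truncata"      = "T",
  "Phalaris brachystachys" = "B",
  "Phalaris canariensis"   = "C",
  "Phalaris aquatica"      = "A",
  "Phalaris coerulescens"  = "C",
  "Phalaris minor"         = "M",
  "Phalaris paradoxa"      = "P",
  "Phalaris californica"   = "CA",
  "Phalaris caroliniana"   = "CR",
  "Phalaris arundinacea"   = "AR",
  "Phalaris lemmonii"      = "L",
  "Phalaris angusta"       = "AN")

.species_prefixes <- function(species) {
  epithet <- vapply(strsplit(species, " ", fixed = TRUE),
                    function(p) p[length(p)], "")
  pre <- ifelse(species %in% names(.KNOWN_PREFIX),
                .KNOWN_PREFIX[species], toupper(substr(epithet, 1L, 1L)))
  names(pre) <- species
  attr(pre, "epithet") <- setNames(epithet, species)
  pre
}

# Make target code prefixes unique among the targets that actually carry
# sites, by appending further epithet letters (the published letter scheme
# is ambiguous in itself; collisions only matter between coded targets).
.resolve_prefixes <- function(prefixes, epithets) {
  out <- character(length(prefixes))
  used <- character(0)
  for (k in seq_along(prefixes)) {
    cand <- prefixes[k]
    pos <- 2L
    while (cand %in% used) {
      extra <- tolower(substr(epithets[k], pos, pos))
      cand <- if (nzchar(extra)) paste0(cand, extra) else
        paste0(prefixes[k], length(used) + 1L)
      pos <- pos + 1L
    }
    out[k] <- cand
    used <- c(used, cand)
  }
  out
}

#' Detect species- and group-diagnostic sites on a masked alignment
#'
#' Scans every mask-true column for diagnostic sites: a column is diagnostic
#' for a target species set S when (i) all determinate members of S share a
#' single state, (ii) that state is absent from every determinate member
#' outside S, and (iii) every species in the alignment has at least
#' `min_coverage` determinate members at the column. Gap characters are the
#' scoreable DEL state, so diagnostic deletions are found alongside SNPs.
#'
#' By default each species is tested as a singleton target, and any pair of
#' species whose member sequences are state-identical at every masked column
#' (an indistinguishable pair, provided the alignment is polymorphic at all)
#' is additionally tested as a joint group target, which surfaces
#' clade-shared sites of the kind that separate two sibling species from the
#' rest of the genus without separating them from each other.
#'
#' @param alignment A [labeled_alignment()] with at least two species.
#' @param targets Optional list of character vectors (species sets). When
#'   `NULL`, singletons for every species plus auto-detected
#'   indistinguishable pairs are used.
#' @param min_coverage Minimum determinate members per species for a column
#'   to be eligible.
#' @param ambiguity Ambiguity-code policy, see [profile_columns()].
#' @return An object of class `barcode_table`: a list with `sites` (data
#'   frame: `code`, `species` (";"-joined for groups), `column` (alignment
#'   column), `position` (1-based over masked columns), `target_state`,
#'   `other_states` ("|"-joined)), `species_without` (species with no
#'   singleton site), `indistinguishable_groups` (list of character
#'   vectors), and `n_columns_scanned`.
#' @export
find_diagnostic_sites <- function(alignment, targets = NULL,
                                  min_coverage = 1L,
                                  ambiguity = c("indeterminate", "expand")) {
  ambiguity <- match.arg(ambiguity)
  prof <- .species_profiles(alignment, ambiguity)
  sp <- prof$species
  if (length(sp) < 2L)
    stop("diagnostic-site detection needs >= 2 species")
  cols <- which(alignment$mask)
  U <- prof$union[, cols, drop = FALSE]
  Neff <- prof$n_eff[, cols, drop = FALSE]
  eligible <- colSums(Neff >= min_coverage) == length(sp)

  # indistinguishable pairs: identical per-species state sets everywhere,
  # in an alignment that is polymorphic somewhere
  polymorphic_any <- any(apply(U, 2L, function(u) {
    u <- u[u > 0L]; length(u) > 0L && length(unique(u)) > 1L
  }))
  groups <- list()
  if (polymorphic_any && length(sp) > 2L) {
    for (i in seq_len(length(sp) - 1L)) for (j in seq(i + 1L, length(sp))) {
      if (all(U[i, ] == U[j, ])) groups[[length(groups) + 1L]] <-
          c(sp[i], sp[j])
    }
  }

  auto <- is.null(targets)
  if (auto) targets <- c(as.list(sp), groups)
  for (tg in targets) {
    absent <- setdiff(tg, sp)
    if (length(absent) > 0L)
      stop("target species absent from the alignment: ",
           paste(absent, collapse = ", "))
  }

  single_bit <- function(u) u %in% .STATE_BITS
  rows_list <- lapply(targets, function(tg) match(tg, sp))
  site_rows <- list()
  for (t in seq_along(targets)) {
    rows <- rows_list[[t]]
    uS <- if (length(rows) == 1L) U[rows, ] else {
      u <- U[rows[1L], ]
      for (r in rows[-1L]) u <- bitwOr(u, U[r, ])
      u
    }
    out_rows <- setdiff(seq_along(sp), rows)
    uO <- if (length(out_rows) == 1L) U[out_rows, ] else {
      u <- U[out_rows[1L], ]
      for (r in out_rows[-1L]) u <- bitwOr(u, U[r, ])
      u
    }
    hit <- which(eligible & single_bit(uS) & bitwAnd(uS, uO) == 0L & uO > 0L)
    if (length(hit) > 0L)
      site_rows[[t]] <- data.frame(
        target_index = t,
        species = paste(targets[[t]], collapse = ";"),
        column = cols[hit],
        position = hit,  # rank among masked columns
        target_state = vapply(uS[hit], function(u) .bits_to_states(u), ""),
        other_states = vapply(uO[hit], function(u)
          paste(sort(.bits_to_states(u)), collapse = "|"), ""),
        stringsAsFactors = FALSE)
  }
  sites <- if (length(site_rows) > 0L) do.call(rbind, site_rows) else
    data.frame(target_index = integer(), species = character(),
               column = integer(), position = integer(),
               target_state = character(), other_states = character(),
               stringsAsFactors = FALSE)

  # code assignment: per-target prefix + ordinal in ascending column order
  pre <- .species_prefixes(sp)
  epi <- attr(pre, "epithet")
  target_prefix <- vapply(targets, function(tg)
    paste(pre[tg], collapse = "-"), "")
  target_epithet <- vapply(targets, function(tg)
    paste(epi[tg], collapse = "-"), "")
  coded <- sort(unique(sites$target_index))
  target_prefix[coded] <- .resolve_prefixes(target_prefix[coded],
                                            target_epithet[coded])
  sites <- sites[order(sites$target_index, sites$column), , drop = FALSE]
  sites$code <- if (nrow(sites) == 0L) character() else
    unlist(lapply(split(seq_len(nrow(sites)), sites$target_index),
                  function(idx)
      paste0(target_prefix[sites$target_index[idx[1L]]], seq_along(idx))),
      use.names = FALSE)
  sites$target_index <- NULL
  sites <- sites[, c("code", "species", "column", "position",
                     "target_state", "other_states")]
  rownames(sites) <- NULL

  singleton_targets <- vapply(targets, length, 1L) == 1L
  with_sites <- unique(sites$species[!grepl(";", sites$species,
                                            fixed = TRUE)])
  tested_single <- unlist(targets[singleton_targets])
  grouped <- unique(unlist(groups))
  species_without <- setdiff(setdiff(tested_single, with_sites), grouped)

  structure(list(sites = sites, species_without = species_without,
                 indistinguishable_groups = groups,
                 n_columns_scanned = length(cols)),
            class = "barcode_table")
}

#' @export
print.barcode_table <- function(x, ...) {
  cat(sprintf("barcode_table: %d diagnostic sites over %d scanned columns\n",
              nrow(x$sites), x$n_columns_scanned))
  if (nrow(x$sites) > 0L) print(x$sites, row.names = FALSE)
  if (length(x$species_without) > 0L)
    cat("no diagnostic site:", paste(x$species_without, collapse = ", "),
        "\n")
  for (g in x$indistinguishable_groups)
    cat("indistinguishable:", paste(g, collapse = " / "), "\n")
  invisible(x)
}

#' Classify a query sequence against a barcode table
#'
#' Scores the query at every diagnostic site: a site is *tested* when the
#' query carries a determinate state (base or gap) at its column, and
#' *matched* when that state equals the site's target state. The query is
#' assigned to a species when exactly one singleton target matches all of
#' its tested sites and out-scores every other target; a winning group
#' target (or a tie) yields an ambiguous verdict, and a query matching no
#' site is unassigned.
#'
#' @param query A character string aligned to the barcode alignment's
#'   coordinate system, or a list with `residues` (and optionally
#'   `accession`).
#' @param table A `barcode_table` from [find_diagnostic_sites()] or
#'   [read_barcode_table()].
#' @param mask Optional logical column mask of the barcode alignment, needed
#'   only when `table` lacks alignment columns (e.g. after reading a TSV)
#'   so that masked positions can be mapped back to columns.
#' @return A list of class `classification_result`: `accession`,
#'   `best_species` (`NA` unless assigned), `verdict` (`"assigned"`,
#'   `"ambiguous"`, `"unassigned"`), `sites_matched`, `sites_tested` (for
#'   the winning target), `scores` (data frame target/matched/tested), and
#'   `ambiguous_between` (species involved in a tie, if any).
#' @export
classify_query <- function(query, table, mask = NULL) {
  accession <- NA_character_
  if (is.list(query)) {
    accession <- query$accession %||% NA_character_
    query <- query$residues
  }
  chars <- strsplit(toupper(query), "", fixed = TRUE)[[1L]]
  sites <- table$sites
  if (nrow(sites) == 0L)
    return(structure(list(accession = accession,
                          best_species = NA_character_,
                          verdict = "unassigned", sites_matched = 0L,
                          sites_tested = 0L,
                          scores = data.frame(), ambiguous_between =
                            character()),
                     class = "classification_result"))
  col <- sites$column
  if (anyNA(col)) {
    if (is.null(mask))
      stop("barcode table lacks alignment columns; supply `mask`")
    masked_cols <- which(mask)
    col <- masked_cols[sites$position]
  }
  if (max(col) > length(chars))
    stop("query is shorter than the barcode alignment coordinate system")
  lut <- .state_lookup("indeterminate")
  bits <- lut[chars[col]]
  state <- rep(NA_character_, length(bits))
  det <- bits %in% .STATE_BITS
  state[det] <- vapply(bits[det], .bits_to_states, "")
  tested <- det
  matched <- det & state == sites$target_state

  agg <- stats::aggregate(cbind(matched = matched, tested = tested),
                          by = list(target = sites$species), FUN = sum)
  agg <- agg[order(-agg$matched, agg$target), , drop = FALSE]
  perfect <- agg$tested > 0L & agg$matched == agg$tested
  any_match <- any(agg$matched > 0L)
  verdict <- "unassigned"; best <- NA_character_; amb <- character()
  if (any_match) {
    top <- agg$matched[1L]
    winners <- which(agg$matched == top)
    if (length(winners) == 1L && perfect[winners]) {
      members <- strsplit(agg$target[winners], ";", fixed = TRUE)[[1L]]
      if (length(members) == 1L) {
        verdict <- "assigned"; best <- members
      } else {
        verdict <- "ambiguous"; amb <- members
      }
    } else {
      verdict <- "ambiguous"
      amb <- unique(unlist(strsplit(agg$target[winners], ";", fixed = TRUE)))
    }
  }
  structure(list(accession = accession, best_species = best,
                 verdict = verdict,
                 sites_matched = agg$matched[1L],
                 sites_tested = agg$tested[1L],
                 scores = agg, ambiguous_between = amb),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("query %s: %s", x$accession, x$verdict))
  if (x$verdict == "assigned")
    cat(sprintf(" -> %s (%d/%d sites)", x$best_species, x$sites_matched,
                x$sites_tested))
  if (length(x$ambiguous_between) > 0L)
    cat(" between", paste(x$ambiguous_between, collapse = " / "))
  cat("\n")
  invisible(x)
}

#' Write / read a barcode table as TSV
#'
#' The TSV carries `code`, `species` (";"-joined for group targets),
#' `position_1based` (over the masked ITS1+ITS2 columns), `target_state` and
#' `other_states` ("|"-joined). Reading reconstructs alignment columns when
#' the originating column mask is supplied.
#'
#' @param table A `barcode_table`.
#' @param path Output TSV path.
#' @return `path` invisibly; for `read_barcode_table`, a `barcode_table`.
#' @export
write_barcode_table <- function(table, path) {
  out <- data.frame(code = table$sites$code, species = table$sites$species,
                    position_1based = table$sites$position,
                    target_state = table$sites$target_state,
                    other_states = table$sites$other_states,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_table
#' @param mask Optional logical column mask used to restore alignment
#'   columns from masked positions.
#' @export
read_barcode_table <- function(path, mask = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(position_1based = "integer"))
  need <- c("code", "species", "position_1based", "target_state",
            "other_states")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("barcode TSV missing column(s): ", paste(miss, collapse = ", "))
  column <- if (is.null(mask)) rep(NA_integer_, nrow(raw)) else
    which(mask)[raw$position_1based]
  sites <- data.frame(code = raw$code, species = raw$species,
                      column = column, position = raw$position_1based,
                      target_state = raw$target_state,
                      other_states = raw$other_states,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, species_without = character(),
                 indistinguishable_groups = list(),
                 n_columns_scanned = NA_integer_),
            class = "barcode_table")
}
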