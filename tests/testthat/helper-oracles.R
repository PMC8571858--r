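# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation of the quantity it
# checks, kept free of the package's own code paths.

tab1_path <- system.file("extdata", "table1_herbarium_specimens.csv",
                         package = "herbarcode")
tab2_path <- system.file("extdata", "table2_fresh_specimens.csv",
                         package = "herbarcode")

make_aln <- function(seqs, species, accession = NULL, mask = NULL) {
  labeled_alignment(seqs, accession %||% sprintf("q%02d", seq_along(seqs)),
                    species, mask = mask)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive enumeration of all global alignments of two tiny strings,
# returning the maximum score (scoring: match / mismatch / linear gap).
enumerate_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (substr(a, i, i) == substr(b, j, j)) match else
                      mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Naive per-column diagnostic-site scan under the default ambiguity policy
# (IUPAC and N indeterminate, '-' the DEL state), testing conditions:
# fixation in the target set, exclusion outside it, coverage everywhere.
oracle_state <- function(ch) {
  if (ch %in% c("A", "C", "G", "T")) return(ch)
  if (ch == "U") return("T")
  if (ch == "-") return("DEL")
  NA_character_
}

oracle_scan <- function(aln, targets, min_coverage = 1) {
  sp <- unique(aln$species)
  masked <- which(aln$mask)
  out <- list()
  for (tg in targets) {
    for (pos in seq_along(masked)) {
      cc <- masked[pos]
      states <- vapply(aln$seq[, cc], oracle_state, "")
      det <- lapply(split(states, aln$species)[sp],
                    function(v) v[!is.na(v)])
      if (any(vapply(det, length, 1L) < min_coverage)) next
      in_states <- unique(unlist(det[tg], use.names = FALSE))
      out_states <- unique(unlist(det[setdiff(sp, tg)], use.names = FALSE))
      if (length(in_states) == 1L && !(in_states %in% out_states) &&
          length(out_states) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          species = paste(tg, collapse = ";"), column = cc, position = pos,
          target_state = in_states,
          other_states = paste(sort(out_states), collapse = "|"),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(species = character(), column = integer(),
                      position = integer(), target_state = character(),
                      other_states = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$species, df$column), , drop = FALSE]
}

site_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(df$species, df$column, df$target_state, df$other_states,
             sep = "~"))
}

# Unrooted monophyly via phangorn's split decomposition (independent of the
# package's own bipartition code).
oracle_mono <- function(tree, leaves, sp_leaves) {
  sp_leaves <- intersect(sp_leaves, leaves)
  if (length(sp_leaves) <= 1L) return(TRUE)
  sub <- ape::keep.tip(tree, leaves)
  splits <- phangorn::as.splits(ape::unroot(sub))
  labs <- attr(splits, "labels")
  target <- sort(sp_leaves)
  for (s in splits) {
    side <- sort(labs[s])
    if (identical(side, target) ||
        identical(sort(setdiff(labs, side)), target)) return(TRUE)
  }
  FALSE
}

# Exhaustive minimal-leaf-removal sets restoring monophyly of every
# multi-member species; returns the list of all minimum-size removal sets.
oracle_min_removal <- function(tree, species) {
  tips <- tree$tip.label
  by_sp <- split(tips, species[tips])
  testable <- by_sp[lengths(by_sp) >= 2L]
  all_ok <- function(leaves) {
    for (spn in names(testable)) {
      if (!oracle_mono(tree, leaves, intersect(testable[[spn]], leaves)))
        return(FALSE)
    }
    TRUE
  }
  if (all_ok(tips)) return(list(character(0)))
  for (k in 1:(length(tips) - 3L)) {
    sets <- utils::combn(tips, k, simplify = FALSE)
    hits <- Filter(function(s) all_ok(setdiff(tips, s)), sets)
    if (length(hits) > 0L) return(hits)
  }
  list()
}

# Additive distance matrix from a random unrooted tree.
random_additive <- function(seed, n_leaves) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves))
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  D <- stats::cophenetic(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Random alignment with arbitrary residues (including gaps, N and ambiguity
# codes) for policy stress tests.
random_messy_alignment <- function(seed, n_species, members, n_cols,
                                   p_gap = 0.03, p_amb = 0.03) {
  set.seed(seed)
  sp <- sprintf("taxon %02d", seq_len(n_species))
  n <- n_species * members
  pool <- c("A", "C", "G", "T")
  m <- matrix(sample(pool, n * n_cols, TRUE), n, n_cols)
  m[matrix(runif(n * n_cols) < p_gap, n, n_cols)] <- "-"
  amb <- matrix(runif(n * n_cols) < p_amb, n, n_cols)
  m[amb] <- sample(c("R", "Y", "N", "W"), sum(amb), TRUE)
  make_aln(apply(m, 1L, paste, collapse = ""),
           rep(sp, each = members))
}
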