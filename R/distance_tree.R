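#' Pairwise distances on a masked alignment
#'
#' Computes per-pair mismatch proportions (p-distance) or Jukes-Cantor
#' corrected distances, `-(3/4) * log(1 - 4p/3)`, over the mask-true
#' columns. Only the four bases are compared: gaps, N and ambiguity codes
#' are missing data here. Under pairwise deletion each pair uses the columns
#' where both members are determinate; under complete deletion only columns
#' where every member is determinate are used.
#'
#' @param alignment A [labeled_alignment()] with >= 2 sequences.
#' @param model `"jukes_cantor"` (default) or `"p_distance"`.
#' @param gap_handling `"pairwise_deletion"` (default) or
#'   `"complete_deletion"`.
#' @return An object of class `distance_matrix`: `taxa`, `values` (symmetric
#'   matrix, zero diagonal), `model`, `gap_handling`, `species` (named by
#'   taxon).
#' @export
pairwise_distance <- function(alignment,
                              model = c("jukes_cantor", "p_distance"),
                              gap_handling = c("pairwise_deletion",
                                               "complete_deletion")) {
  model <- match.arg(model)
  gap_handling <- match.arg(gap_handling)
  n <- nrow(alignment$seq)
  if (n < 2L) stop("need >= 2 sequences for pairwise distances")
  S <- alignment$seq[, alignment$mask, drop = FALSE]
  det <- matrix(S %in% .BASES, nrow = n)
  if (gap_handling == "complete_deletion") {
    keep <- colSums(det) == n
    S <- S[, keep, drop = FALSE]
    det <- det[, keep, drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(alignment$accession,
                                       alignment$accession))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- det[i, ] & det[j, ]
    m <- sum(ok)
    if (m == 0L)
      stop("no comparable sites for pair ", alignment$accession[i], " / ",
           alignment$accession[j])
    p <- sum(S[i, ok] != S[j, ok]) / m
    d <- if (model == "p_distance") p else {
      if (p >= 0.75)
        stop("Jukes-Cantor distance undefined (p >= 0.75) for pair ",
             alignment$accession[i], " / ", alignment$accession[j])
      -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  structure(list(taxa = alignment$accession, values = D, model = model,
                 gap_handling = gap_handling,
                 species = setNames(alignment$species,
                                    alignment$accession)),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d taxa, model = %s, %s\n",
              length(x$taxa), x$model, x$gap_handling))
  print(round(x$values, 4))
  invisible(x)
}

.as_dist_values <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  taxa <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  list(taxa = taxa, values = D, species = NULL)
}

#' Neighbor-joining tree
#'
#' Classic agglomerative neighbor joining: at each step the pair minimising
#' `Q(i,j) = (n - 2) d(i,j) - R_i - R_j` is merged, with ties broken by the
#' lowest pair of active-cluster indices (original taxon order first, merged
#' clusters appended in creation order), so the result is deterministic.
#' The returned tree is unrooted. Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero in the tree; raw
#' values are kept in `attr(tree, "raw.edge.length")`.
#'
#' @param D A `distance_matrix` from [pairwise_distance()], or a plain
#'   symmetric numeric matrix with taxon rownames.
#' @return An [ape::read.tree()]-style `phylo` object; `tree$species` holds
#'   the species label per tip when `D` carries them.
#' @export
neighbor_joining <- function(D) {
  D <- .as_dist_values(D)
  M <- D$values
  n <- nrow(M)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  fmt <- function(x) sprintf("%.17g", x)
  sub <- D$taxa  # newick fragment per active cluster
  repeat {
    n <- nrow(M)
    if (n == 3L) break
    R <- rowSums(M)
    Q <- (n - 2) * M - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # lowest-index tie-break: smallest i, then smallest j (i < j)
    hit <- which(Q == qmin, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- M[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- M[i, j] - li
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    dk <- (M[i, ] + M[j, ] - M[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    M2 <- rbind(cbind(M[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    M <- M2
    sub <- c(sub[keep], new_sub)
  }
  la <- (M[1, 2] + M[1, 3] - M[2, 3]) / 2
  lb <- (M[1, 2] + M[2, 3] - M[1, 3]) / 2
  lc <- (M[1, 3] + M[2, 3] - M[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1L], fmt(la), sub[2L],
                 fmt(lb), sub[3L], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw.edge.length") <- tree$edge.length
  tree$edge.length <- pmax(tree$edge.length, 0)
  if (!is.null(D$species))
    tree$species <- unname(D$species[tree$tip.label])
  tree
}

# Bipartitions of the internal edges of an unrooted tree, as canonical keys.
# Each internal edge splits the tips in two; the key is the sorted side not
# containing the overall-first tip label, so keys are rotation-invariant.
.tree_splits <- function(tree, with_nodes = FALSE) {
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  desc <- .descendant_tips(tree)
  internal <- which(tree$edge[, 2L] > ntip)
  keys <- character(0); nodes <- integer(0)
  for (e in internal) {
    side <- desc[[tree$edge[e, 2L] - ntip]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, tree$edge[e, 2L])
  }
  if (with_nodes) list(keys = keys, nodes = nodes) else keys
}

# Tip labels descending from each internal node (index 1 = node ntip+1).
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # accumulate children into parents from highest node id downwards
  # (read.tree numbers internal nodes in preorder, so children come first)
  for (node in sort(unique(tree$edge[, 1L]), decreasing = TRUE)) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    sets[[node]] <- unlist(sets[kids])
  }
  sets[(ntip + 1L):(ntip + nnode)]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples mask-true alignment columns with replacement, rebuilds the NJ
#' tree per replicate, and annotates each internal edge of the reference
#' tree (built from the original alignment) with the percentage of
#' replicates containing the same unrooted bipartition. Replicates in which
#' some pair has no comparable site are dropped with a warning and counted.
#'
#' @param alignment A [labeled_alignment()].
#' @param replicates Number of bootstrap replicates (default 100).
#' @param seed Integer RNG seed; required, there is no silent default.
#' @param model,gap_handling Passed to [pairwise_distance()].
#' @return The reference `phylo` tree with integer-percent node labels in
#'   `tree$node.label`, plus attributes `replicates_used` and
#'   `replicates_dropped`.
#' @export
bootstrap_support <- function(alignment, replicates = 100L, seed,
                              model = "jukes_cantor",
                              gap_handling = "pairwise_deletion") {
  if (missing(seed) || is.null(seed)) stop("an explicit `seed` is required")
  stopifnot(replicates >= 1L)
  ref <- neighbor_joining(pairwise_distance(alignment, model, gap_handling))
  sp <- .tree_splits(ref, with_nodes = TRUE)
  tally <- setNames(numeric(length(sp$keys)), sp$keys)
  cols <- which(alignment$mask)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  dropped <- 0L
  used <- 0L
  for (r in seq_len(replicates)) {
    pick <- sample(cols, length(cols), replace = TRUE)
    boot <- subset_columns(alignment, pick)
    boot$mask <- rep(TRUE, length(pick))
    Db <- tryCatch(pairwise_distance(boot, model, gap_handling),
                   error = function(e) NULL)
    if (is.null(Db)) { dropped <- dropped + 1L; next }
    used <- used + 1L
    keys <- .tree_splits(neighbor_joining(Db))
    hit <- intersect(keys, names(tally))
    tally[hit] <- tally[hit] + 1
  }
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped: pair(s) with no ",
            "comparable sites")
  support <- if (used > 0L) 100 * tally / used else tally * NA_real_
  ntip <- length(ref$tip.label)
  lab <- rep("", ref$Nnode)
  lab[sp$nodes - ntip] <- as.character(round(support))
  ref$node.label <- lab
  attr(ref, "replicates_used") <- used
  attr(ref, "replicates_dropped") <- dropped
  ref
}

#' Write a tree to Newick
#'
#' Branch lengths are included and bootstrap supports (when present) are
#' written as internal-node labels, rendered as integers 0-100.
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Flag accessions that violate species monophyly
#'
#' Tests, for every species with two or more leaves, whether an edge of the
#' unrooted tree isolates exactly that species' leaves. For each
#' non-monophyletic species, leaves are removed greedily - at each step the
#' leaf whose removal most reduces the number of foreign leaves inside the
#' species' minimal spanning clade (ties broken by the lowest accession id)
#' - until the remaining members are monophyletic; every removed leaf is
#' flagged as a misassignment candidate. A flagged leaf is attributed to the
#' species holding the majority among its three nearest leaves by patristic
#' distance.
#'
#' @param tree A `phylo` tree whose tips carry species labels, either in
#'   `tree$species` (as produced by [neighbor_joining()]) or via the
#'   `species` argument.
#' @param species Optional character vector of species labels named by tip
#'   label.
#' @return A list of class `misassignment_report`: `flagged` (data frame
#'   `accession`, `labeled_species`, `resolved_clade_species`),
#'   `monophyletic_species`, `non_monophyletic_species`,
#'   `untestable_species` (single-leaf species).
#' @export
flag_misassignments <- function(tree, species = NULL) {
  if (is.null(species)) {
    if (is.null(tree$species)) stop("tree carries no species labels")
    species <- setNames(tree$species, tree$tip.label)
  }
  tips <- tree$tip.label
  species <- species[tips]
  if (length(unique(species)) < 2L) stop("need >= 2 species")

  # both sides of every edge, as tip-label sets
  ntip <- length(tips)
  desc <- .descendant_tips(tree)
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    s <- if (child <= ntip) tips[child] else desc[[child - ntip]]
    sides[[length(sides) + 1L]] <- s
    sides[[length(sides) + 1L]] <- setdiff(tips, s)
  }
  sides <- unique(lapply(sides, sort))

  is_mono <- function(S, L) {
    SL <- sort(intersect(S, L))
    if (length(SL) <= 1L) return(TRUE)
    for (sd in sides) {
      r <- sort(intersect(sd, L))
      if (identical(r, SL)) return(TRUE)
    }
    FALSE
  }
  # minimal side (restricted to live leaves L) containing all of S
  foreign_count <- function(S, L) {
    SL <- intersect(S, L)
    if (length(SL) <= 1L) return(0L)
    best <- length(L)
    for (sd in sides) {
      r <- intersect(sd, L)
      if (all(SL %in% r) && length(r) < best) best <- length(r)
    }
    best - length(SL)
  }
  spanning_leaves <- function(S, L) {
    SL <- intersect(S, L)
    best <- L
    for (sd in sides) {
      r <- intersect(sd, L)
      if (all(SL %in% r) && length(r) < length(best)) best <- r
    }
    best
  }

  by_sp <- split(tips, species)
  untestable <- names(by_sp)[lengths(by_sp) == 1L]
  testable <- names(by_sp)[lengths(by_sp) >= 2L]
  non_mono <- character(0)
  flagged <- character(0)
  for (spn in testable) {
    S <- by_sp[[spn]]
    L <- tips
    if (!is_mono(S, L)) non_mono <- c(non_mono, spn)
    while (!is_mono(S, L)) {
      cand <- sort(spanning_leaves(intersect(S, L), L))
      gain <- vapply(cand, function(leaf)
        foreign_count(setdiff(S, leaf), setdiff(L, leaf)), 0L)
      # ties: prefer removing a foreign leaf (the intruder reading, which
      # matches the exhaustive minimal-removal solution), then the lowest
      # accession id (cand is sorted)
      best <- which(gain == min(gain))
      foreign_first <- best[!(cand[best] %in% S)]
      pick <- cand[if (length(foreign_first) > 0L) foreign_first[1L] else
        best[1L]]
      L <- setdiff(L, pick)
      flagged <- c(flagged, pick)
    }
  }
  flagged <- sort(unique(flagged))

  resolved <- character(length(flagged))
  if (length(flagged) > 0L) {
    pd <- ape::cophenetic.phylo(tree)
    for (k in seq_along(flagged)) {
      leaf <- flagged[k]
      d <- pd[leaf, setdiff(tips, leaf)]
      nn <- names(sort(d))[seq_len(min(3L, length(d)))]
      votes <- sort(table(species[nn]), decreasing = TRUE)
      resolved[k] <- names(votes)[1L]
    }
  }
  non_mono <- sort(unique(c(non_mono, unname(species[flagged]))))
  structure(list(
    flagged = data.frame(accession = flagged,
                         labeled_species = unname(species[flagged]),
                         resolved_clade_species = resolved,
                         stringsAsFactors = FALSE),
    monophyletic_species = setdiff(testable, non_mono),
    non_monophyletic_species = non_mono,
    untestable_species = untestable), class = "misassignment_report")
}

#' @export
print.misassignment_report <- function(x, ...) {
  cat(sprintf("misassignment_report: %d flagged, %d non-monophyletic species\n",
              nrow(x$flagged), length(x$non_monophyletic_species)))
  if (nrow(x$flagged) > 0L) print(x$flagged, row.names = FALSE)
  invisible(x)
}
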