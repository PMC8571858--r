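test_that("p-distances count mismatches over comparable sites and JC corrects them", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 90), strrep("C", 10))
  aln <- make_aln(c(a, a, b), c("x", "x", "y"))
  D <- pairwise_distance(aln, model = "p_distance")
  expect_equal(D$values[1, 2], 0)
  expect_equal(D$values[1, 3], 0.10)
  # closed form evaluated independently: -0.75 * log(1 - 0.4/3)
  jc <- pairwise_distance(aln, model = "jukes_cantor")
  expect_equal(jc$values[1, 3], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(round(jc$values[1, 3], 4), 0.1073)

  # symmetry, zero diagonal, JC >= p entrywise
  cfg <- study_barcode_config(seed = 3, members_per_species = 2L)
  aln2 <- simulate_alignment(cfg)$alignment
  p <- pairwise_distance(aln2, model = "p_distance")$values
  j <- pairwise_distance(aln2, model = "jukes_cantor")$values
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), rep(0, nrow(p)))
  expect_true(all(j >= p - 1e-12))
})

test_that("distance errors name incomparable pairs and JC saturation", {
  aln <- make_aln(c("AAAA", "----"), c("x", "y"), accession = c("u1", "u2"))
  expect_error(pairwise_distance(aln), "u1 / u2")
  sat <- make_aln(c("AAAA", "CCCC"), c("x", "y"))
  expect_error(pairwise_distance(sat, model = "jukes_cantor"), "0.75")
  expect_equal(pairwise_distance(sat, model = "p_distance")$values[1, 2], 1)
})

test_that("distances agree with ape::dist.dna on gap-free alignments", {
  for (seed in 1:4) {
    cfg <- sim_config(seed = seed, n_species = 6L,
                      members_per_species = 2L,
                      inter_species_divergence = 0.05,
                      within_species_polymorphism = 0.01)
    aln <- simulate_alignment(cfg)$alignment
    aln$mask <- rep(TRUE, ncol(aln$seq))  # compare on all columns
    bin <- ape::as.DNAbin(aln$seq)
    for (model in c("p_distance", "jukes_cantor")) {
      mine <- pairwise_distance(aln, model = model)$values
      ref <- as.matrix(ape::dist.dna(bin, model = if (model == "p_distance")
        "raw" else "JC69", pairwise.deletion = TRUE))
      expect_equal(mine, ref[rownames(mine), colnames(mine)],
                   tolerance = 1e-12)
    }
  }
})

test_that("three-taxon NJ solves the closed-form branch lengths exactly", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(length(tr$tip.label), 3L)
  len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                       tr$edge[, 2L])], tr$tip.label)
  expect_equal(len[["a"]], (3 + 4 - 5) / 2, tolerance = 1e-12)
  expect_equal(len[["b"]], (3 + 5 - 4) / 2, tolerance = 1e-12)
  expect_equal(len[["c"]], (4 + 5 - 3) / 2, tolerance = 1e-12)
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers topology and branch lengths exactly from additive matrices", {
  for (seed in 1:25) {
    gen <- random_additive(seed, n_leaves = sample(5:12, 1))
    rec <- neighbor_joining(gen$D)
    expect_equal(ape::dist.topo(ape::unroot(gen$tree), rec), 0,
                 ignore_attr = TRUE)
    patristic <- stats::cophenetic(rec)
    expect_equal(max(abs(patristic[rownames(gen$D), colnames(gen$D)] -
                           gen$D)), 0, tolerance = 1e-9)
  }
})

test_that("NJ topology agrees with ape::nj on noisy matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    gen <- random_additive(seed + 100, n_leaves = 8L)
    D <- gen$D + matrix(runif(64, 0, 0.01), 8, 8)
    D <- (D + t(D)) / 2; diag(D) <- 0
    mine <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(mine, ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("Q-criterion ties merge the lowest-index pair first", {
  # four equidistant taxa: every Q is tied, so (t1, t2) must merge first,
  # giving the t1t2 | t3t4 resolution
  D <- matrix(1, 4, 4); diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:4), paste0("t", 1:4))
  tr <- neighbor_joining(D)
  splits <- herbarcode:::.tree_splits(tr)
  expect_length(splits, 1L)
  side <- strsplit(splits, "\r", fixed = TRUE)[[1L]]
  expect_true(setequal(side, c("t3", "t4")) ||
                setequal(side, c("t1", "t2")))
})

test_that("bootstrap supports saturate on well-separated clades and reproduce by seed", {
  set.seed(20)
  base <- sample(c("A", "C", "G", "T"), 120, TRUE)
  other <- base  # second clade: 60 fixed differences (p = 0.5, JC-safe)
  other[1:60] <- vapply(base[1:60], function(ch)
    setdiff(c("A", "C", "G", "T"), ch)[1L], "")
  jitter_one <- function(v, at) { v[at] <- setdiff(c("A", "C", "G", "T"),
                                                   v[at])[1L]; v }
  seqs <- c(
    vapply(1:4, function(k) paste(jitter_one(base, k), collapse = ""), ""),
    vapply(1:4, function(k) paste(jitter_one(other, k + 8), collapse = ""),
           ""))
  aln <- make_aln(seqs, rep(c("cl a", "cl b"), each = 4L),
                  accession = sprintf("b%02d", 1:8))
  tr <- bootstrap_support(aln, replicates = 30L, seed = 5L)
  splits <- herbarcode:::.tree_splits(tr, with_nodes = TRUE)
  main <- which(vapply(strsplit(splits$keys, "\r", fixed = TRUE),
                       length, 1L) == 4L)
  expect_true(length(main) >= 1L)
  lab <- tr$node.label[splits$nodes[main] - length(tr$tip.label)]
  expect_true(all(lab == "100"))

  # replicates = 1: supports can only be 0 or 100
  t1 <- bootstrap_support(aln, replicates = 1L, seed = 9L)
  vals <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(vals[!is.na(vals)] %in% c(0, 100)))

  # identical seed, identical supports; input order does not matter
  # (order invariance needs a tie-free matrix, so every member is distinct)
  cfg <- sim_config(seed = 8, n_species = 6L, members_per_species = 2L,
                    inter_species_divergence = 0.1,
                    within_species_polymorphism = 0.02)
  aln2 <- simulate_alignment(cfg)$alignment
  b1 <- bootstrap_support(aln2, replicates = 25L, seed = 17L)
  b2 <- bootstrap_support(aln2, replicates = 25L, seed = 17L)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))

  perm <- sample(nrow(aln2$seq))
  aln3 <- labeled_alignment(apply(aln2$seq[perm, ], 1L, paste,
                                  collapse = ""),
                            aln2$accession[perm], aln2$species[perm],
                            mask = aln2$mask)
  b3 <- bootstrap_support(aln3, replicates = 25L, seed = 17L)
  key_support <- function(tr) {
    s <- herbarcode:::.tree_splits(tr, with_nodes = TRUE)
    setNames(tr$node.label[s$nodes - length(tr$tip.label)], s$keys)
  }
  k1 <- key_support(b1); k3 <- key_support(b3)
  shared <- intersect(names(k1), names(k3))
  expect_true(length(shared) >= 1L)
  expect_identical(k1[shared], k3[shared])

  expect_error(bootstrap_support(aln2, replicates = 10L), "seed")
})

test_that("newick output round-trips with integer supports and branch lengths", {
  cfg <- study_barcode_config(seed = 4, members_per_species = 2L)
  aln <- simulate_alignment(cfg)$alignment
  tr <- bootstrap_support(aln, replicates = 10L, seed = 2L)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(herbarcode:::.tree_splits(back),
                  herbarcode:::.tree_splits(tr))
  labs <- back$node.label[nzchar(back$node.label)]
  expect_true(all(grepl("^\\d+$", labs)))
  expect_true(all(as.integer(labs) >= 0 & as.integer(labs) <= 100))

  tiny <- neighbor_joining(matrix(c(0, .3, .25, .3, 0, .35, .25, .35, 0),
                                  3, 3, dimnames = list(c("A", "B", "C"),
                                                        c("A", "B", "C"))))
  write_newick(tiny, nwk)
  expect_match(readLines(nwk), "^\\(.*A:.*B:.*C:.*\\);$")
})

test_that("misassignment flagging matches the exhaustive minimal-removal oracle", {
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed, n_species = 4L,
                      members_per_species = 3L,
                      inter_species_divergence = 0.2,
                      within_species_polymorphism = 0.005,
                      mislabel_count = (seed %% 2L) + 1L)
    sim <- simulate_alignment(cfg)
    tr <- neighbor_joining(pairwise_distance(sim$alignment))
    rep <- flag_misassignments(tr)
    minimal <- oracle_min_removal(tr, setNames(tr$species, tr$tip.label))
    expect_true(length(minimal) >= 1L)
    expect_equal(length(rep$flagged$accession), length(minimal[[1L]]))
    expect_true(any(vapply(minimal, setequal, TRUE,
                           y = rep$flagged$accession)))
  }
})

test_that("a planted intruder is flagged and resolved to its host clade", {
  cfg <- sim_config(seed = 40, n_species = 5L, members_per_species = 3L,
                    inter_species_divergence = 0.15,
                    within_species_polymorphism = 0.002,
                    mislabel_count = 1L)
  sim <- simulate_alignment(cfg)
  tr <- neighbor_joining(pairwise_distance(sim$alignment))
  rep <- flag_misassignments(tr)
  expect_equal(rep$flagged$accession, sim$truth$mislabeled)
  truth <- sim$truth$true_labels[[sim$truth$mislabeled]]
  expect_equal(rep$flagged$resolved_clade_species, truth)
  expect_true(all(rep$flagged$labeled_species %in%
                    rep$non_monophyletic_species))

  clean <- sim_config(seed = 41, n_species = 5L, members_per_species = 3L,
                      inter_species_divergence = 0.15,
                      within_species_polymorphism = 0.002)
  tr2 <- neighbor_joining(pairwise_distance(
    simulate_alignment(clean)$alignment))
  rep2 <- flag_misassignments(tr2)
  expect_equal(nrow(rep2$flagged), 0L)
  expect_length(rep2$non_monophyletic_species, 0L)
})
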