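test_that("column profiles match a hand-built tally on a toy alignment", {
  aln <- make_aln(c("AC-", "ACT", "GCT", "GCT"),
                  c("x", "x", "y", "y"))
  prof <- profile_columns(aln)
  expect_length(prof, 3L)
  expect_equal(prof[[1]]$counts["x", "A"], 2L)
  expect_equal(prof[[1]]$counts["y", "G"], 2L)
  expect_equal(prof[[3]]$counts["x", "DEL"], 1L)
  expect_equal(prof[[3]]$counts["x", "T"], 1L)
  expect_equal(prof[[3]]$n_effective, c(x = 2L, y = 2L))

  # an R is indeterminate by default, expanded to A and G under "expand"
  amb <- make_aln(c("R", "A", "G"), c("x", "x", "y"))
  p1 <- profile_columns(amb)[[1]]
  expect_equal(p1$n_effective[["x"]], 1L)
  expect_equal(p1$counts["x", "A"], 1L)
  p2 <- profile_columns(amb, ambiguity = "expand")[[1]]
  expect_equal(p2$n_effective[["x"]], 2L)
  expect_equal(unname(p2$counts["x", c("A", "G")]), c(2L, 1L))
})

test_that("diagnostic-site detection equals the brute-force column scan", {
  # simulator-generated alignments with planted sites, deletions,
  # mislabeling and missing data
  for (seed in 1:6) {
    cfg <- study_barcode_config(seed = seed, members_per_species = 3L,
                                missing_data_rate = 0.01)
    aln <- simulate_alignment(cfg)$alignment
    found <- find_diagnostic_sites(aln)
    keep <- !grepl(";", found$sites$species, fixed = TRUE)
    want <- oracle_scan(aln, as.list(unique(aln$species)))
    expect_identical(site_key(found$sites[keep, ]), site_key(want))
  }
  # fully random alignments with gaps and ambiguity codes
  for (seed in 1:6) {
    aln <- random_messy_alignment(seed, n_species = 5L, members = 3L,
                                  n_cols = 80L)
    found <- find_diagnostic_sites(aln)
    keep <- !grepl(";", found$sites$species, fixed = TRUE)
    want <- oracle_scan(aln, as.list(unique(aln$species)))
    expect_identical(site_key(found$sites[keep, ]), site_key(want))
  }
})

test_that("an alignment of identical sequences yields no sites and lists every species", {
  aln <- make_aln(rep(strrep("ACGT", 10), 4), c("w", "x", "y", "z"))
  bt <- find_diagnostic_sites(aln)
  expect_equal(nrow(bt$sites), 0L)
  expect_setequal(bt$species_without, c("w", "x", "y", "z"))
  expect_length(bt$indistinguishable_groups, 0L)
})

test_that("planted sites are recovered exactly, deletions included, with published-style codes", {
  cfg <- study_barcode_config(seed = 101)
  sim <- simulate_alignment(cfg)
  bt <- find_diagnostic_sites(sim$alignment)
  k <- c("species", "column", "position", "target_state", "other_states")
  expect_identical(site_key(bt$sites[k]), site_key(sim$truth$true_sites[k]))

  # recall and precision both 1 relative to the planted truth
  expect_equal(nrow(bt$sites), nrow(sim$truth$true_sites))

  del <- bt$sites[bt$sites$target_state == "DEL", ]
  expect_equal(del$species, "Phalaris coerulescens")
  expect_match(del$code, "^C1$")
  para <- bt$sites[bt$sites$species == "Phalaris paradoxa", ]
  expect_equal(nrow(para), 1L)
  expect_equal(para$code, "P1")
  expect_setequal(bt$species_without,
                  c("Phalaris lemmonii", "Phalaris angusta"))
  expect_equal(bt$indistinguishable_groups,
               list(c("Phalaris brachystachys", "Phalaris canariensis")))
  group <- bt$sites[grepl(";", bt$sites$species, fixed = TRUE), ]
  expect_equal(nrow(group), 9L)
  expect_true(all(grepl("^B-C", group$code)))
})

test_that("deleting a competitor species never removes a target's diagnostic sites", {
  for (seed in 1:4) {
    cfg <- study_barcode_config(seed = seed, members_per_species = 3L)
    aln <- simulate_alignment(cfg)$alignment
    full <- find_diagnostic_sites(aln)
    target <- "Phalaris truncata"
    competitor <- "Phalaris minor"
    keep <- aln$species != competitor
    sub <- labeled_alignment(apply(aln$seq[keep, ], 1L, paste,
                                   collapse = ""),
                             aln$accession[keep], aln$species[keep],
                             mask = aln$mask)
    reduced <- find_diagnostic_sites(sub)
    before <- full$sites$column[full$sites$species == target]
    after <- reduced$sites$column[reduced$sites$species == target]
    expect_true(all(before %in% after))
  }
})

test_that("emitted singleton sites are sound: fixed inside the target, absent outside", {
  cfg <- study_barcode_config(seed = 77, missing_data_rate = 0.02)
  aln <- simulate_alignment(cfg)$alignment
  bt <- find_diagnostic_sites(aln)
  singles <- bt$sites[!grepl(";", bt$sites$species, fixed = TRUE), ]
  for (r in seq_len(nrow(singles))) {
    cc <- singles$column[r]
    st <- vapply(aln$seq[, cc], oracle_state, "")
    inside <- st[aln$species == singles$species[r]]
    outside <- st[aln$species != singles$species[r]]
    expect_true(all(inside[!is.na(inside)] == singles$target_state[r]))
    expect_false(singles$target_state[r] %in% outside[!is.na(outside)])
  }
})

test_that("queries classify to their species, fail gracefully on Ns, and tie on group sites", {
  cfg <- study_barcode_config(seed = 31)
  sim <- simulate_alignment(cfg)
  aln <- sim$alignment
  bt <- find_diagnostic_sites(aln)

  # self-classification of each species consensus that has singleton sites
  with_sites <- setdiff(unique(aln$species),
                        c(bt$species_without,
                          unlist(bt$indistinguishable_groups)))
  for (spn in with_sites) {
    consensus <- paste(aln$seq[which(aln$species == spn)[1L], ],
                       collapse = "")
    res <- classify_query(consensus, bt)
    expect_equal(res$verdict, "assigned")
    expect_equal(res$best_species, spn)
    expect_equal(res$sites_matched, res$sites_tested)
  }

  # all-N query: nothing tested, unassigned
  res_n <- classify_query(strrep("N", ncol(aln$seq)), bt)
  expect_equal(res_n$verdict, "unassigned")
  expect_equal(sum(res_n$scores$tested), 0L)

  # a member of the indistinguishable pair matches the nine group sites but
  # no singleton site: ambiguous between the two siblings
  pair <- bt$indistinguishable_groups[[1L]]
  q <- paste(aln$seq[which(aln$species == pair[1L])[1L], ], collapse = "")
  res_g <- classify_query(q, bt)
  expect_equal(res_g$verdict, "ambiguous")
  expect_setequal(res_g$ambiguous_between, pair)
  expect_equal(res_g$sites_matched, 9L)
})

test_that("barcode tables round-trip through TSV and still classify via the mask", {
  cfg <- study_barcode_config(seed = 13)
  sim <- simulate_alignment(cfg)
  bt <- find_diagnostic_sites(sim$alignment)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_table(bt, tsv)
  back <- read_barcode_table(tsv, mask = sim$alignment$mask)
  cols <- c("code", "species", "position", "target_state", "other_states")
  expect_equal(back$sites[cols], bt$sites[cols])
  expect_equal(back$sites$column, bt$sites$column)

  q <- paste(sim$alignment$seq[1L, ], collapse = "")
  expect_equal(classify_query(q, back)$verdict,
               classify_query(q, bt)$verdict)

  empty <- find_diagnostic_sites(
    make_aln(rep(strrep("AC", 10), 2), c("x", "y")))
  write_barcode_table(empty, tsv)
  expect_equal(nrow(read_barcode_table(tsv)$sites), 0L)
  expect_equal(length(readLines(tsv)), 1L)  # header only
})

test_that("a missing target species is reported by name", {
  aln <- make_aln(c("ACGT", "ACGA"), c("x", "y"))
  expect_error(find_diagnostic_sites(aln, targets = list("z")), "z")
})
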