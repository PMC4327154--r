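test_that("polarization flips alt-ancestral sites and flags unresolvable ones", {
  calls <- matrix(c(0L, 1L, 1L, 0L, 1L, 0L), 3, 2,
                  dimnames = list(c("S1", "S2", "OUT"), NULL))
  st <- data.frame(chrom = "chrY", pos = c(10L, 20L), ref = "A", alt = "G")
  hm <- haplotype_matrix(calls, st)

  # outgroup carries alt at site1 -> calls flipped there; ref at site2 -> kept
  pol <- polarize(hm, "OUT")
  expect_equal(unname(pol$calls[, 1]), c(1L, 0L))
  expect_equal(unname(pol$calls[, 2]), c(0L, 1L))
  expect_true(all(pol$ancestral_known))
  expect_false("OUT" %in% sample_ids(pol))

  # ref-is-ancestral leaves the matrix unchanged
  pol2 <- polarize(hm, "ref")
  expect_identical(pol2$calls, hm$calls)

  # missing outgroup call -> unresolvable flag, not an error
  calls[3, 2] <- NA
  hm2 <- haplotype_matrix(calls, st)
  expect_message(pol3 <- polarize(hm2, "OUT"), "1 site\\(s\\) unresolvable")
  expect_equal(pol3$ancestral_known, c(TRUE, FALSE))
})

test_that("polarization recovers simulated ancestral states exactly", {
  sim <- simulate_dataset(sim_config(n_tips = 15, seed = 11))
  hm <- sim$matrix                      # truth: derived-coded, ancestral = ref
  set.seed(42)
  flip <- runif(ncol(hm$calls)) < 0.5   # scramble coding at random sites
  scr <- hm$calls
  scr[, flip] <- 1L - scr[, flip]
  st <- hm$sites[, c("chrom", "pos", "ref", "alt")]
  tmp <- st$ref[flip]; st$ref[flip] <- st$alt[flip]; st$alt[flip] <- tmp
  # the true ancestral allele is the original ref (site ids change where
  # ref/alt were swapped, so rebuild them for the lookup table)
  anc_tab <- data.frame(site_id = site_ids(st), allele = hm$sites$ref)
  pol <- polarize(haplotype_matrix(scr, st), anc_tab)
  expect_true(all(pol$ancestral_known))
  expect_identical(unname(pol$calls), unname(hm$calls))
})

test_that("perfect phylogeny on the worked laminar family", {
  tr <- build_tree(worked_matrix())
  bs <- branch_stats(tr)
  lb <- setNames(bs$l_b, vapply(bs$branch, function(b)
    paste(sort(tr$phy$tip.label[tips_below_pub(tr$phy, b)]), collapse = ","), ""))
  expect_equal(lb[["S1,S2"]], 1L)
  expect_equal(lb[["S1"]], 1L)
  expect_equal(lb[["S3,S4"]], 2L)
  expect_true(all(tr$site_report$compatible))
  expect_equal(sum(tr$site_report$n_events), 4L)

  # adding site5 = {S2,S3} makes it incompatible: 2 events, total 6
  tr2 <- build_tree(worked_matrix(with_incompatible = TRUE))
  rep5 <- tr2$site_report[tr2$site_report$site_id == "chrY:500:A:G", ]
  expect_false(rep5$compatible)
  expect_equal(rep5$n_events, 2L)
  expect_equal(sum(tr2$site_report$n_events), 6L)

  # singleton-only matrix gives a star with one terminal event per tip
  k <- 6
  calls <- diag(k); storage.mode(calls) <- "integer"
  rownames(calls) <- paste0("T", 1:k)
  star <- build_tree(haplotype_matrix(
    calls, data.frame(chrom = "chrY", pos = seq_len(k) * 10L, ref = "A", alt = "G")))
  expect_equal(star$phy$Nnode, 1L)
  expect_equal(unname(mutations_to_root(star)), rep(1L, k))

  # degenerate inputs
  expect_error(build_tree(haplotype_matrix(
    matrix(integer(), 0, 0, dimnames = list(NULL, NULL)),
    data.frame(chrom = character(), pos = integer(),
               ref = character(), alt = character()))),
    class = "ychron_error")
})

test_that("recurrent-site placement equals exhaustive two-state parsimony", {
  tr <- build_tree(worked_matrix())
  # carrier set equal to an existing clade: one event
  expect_equal(place_recurrent(tr, c("S3", "S4"))$n_events, 1L)
  # two tips in disjoint clades: two events
  pl <- place_recurrent(tr, c("S2", "S3"))
  expect_equal(pl$n_events, 2L)
  expect_equal(pl$n_events, brute_parsimony(tr$phy, c(2L, 3L)))
  # complement of a clade: one event with free root, flagged back-mutation
  pl2 <- place_recurrent(tr, c("S2", "S3", "S4"))
  expect_equal(pl2$n_events, 1L)
  expect_true(pl2$back_mutation)
  expect_equal(pl2$n_events, brute_parsimony(tr$phy, 2:4))
  # unknown tip
  expect_error(place_recurrent(tr, "nope"), "unknown tip", class = "ychron_error")

  # random trees up to 8 tips vs the brute-force oracle
  set.seed(202)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    phy <- ape::rtree(n)
    mt <- mutation_tree(phy)
    carriers <- sample(phy$tip.label, sample(seq_len(n - 1), 1))
    got <- place_recurrent(mt, carriers)$n_events
    expect_equal(got, brute_parsimony(mt$phy, match(carriers, phy$tip.label)),
                 info = sprintf("tree %d", i))
  }
})

test_that("mutations to root: worked counts, star case, simulator truth", {
  tr <- build_tree(worked_matrix())
  expect_equal(mutations_to_root(tr),
               c(S1 = 2L, S2 = 1L, S3 = 2L, S4 = 2L))

  sim <- simulate_dataset(sim_config(n_tips = 50, seed = 3))
  tr2 <- build_tree(sim$matrix)
  expect_identical(mutations_to_root(tr2)[names(sim$tip_counts)],
                   sim$tip_counts)
})

test_that("identity classes under SNPs and STR subsets", {
  hm <- worked_matrix()
  dup <- hm$calls[c(1, 1, 2, 3, 4), ]
  rownames(dup) <- c("S1", "S1b", "S2", "S3", "S4")
  g <- identical_groups(haplotype_matrix(dup, hm$sites))
  # S3 and S4 are also indistinguishable in the worked fixture (both carry
  # exactly sites 2 and 4)
  expect_equal(g$groups, list(c("S1", "S1b"), c("S3", "S4")))
  expect_equal(g$n_classes, 3L)

  # two samples differing only at DYS576: identical under set17, distinct
  # under set21
  loci <- str_subsets()$set21
  m <- matrix(14L, 2, length(loci), dimnames = list(c("A", "B"), loci))
  m["B", "DYS576"] <- 15L
  tab <- str_profile_table(m)
  expect_equal(identical_groups(tab, "set17")$groups, list(c("A", "B")))
  expect_equal(length(identical_groups(tab, "set21")$groups), 0L)

  # SNP-difference counts inside STR-identical groups
  snp <- haplotype_matrix(
    matrix(c(0L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)),
    data.frame(chrom = "chrY", pos = 7L, ref = "A", alt = "C"))
  g2 <- identical_groups(tab, "set17", snp = snp)
  expect_equal(unname(g2$snp_differences[[1]]), 1L)
})

test_that("tree invariants hold on random simulated data", {
  for (seed in c(5, 17, 29)) {
    sim <- simulate_dataset(sim_config(n_tips = 25, seed = seed))
    tr <- build_tree(sim$matrix)

    # infinite-sites data: no recurrence
    expect_equal(sum(!tr$site_report$compatible), 0L)

    # perfect-phylogeny round trip: rebuild haplotypes from branch events
    rebuilt <- rebuild_matrix_from_tree(tr, colnames(sim$matrix$calls))
    expect_identical(rebuilt, sim$matrix$calls[rownames(rebuilt), ])

    # branch-sum rho equals mean tip path length (algebraic identity)
    rs <- rho_sigma(tr, "ROOT")
    expect_equal(rs$rho, mean(mutations_to_root(tr)))
  }
})

test_that("finite-sites recurrence report matches the simulator truth log", {
  cfg <- sim_config(n_tips = 12, Ne = 20000, sites_model = "finite",
                    n_sites = 40, seed = 9)
  sim <- simulate_dataset(cfg)
  tr <- build_tree(sim$matrix)
  truth_events <- table(sim$events$site_id)
  multi <- names(truth_events)[truth_events >= 2]
  flagged <- tr$site_report$site_id[!tr$site_report$compatible]
  # parsimony can never need more events than truly happened, and every
  # flagged site must truly be multi-hit
  expect_true(all(flagged %in% multi))
  rep_sub <- tr$site_report[match(intersect(tr$site_report$site_id,
                                            names(truth_events)),
                                  tr$site_report$site_id), ]
  expect_true(all(rep_sub$n_events <=
                  as.integer(truth_events[rep_sub$site_id])))
})
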