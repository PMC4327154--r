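test_that("genealogy models: star depths, coalescent expectation, determinism", {
  cfg <- sim_config(n_tips = 10, genealogy = "star", star_depth = 125826,
                    seed = 1)
  skel <- sim_genealogy(cfg)
  expect_equal(unname(skel$node_times[skel$phy$tip.label]), rep(0, 10))
  expect_equal(unname(skel$node_times["ROOT"]), 125826)
  expect_equal(skel$phy$edge.length, rep(125826, 10))

  # n = 2 coalescent: E[TMRCA] = Ne generations = Ne * g years
  cfg2 <- sim_config(n_tips = 2, Ne = 1000, seed = 5)
  t2 <- vapply(seq_len(2000), function(i)
    unname(sim_genealogy(cfg2, seed = i)$node_times["ROOT"]), 1.0)
  expected <- 1000 * 30
  se <- stats::sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - expected), 3 * se)

  # fixed seed: identical tree twice
  s1 <- sim_genealogy(sim_config(n_tips = 12, seed = 99))
  s2 <- sim_genealogy(sim_config(n_tips = 12, seed = 99))
  expect_identical(s1$phy, s2$phy)
  expect_identical(s1$node_times, s2$node_times)

  expect_error(sim_config(n_tips = 1, seed = 1), class = "ychron_error")
  expect_error(sim_config(n_tips = 5), "seed is mandatory", class = "ychron_error")
})

test_that("SNP simulation matches its Poisson model and truth log", {
  # star at the reference depth: mean tip count ~ mu * L * T = 468.6
  cfg <- sim_config(n_tips = 500, genealogy = "star", star_depth = 125826,
                    seed = 7)
  skel <- sim_genealogy(cfg)
  snps <- sim_snps(skel, cfg, return_matrix = FALSE)
  expected <- 1.0e-9 * 3724156 * 125826
  se <- stats::sd(snps$tip_counts) / sqrt(length(snps$tip_counts))
  expect_lt(abs(mean(snps$tip_counts) - expected), 3 * se)

  # zero rate: no variant sites
  cfg0 <- sim_config(n_tips = 5, snp_rate = 0, seed = 2)
  skel0 <- sim_genealogy(cfg0)
  expect_equal(nrow(sim_snps(skel0, cfg0)$events), 0L)
  expect_equal(ncol(sim_snps(skel0, cfg0)$matrix$calls), 0L)

  # event log and matrix agree: carriers of each site = tips below the
  # branches carrying its gains (infinite sites: exactly one event per site)
  cfg1 <- sim_config(n_tips = 15, seed = 13)
  sim <- simulate_dataset(cfg1)
  expect_equal(nrow(sim$events), ncol(sim$matrix$calls))
  expect_equal(anyDuplicated(sim$events$site_id), 0L)
  expect_identical(sim$tip_counts[colnames(sim$matrix$calls)[0]],
                   sim$tip_counts[character(0)])
  expect_equal(unname(colSums(sim$matrix$calls) >= 1), rep(TRUE, ncol(sim$matrix$calls)))
})

test_that("STR simulation: zero rate, unbiased ASD, determinism", {
  loci <- paste0("L", 1:20)
  cfg0 <- sim_config(n_tips = 8, genealogy = "star", star_depth = 30000,
                     str_rates = setNames(rep(0, 20), loci), seed = 3)
  skel <- sim_genealogy(cfg0)
  s0 <- sim_strs(skel, cfg0)
  expect_true(all(s0$profiles$counts == 14L))

  # E[ASD] = rate * t at t = 1000 generations
  cfg1 <- sim_config(n_tips = 500, genealogy = "star", star_depth = 30000,
                     str_rates = setNames(rep(6.9e-4, 20), loci), seed = 4)
  skel1 <- sim_genealogy(cfg1)
  s1 <- sim_strs(skel1, cfg1)
  a <- asd(s1$profiles, rownames(s1$profiles$counts), s1$root, loci)
  mu_t <- 6.9e-4 * 1000
  # SE of the mean over 10,000 (sample, locus) cells; per-cell variance of a
  # squared net displacement ~ 2 (mu t)^2 + mu t
  se <- sqrt((2 * mu_t^2 + mu_t) / (500 * 20))
  expect_lt(abs(a - mu_t), 3 * se)

  s2 <- sim_strs(skel1, cfg1)
  expect_identical(s1$profiles$counts, s2$profiles$counts)
})

test_that("metadata simulation: tissue labels and LCL somatic singletons", {
  # 1,000 all-LCL tips at extra rate 3: mean extra count within 3 SE of 3
  cfg <- sim_config(n_tips = 1000, genealogy = "star", star_depth = 1000,
                    tissue_probs = c(LCL = 1, blood = 0, saliva = 0),
                    lcl_extra_rate = 3, seed = 21)
  skel <- sim_genealogy(cfg)
  md <- sim_metadata(skel, cfg, matrix = NULL)
  expect_true(all(md$meta$tissue_source == "LCL"))
  per_tip <- table(factor(md$extra_events$branch, levels = skel$phy$tip.label))
  expect_lt(abs(mean(per_tip) - 3), 3 * sqrt(3 / 1000))

  # rate 0: matrix unchanged
  cfg0 <- sim_config(n_tips = 10, seed = 22, lcl_extra_rate = 0)
  sim0 <- simulate_dataset(cfg0)
  snps0 <- sim_snps(sim_genealogy(cfg0), cfg0)
  expect_identical(sim0$matrix$calls, snps0$matrix$calls)

  # extras appended to the matrix are private singletons on LCL tips
  cfg3 <- sim_config(n_tips = 40, genealogy = "star", star_depth = 5000,
                     tissue_probs = c(LCL = 0.5, blood = 0.5, saliva = 0),
                     lcl_extra_rate = 4, seed = 23)
  skel3 <- sim_genealogy(cfg3)
  snps3 <- sim_snps(skel3, cfg3)
  md3 <- sim_metadata(skel3, cfg3, matrix = snps3$matrix)
  stopifnot(nrow(md3$extra_events) > 0)
  expect_equal(ncol(md3$matrix$calls),
               ncol(snps3$matrix$calls) + nrow(md3$extra_events))
  extra_cols <- md3$extra_events$site_id
  expect_true(all(colSums(md3$matrix$calls[, extra_cols, drop = FALSE]) == 1L))
  lcl <- md3$meta$sample_id[md3$meta$tissue_source == "LCL"]
  expect_true(all(md3$extra_events$branch %in% lcl))
})

test_that("tissue-source ANOVA detects a simulated LCL somatic excess", {
  # 3 equal tissue groups; LCL excess of 3 mutations on a background of
  # ~45 (12 ka star depth keeps the Poisson variance small enough for the
  # protocol to have high power at n = 150 per group)
  run_p <- function(seed, extra) {
    cfg <- sim_config(n_tips = 450, genealogy = "star", star_depth = 12000,
                      tissue_probs = c(LCL = 1, blood = 1, saliva = 1) / 3,
                      lcl_extra_rate = extra, seed = seed)
    skel <- sim_genealogy(cfg)
    snps <- sim_snps(skel, cfg, return_matrix = FALSE)
    md <- sim_metadata(skel, cfg, matrix = NULL)
    counts <- snps$tip_counts
    if (nrow(md$extra_events)) {
      add <- table(md$extra_events$branch)
      counts[names(add)] <- counts[names(add)] + as.integer(add)
    }
    gr <- split(as.numeric(counts),
                md$meta$tissue_source[match(names(counts), md$meta$sample_id)])
    anova_one_way(gr)$p_value
  }
  hits <- sum(vapply(1:100, function(s) run_p(s, 3) < 0.05, NA))
  expect_gte(hits, 80)
  # null control: no excess, detection at the nominal level
  null_hits <- sum(vapply(1:60, function(s) run_p(1000 + s, 0) < 0.05, NA))
  expect_lte(null_hits / 60, 0.15)
})

test_that("simulation is a pure function of (config, seed) end to end", {
  cfg <- sim_config(n_tips = 20, seed = 50, lcl_extra_rate = 2)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$matrix$calls, s2$matrix$calls)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$str$profiles$counts, s2$str$profiles$counts)
  expect_identical(s1$meta, s2$meta)

  # written files are text and round-trip
  pre <- file.path(tempdir(), "simtest")
  paths <- write_simulation(s1, pre)
  expect_true(all(file.exists(paths)))
  hm <- read_haploid_vcf(paths["vcf"])
  expect_identical(hm$calls, s1$matrix$calls)
  tab <- read_str_table(paths["str"])
  expect_identical(tab$counts, s1$str$profiles$counts)
})
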