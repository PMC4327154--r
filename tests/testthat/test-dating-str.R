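make_profiles <- function(m, loci = NULL) {
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(m)))
  dimnames(m) <- list(paste0("S", seq_len(nrow(m))), loci)
  str_profile_table(m)
}

test_that("modal haplotype takes the per-locus mode with smallest-allele ties", {
  tab <- make_profiles(rbind(c(10L, 10L), c(10L, 12L), c(12L, 12L)))
  mh <- modal_haplotype(tab, c("S1", "S2", "S3"), c("L1", "L2"))
  expect_equal(unname(mh$alleles), c(10L, 12L))
  # tie {10,12} at L1 between S2 and S3 -> smallest allele
  mh2 <- modal_haplotype(tab, c("S2", "S3"), c("L1", "L2"))
  expect_equal(unname(mh2$alleles[1]), 10L)
  # single member: its own haplotype
  mh3 <- modal_haplotype(tab, "S3", c("L1", "L2"))
  expect_equal(unname(mh3$alleles), c(12L, 12L))
  expect_equal(mh3$provenance, "modal")
  expect_error(modal_haplotype(tab, character(0)), "empty", class = "ychron_error")
})

test_that("ASD and STR rho on the worked 2x2 case", {
  tab <- make_profiles(rbind(c(10L, 12L), c(12L, 14L)))
  root <- root_haplotype(c(L1 = 11L, L2 = 13L))
  expect_equal(asd(tab, c("S1", "S2"), root, c("L1", "L2")), 1.0)
  expect_equal(rho_str(tab, c("S1", "S2"), root, c("L1", "L2")), 1.0)
  # members equal to root -> 0
  root2 <- root_haplotype(c(L1 = 10L, L2 = 12L))
  expect_equal(asd(tab, "S1", root2, c("L1", "L2")), 0)
  expect_equal(rho_str(tab, "S1", root2, c("L1", "L2")), 0)
  # root must cover the subset
  expect_error(asd(tab, "S1", root_haplotype(c(L1 = 10L)), c("L1", "L2")),
               "cover", class = "ychron_error")
})

test_that("ASD/rho invariances: allele shift and scaling", {
  set.seed(5)
  m <- matrix(sample(8:20, 40, replace = TRUE), 8, 5)
  tab <- make_profiles(m)
  root <- root_haplotype(setNames(rep(14L, 5), colnames(tab$counts)))
  a0 <- asd(tab, rownames(tab$counts), root, colnames(tab$counts))
  r0 <- rho_str(tab, rownames(tab$counts), root, colnames(tab$counts))
  # shift every allele (and the root) by +5: both statistics unchanged
  tab2 <- make_profiles(m + 5L)
  root2 <- root_haplotype(setNames(rep(19L, 5), colnames(tab2$counts)))
  expect_equal(asd(tab2, rownames(tab2$counts), root2, colnames(tab2$counts)), a0)
  expect_equal(rho_str(tab2, rownames(tab2$counts), root2, colnames(tab2$counts)), r0)
  # scale by k: ASD scales k^2, rho scales k
  k <- 3L
  tab3 <- make_profiles(m * k)
  root3 <- root_haplotype(setNames(rep(14L * k, 5), colnames(tab3$counts)))
  expect_equal(asd(tab3, rownames(tab3$counts), root3, colnames(tab3$counts)),
               a0 * k^2)
  expect_equal(rho_str(tab3, rownames(tab3$counts), root3, colnames(tab3$counts)),
               r0 * k)
})

test_that("STR TMRCA conversion: rates, linearity, regimes", {
  rm <- rate_model()
  est <- tmrca_str(1.0, "asd", "set21", "evolutionary", rm)
  expect_equal(est$tmrca_generations, 1 / 6.9e-4, tolerance = 1e-12)
  expect_equal(est$tmrca_years, 30 / 6.9e-4, tolerance = 1e-12)

  expect_equal(tmrca_str(0, "asd", "set21", "evolutionary", rm)$tmrca_years, 0)

  # pedigree vs evolutionary estimates are in the exact inverse rate ratio
  for (ss in c("set21", "set17", "set13")) {
    ped <- str_mean_rate(rm, ss, "pedigree")
    expect_true(ped >= 2.797e-3 && ped <= 4.238e-3)
    e1 <- tmrca_str(2.5, "asd", ss, "evolutionary", rm)$tmrca_years
    e2 <- tmrca_str(2.5, "asd", ss, "pedigree", rm)$tmrca_years
    expect_equal(e1 / e2, ped / 6.9e-4, tolerance = 1e-12)
  }
  # linearity in the statistic
  expect_equal(tmrca_str(3, "rho", "set13", "evolutionary", rm)$tmrca_years,
               3 * tmrca_str(1, "rho", "set13", "evolutionary", rm)$tmrca_years)
})

test_that("ASD is unbiased under single-step mutation; rho saturates", {
  g <- 30
  # moderate depth: E[ASD] = rate * t
  t_gen <- 1000; rate <- 6.9e-4
  cfg <- sim_config(n_tips = 400, genealogy = "star", star_depth = t_gen * g,
                    str_rates = setNames(rep(rate, 20), paste0("L", 1:20)),
                    seed = 31)
  sim_s <- sim_strs(sim_genealogy(cfg), cfg)
  a <- asd(sim_s$profiles, rownames(sim_s$profiles$counts), sim_s$root,
           paste0("L", 1:20))
  mu_t <- rate * t_gen
  se <- sqrt((2 * mu_t^2 + mu_t) / (400 * 20))   # var of squared net steps
  expect_lt(abs(a - mu_t), 3 * se)

  # deep genealogy (mu*t >= 4): net displacement undercounts events
  t_gen2 <- 6500
  cfg2 <- sim_config(n_tips = 400, genealogy = "star", star_depth = t_gen2 * g,
                     str_rates = setNames(rep(rate, 20), paste0("L", 1:20)),
                     seed = 32)
  sim2 <- sim_strs(sim_genealogy(cfg2), cfg2)
  members <- rownames(sim2$profiles$counts)
  a2 <- asd(sim2$profiles, members, sim2$root, paste0("L", 1:20))
  r2 <- rho_str(sim2$profiles, members, sim2$root, paste0("L", 1:20))
  expect_lt(r2, rate * t_gen2)
  expect_lt(r2, a2)
})

test_that("STR-vs-SNP comparison table: exact agreement and systematic bias", {
  snp <- do.call(rbind, lapply(1:5, function(i)
    tmrca_snp(i * 50, rates = rate_model(), clade = paste0("C", i), n = 10L)))
  mk_str <- function(f) {
    do.call(rbind, lapply(1:5, function(i) {
      est <- tmrca_str(1, "asd", "set21", "evolutionary", rate_model(),
                       clade = paste0("C", i), root_provenance = "modal")
      est$tmrca_years <- f * snp$tmrca_years[i]
      est
    }))
  }
  cmp1 <- compare_estimates(snp, mk_str(1))
  expect_equal(cmp1$pearson_r, 1)
  expect_equal(cmp1$mean_rel_error, 0)
  cmp2 <- compare_estimates(snp, mk_str(2))
  expect_equal(cmp2$pearson_r, 1)
  expect_equal(cmp2$mean_rel_error, 1)
  expect_equal(cmp2$bias, "over")

  # < 3 shared clades: correlation undefined
  cmp3 <- compare_estimates(snp[1:2, ], mk_str(1)[1:2, ])
  expect_true(is.na(cmp3$pearson_r))
})

test_that("evolutionary rate overestimates and pedigree underestimates when the truth is between them", {
  # star clades of known depth simulated at a rate between the two regimes
  g <- 30
  true_rate <- 1.6e-3
  depths <- seq(500, 2400, length.out = 8) * g
  rows_snp <- list(); rows_str <- list()
  rm <- rate_model()
  for (i in seq_along(depths)) {
    cfg <- sim_config(n_tips = 60, genealogy = "star", star_depth = depths[i],
                      str_rates = setNames(rep(true_rate, 17), str_subsets()$set17),
                      seed = 100 + i)
    skel <- sim_genealogy(cfg)
    strs <- sim_strs(skel, cfg)
    a <- asd(strs$profiles, rownames(strs$profiles$counts), strs$root, "set17")
    rows_str[[i]] <- rbind(
      tmrca_str(a, "asd", "set17", "evolutionary", rm, clade = paste0("C", i),
                root_provenance = "ancestral"),
      tmrca_str(a, "asd", "set17", "pedigree", rm, clade = paste0("C", i),
                root_provenance = "ancestral"))
    # stand-in "SNP" estimate = truth (what rho dating recovers on average)
    rows_snp[[i]] <- data.frame(clade = paste0("C", i),
                                tmrca_years = depths[i])
  }
  cmp <- compare_estimates(do.call(rbind, rows_snp), do.call(rbind, rows_str))
  evo <- cmp[cmp$regime == "evolutionary", ]
  ped <- cmp[cmp$regime == "pedigree", ]
  expect_equal(evo$bias, "over")
  expect_equal(ped$bias, "under")
  expect_gt(evo$pearson_r, 0.9)   # ordering is preserved even when biased
})
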