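test_that("equal seeds give identical outputs for every generator", {
  cfg <- community_config(n_taxa = 30, n_orfs = 2000, n_samples = 2, seed = 99)
  expect_identical(generate_orf_table(cfg), generate_orf_table(cfg))

  p1 <- generate_codon_pair(2, n_codons = 100, n_events = 30, seed = 5)
  p2 <- generate_codon_pair(2, n_codons = 100, n_events = 30, seed = 5)
  expect_identical(p1, p2)

  g1 <- generate_aa_groups(n1 = 8, n2 = 6, seed = 3)
  g2 <- generate_aa_groups(n1 = 8, n2 = 6, seed = 3)
  expect_identical(g1, g2)

  s1 <- generate_presence_sets(c(10, 12), 4, seed = 7)
  s2 <- generate_presence_sets(c(10, 12), 4, seed = 7)
  expect_identical(s1, s2)
})

test_that("generated tables satisfy the ORF-table invariants", {
  cfg <- community_config(n_taxa = 60, n_orfs = 5000, n_samples = 3,
                          transposase_fraction = 0.03, seed = 17)
  tb <- generate_orf_table(cfg)
  tpm <- as.matrix(tb[grep("^tpm_", names(tb))])
  expect_equal(unname(colSums(tpm)), rep(1e6, 3), tolerance = 1e-9)
  expect_true(all(tb$length_bp >= 60 & tb$length_bp <= 8748))
  expect_true(all(tb$length_bp %% 3 == 0))
  expect_true(all(tb$gc_fraction > 0 & tb$gc_fraction < 1))
  expect_false(anyDuplicated(tb$orf_id) > 0)
  taxa <- attr(tb, "taxa")
  expect_equal(sum(taxa$d_obs), nrow(tb))
})

test_that("realized transposase fraction concentrates on the target", {
  cfg <- community_config(n_taxa = 160, n_orfs = 50000, n_samples = 1,
                          transposase_fraction = 0.0271, seed = 23)
  tb <- generate_orf_table(cfg)
  pct <- 100 * mean(tb$gene_name == "transposase")
  expect_lt(abs(pct - 2.71), 0.3)
  expect_true(all(tb$cog[tb$gene_name == "transposase"] %in% c("COG2801", "COG2963")))

  cfg0 <- community_config(n_taxa = 30, n_orfs = 2000, n_samples = 1,
                           transposase_fraction = 0, seed = 23)
  cen <- transposase_census(generate_orf_table(cfg0))
  expect_equal(cen$mean_count_pct, 0)
})

test_that("noiseless richness generation lies on the generating power law", {
  pts <- generate_richness_points(50, c = 0.2, gamma = 1,
                                  abundance_log10_range = c(1, 3),
                                  noise = "none", seed = 2)
  keep <- pts$d_obs >= 1
  # up to integer rounding of counts
  expect_true(all(abs(pts$d_obs - pts$d_expected) <= 0.5))
  fit <- fit_power_law(pts)
  expect_equal(fit$gamma, 1, tolerance = 0.02)

  # exact at the expectation level for any (c, gamma)
  pts2 <- generate_richness_points(40, c = 3.7, gamma = 0.6,
                                   abundance_log10_range = c(2, 4),
                                   noise = "none", seed = 3)
  expect_equal(pts2$d_expected, 3.7 * pts2$A^0.6, tolerance = 1e-12)
})

test_that("full-table noiseless generation recovers the generating law", {
  cfg <- community_config(n_taxa = 30, n_orfs = 1000, n_samples = 1,
                          abundance_log10_range = c(2, 4),
                          richness_intercept = 0.5, richness_slope = 1,
                          richness_noise = "none", transposase_fraction = 0,
                          orphan_fraction = 0, sample_sdlog = 0, orf_sdlog = 0,
                          presence_prob = 1, seed = 3)
  tb <- generate_orf_table(cfg)
  fit <- fit_power_law(build_points(tb))
  expect_equal(fit$gamma, 1, tolerance = 1e-3)
  expect_equal(fit$c, 0.5, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("omega limiting cases shape the descendant sequence", {
  p0 <- generate_codon_pair(omega = 1, n_codons = 50, n_events = 0, seed = 1)
  expect_identical(p0$seq_a, p0$seq_b)
  est0 <- ng86(p0$seq_a, p0$seq_b)
  expect_equal(est0$Sd + est0$Nd, 0)

  psyn <- generate_codon_pair(omega = 0, n_codons = 200, n_events = 100, seed = 2)
  est <- ng86(psyn$seq_a, psyn$seq_b)
  expect_equal(est$Nd, 0)
  expect_gt(est$Sd, 0)
})

test_that("presence sets honor requested sizes and overlaps exactly", {
  s <- generate_presence_sets(c(170, 168), 106, seed = 1)
  expect_equal(lengths(s), c(S1 = 170L, S2 = 168L))
  expect_equal(length(intersect(s$S1, s$S2)), 106)
  expect_equal(jaccard(s$S1, s$S2), 106 / 232, tolerance = 1e-12)
  expect_equal(round(jaccard(s$S1, s$S2), 4), 0.4569)

  same <- generate_presence_sets(c(5, 5), 5, seed = 2)
  expect_equal(jaccard(same$S1, same$S2), 1)
  disjoint <- generate_presence_sets(c(5, 5), 0, seed = 3)
  expect_equal(jaccard(disjoint$S1, disjoint$S2), 0)

  three <- generate_presence_sets(c(20, 18, 15), c(8, 6, 5), seed = 4)
  expect_equal(length(intersect(three$S1, three$S2)), 8)
  expect_equal(length(intersect(three$S1, three$S3)), 6)
  expect_equal(length(intersect(three$S2, three$S3)), 5)
  expect_error(generate_presence_sets(c(5, 5), 6, seed = 1),
               class = "deuteromics_config_error")
})

test_that("config contract violations are rejected", {
  expect_error(community_config(n_taxa = 100, n_orfs = 50),
               class = "deuteromics_config_error")
  expect_error(community_config(min_bp = 10), class = "deuteromics_config_error")
  expect_error(generate_aa_groups(effect_profile = c(rep(-0.06, 10), rep(0, 10))),
               class = "deuteromics_config_error")
})
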