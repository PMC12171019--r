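test_that("points aggregate ORFs by species with summed abundance", {
  taxa <- c(rep("Bacteria;P;G;species_1", 3), "Bacteria;P;G;species_2")
  tb <- make_orf_table(4, samples = "S1", taxon = taxa)
  tb$tpm_S1 <- c(10, 20, 30, 5)
  pts <- build_points(tb, "drum1")
  p1 <- pts[pts$taxon == "species_1", ]
  expect_equal(p1$A, 60)
  expect_equal(p1$d_obs, 3L)

  # an ORF present in two samples counts once but sums both abundances
  tb2 <- make_orf_table(1, samples = c("S1", "S2"))
  tb2$tpm_S1 <- 40; tb2$tpm_S2 <- 25
  pts2 <- build_points(tb2)
  expect_equal(pts2$d_obs, 1L)
  expect_equal(pts2$A, 65)
})

test_that("gene scoping restricts points and can empty a taxon", {
  taxa <- c("Bacteria;P;G;species_1", "Bacteria;P;G;species_2")
  tb <- make_orf_table(2, samples = "S1", taxon = taxa)
  tb$gene_name <- c("nifH", "recA")
  pts <- build_points(tb, gene_scope = "nifH")
  expect_equal(pts$taxon, "species_1")
  expect_warning(empty <- build_points(tb, gene_scope = "nosuchgene"))
  expect_equal(nrow(empty), 0)
})

test_that("exact log-linear data is recovered perfectly", {
  fit <- fit_power_law(tibble::tibble(A = c(10, 100, 1000), d_obs = c(2, 20, 200)))
  expect_equal(fit$gamma, 1, tolerance = 1e-12)
  expect_equal(fit$c, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  fit2 <- fit_power_law(tibble::tibble(A = c(4, 16, 64), d_obs = c(10, 20, 40)))
  expect_equal(fit2$gamma, 0.5, tolerance = 1e-12)
  expect_equal(fit2$c, 5, tolerance = 1e-12)
})

test_that("degenerate inputs raise fit errors and exclusions are counted", {
  expect_error(fit_power_law(tibble::tibble(A = c(1, 2), d_obs = c(1, 2))),
               class = "deuteromics_fit_error")
  expect_error(fit_power_law(tibble::tibble(A = rep(10, 5), d_obs = 1:5)),
               class = "deuteromics_fit_error")
  pts <- tibble::tibble(A = c(10, 100, 1000, 50), d_obs = c(2L, 20L, 200L, 0L))
  fit <- fit_power_law(pts)
  expect_equal(fit$n_points, 3)
  expect_equal(fit$n_excluded, 1)
})

test_that("delta coefficients and their geometric mean behave as OLS residuals", {
  set.seed(14)
  pts <- generate_richness_points(200, c = 0.8, gamma = 0.75,
                                  abundance_log10_range = c(2, 4), seed = 14)
  fit <- fit_power_law(pts)
  dd <- delta_distribution(pts, fit)
  expect_equal(mean(dd$deltas$log_delta), 0, tolerance = 1e-9)

  # point exactly double the expectation has delta 2
  one <- tibble::tibble(A = 100, d_obs = as.integer(round(2 * expected_richness(fit, 100))))
  d1 <- one$d_obs / expected_richness(fit, one$A)
  expect_equal(d1, 2, tolerance = 0.01)

  # points exactly on the law: all deltas 1, KDE peaks at 0
  exact <- tibble::tibble(A = 10^seq(1, 3, length.out = 20),
                          d_obs = as.integer(round(5 * (10^seq(1, 3, length.out = 20))^0.5)))
  fit_e <- fit_power_law(exact)
  dd_e <- delta_distribution(exact, fit_e, kde_bandwidth = 0.05)
  expect_true(all(abs(dd_e$deltas$log_delta) < 0.01))
  expect_lt(abs(dd_e$kde$x[which.max(dd_e$kde$density)]), 0.02)
})

test_that("slope comparison matches the hand-computed z test", {
  res <- compare_slopes(list(gamma = 0.757, se_gamma = 0.072),
                        list(gamma = 0.78, se_gamma = 0.023))
  expect_equal(res$z, -0.304, tolerance = 1e-3)
  expect_equal(res$p_value, 0.761, tolerance = 1e-3)

  same <- compare_slopes(list(gamma = 0.7, se_gamma = 0.05),
                         list(gamma = 0.7, se_gamma = 0.05))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  ab <- compare_slopes(list(gamma = 0.5, se_gamma = 0.1),
                       list(gamma = 0.9, se_gamma = 0.2))
  ba <- compare_slopes(list(gamma = 0.9, se_gamma = 0.2),
                       list(gamma = 0.5, se_gamma = 0.1))
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("spread ratio scales with the log-delta dispersion", {
  set.seed(15)
  pts <- generate_richness_points(150, c = 1, gamma = 0.7,
                                  abundance_log10_range = c(2, 4), seed = 15)
  fit <- fit_power_law(pts)
  dd <- delta_distribution(pts, fit)
  expect_equal(compare_spread(dd, dd), 1)

  wide <- dd
  wide$spread <- 2 * dd$spread
  expect_equal(compare_spread(wide, dd), 2)

  # extra dispersion widens the distribution
  noisy <- pts
  noisy$d_obs <- as.integer(pmax(1, round(noisy$d_obs * exp(rnorm(150, 0, 0.5)))))
  fit_n <- fit_power_law(noisy)
  dd_n <- delta_distribution(noisy, fit_n)
  expect_gt(compare_spread(dd_n, dd), 1)
})

test_that("parameter recovery at survey scale is unbiased within tolerance", {
  gammas <- vapply(1:30, function(i) {
    pts <- generate_richness_points(319, c = 0.5, gamma = 0.757,
                                    abundance_log10_range = c(2.5, 4.5),
                                    seed = 1000 + i)
    fit_power_law(pts)$gamma
  }, 0)
  expect_lt(abs(mean(gammas) - 0.757), 0.02)
  expect_lt(sd(gammas), 0.05)
})

test_that("broom-style accessors expose fit quantities", {
  fit <- fit_power_law(tibble::tibble(A = c(10, 100, 1000, 40),
                                      d_obs = c(3L, 18L, 150L, 9L)))
  td <- tidy(fit)
  expect_equal(td$term, c("c", "gamma"))
  expect_equal(td$estimate[2], fit$gamma)
  gl <- glance(fit)
  expect_equal(gl$n_points, 4)
})
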