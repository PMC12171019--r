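test_that("composition rows are relative frequencies on the 20-letter alphabet", {
  m <- composition_matrix(c(s1 = "AAAA", s2 = "ACACACAC", s3 = "AXA-"))
  x <- as.matrix(m[, -1])
  expect_equal(unname(x["s1" == m$sequence_id, "A"]), 1)
  expect_equal(unname(x[2, "A"]), 0.5)
  expect_equal(unname(x[2, "C"]), 0.5)
  expect_equal(unname(x[3, "A"]), 1)  # X and gap dropped before normalization
  expect_equal(unname(rowSums(x)), rep(1, 3), tolerance = 1e-9)
  expect_error(composition_matrix(c(bad = "XX--")), class = "deuteromics_value_error")
})

test_that("self-correlation is 1 for identical rows and 0 for orthogonal ones", {
  m <- composition_matrix(c(a = "ACDEFG", b = "ACDEFG", c = "ACDEFG"))
  expect_equal(group_self_correlation(m), 1, tolerance = 1e-12)

  # two centered, orthogonal frequency vectors by construction
  r1 <- c(2, 2, 1, 1, rep(1.5, 16)); r1 <- r1 / sum(r1)
  r2 <- c(2, 1, 2, 1, rep(1.5, 16))
  r2 <- r2 * (sum(r1) / sum(r2)); r2 <- r2 / sum(r2)
  m2 <- tibble::as_tibble(rbind(r1, r2), .name_repair = "minimal")
  names(m2) <- deuteromics:::AA20
  m2 <- tibble::add_column(m2, sequence_id = c("r1", "r2"), .before = 1)
  class(m2) <- c("aa_composition", class(m2))
  expect_equal(abs(group_self_correlation(m2)),
               abs(cor(r1, r2)), tolerance = 1e-12)
  expect_equal(group_self_correlation(m2), 0, tolerance = 1e-9)

  expect_equal(group_self_correlation(m), group_self_correlation(m), tolerance = 0)
})

test_that("identical groups classify every residue as same", {
  g <- generate_aa_groups(n1 = 10, n2 = 10, seed = 4)
  res <- enrichment_test(g$a, g$a)
  expect_true(all(res$class == "same"))
  expect_equal(unname(attr(res, "counts")["n_same"]), 20L)
})

test_that("classification counts sum to 20 and swap under group exchange", {
  shifts <- c(rep(0.015, 3), rep(-0.009, 5), rep(0, 12))
  g <- generate_aa_groups(n1 = 60, n2 = 40, effect_profile = shifts, seed = 10)
  ab <- enrichment_test(g$a, g$b)
  ba <- enrichment_test(g$b, g$a)
  expect_equal(sum(attr(ab, "counts")), 20L)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$class == "enriched", ba$class == "depleted")
  expect_equal(ab$class == "same", ba$class == "same")
})

test_that("vectorized Welch test agrees with stats::t.test per column", {
  g <- generate_aa_groups(n1 = 15, n2 = 12,
                          effect_profile = c(0.01, rep(0, 19)), seed = 2)
  res <- enrichment_test(g$a, g$b)
  for (j in c(1, 5, 20)) {
    ref <- t.test(g$a[[deuteromics:::AA20[j]]], g$b[[deuteromics:::AA20[j]]])
    expect_equal(res$t_statistic[j], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$p_value[j], ref$p.value, tolerance = 1e-9)
  }
  res_student <- enrichment_test(g$a, g$b, var_equal = TRUE)
  ref <- t.test(g$a$A, g$b$A, var.equal = TRUE)
  expect_equal(res_student$p_value[1], ref$p.value, tolerance = 1e-9)
})

test_that("Benjamini-Hochberg correction is available and never more liberal", {
  shifts <- c(rep(0.012, 2), rep(-0.008, 3), rep(0, 15))
  g <- generate_aa_groups(n1 = 40, n2 = 30, effect_profile = shifts, seed = 6)
  raw <- enrichment_test(g$a, g$b, correction = "none")
  bh <- enrichment_test(g$a, g$b, correction = "bh")
  expect_true(all(bh$adjusted_p >= raw$p_value - 1e-15))
  expect_lte(sum(bh$class != "same"), sum(raw$class != "same"))
})
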