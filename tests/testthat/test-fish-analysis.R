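test_that("shortest inter-locus distance takes the minimum over allele pairs", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0),      # bait alleles
               c(0.3, 0, 0), c(3, 0, 0))    # partner alleles
  fish <- unit_sphere_fish(pos, gene = c("bait", "bait", "gX", "gX"))
  d <- min_pair_distance(fish, "bait", "gX")
  expect_equal(d$distance_um, 0.3)
  # single partner allele nearest to the second bait allele
  pos2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0.2, 0))
  fish2 <- unit_sphere_fish(pos2, gene = c("bait", "bait", "gX"))
  expect_equal(min_pair_distance(fish2, "bait", "gX")$distance_um, 0.2)
  # symmetry
  expect_equal(min_pair_distance(fish, "gX", "bait")$distance_um, 0.3)
  # nucleus missing a gene is skipped and logged
  fish3 <- unit_sphere_fish(rbind(c(0, 0, 0)), gene = "bait")
  d3 <- min_pair_distance(fish3, "bait", "gX")
  expect_equal(nrow(d3), 0)
  expect_equal(attr(d3, "skipped")$missing, "gX")
})

test_that("min distance matches a brute-force all-pairs oracle", {
  withr::local_seed(61)
  for (i in 1:15) {
    na <- sample(1:3, 1)
    nb <- sample(1:3, 1)
    pos <- matrix(runif((na + nb) * 3, -5, 5), ncol = 3)
    fish <- unit_sphere_fish(pos, gene = rep(c("A", "B"), c(na, nb)))
    got <- min_pair_distance(fish, "A", "B")$distance_um
    want <- Inf
    for (a in seq_len(na)) {
      for (b in seq_len(nb)) {
        want <- min(want, sqrt(sum((pos[a, ] - pos[na + b, ])^2)))
      }
    }
    expect_equal(got, want)
  }
})

test_that("association call is inclusive at exactly 500 nm", {
  expect_true(call_association(0.499))
  expect_true(call_association(0.5))
  expect_false(call_association(0.501))
  expect_error(call_association(-1), ">= 0")
})

test_that("association frequencies conserve nucleus counts per condition", {
  cfg <- tiny_synth_config(n_nuclei = 60, seed = 63)
  fish <- simulate_fish(cfg, partners = "gX",
                        assoc_fraction = c("NPC" = 0.1, "LIF+" = 0.6,
                                           "LIF-" = 0.1))
  af <- association_frequencies(fish, "bait", "gX")
  expect_equal(unname(colSums(af$table)), af$frequencies$n_total)
  expect_equal(af$frequencies$n_total, rep(60L, 3))
  expect_true(all(af$frequencies$fraction >= 0 &
                    af$frequencies$fraction <= 1))
  expect_warning(association_frequencies(fish, "bait", "gX",
                                         conditions = c("NPC", "ESC")),
                 "ESC")
})

test_that("planted association fractions are recovered within binomial error", {
  cfg <- tiny_synth_config(n_nuclei = 400, seed = 65)
  f0 <- 0.5
  fish <- simulate_fish(cfg, partners = "gX", assoc_fraction = f0,
                        conditions = "LIF+")
  af <- association_frequencies(fish, "bait", "gX")
  se <- sqrt(f0 * (1 - f0) / 400)
  # small upward bias from chance proximity of unplanted alleles (~0.004)
  expect_lt(abs(af$frequencies$fraction - f0), 3 * se + 0.01)
})

test_that("chi-squared residual analysis matches direct arithmetic", {
  # independence: zero statistic and residuals
  ind <- outer(c(10, 20), c(3, 7)) / 10
  r0 <- chisq_residual_test(ind)
  expect_equal(r0$statistic, 0)
  expect_equal(unname(as.vector(r0$residuals)), rep(0, 4))
  # hand-computed 2x2
  m <- matrix(c(10, 20, 20, 10), 2)
  r <- chisq_residual_test(m)
  want <- oracle_chisq(m)
  expect_equal(r$statistic, want$chi2)
  expect_equal(unname(r$residuals), unname(want$adj))
  # over-represented cell positive, complement negative
  expect_gt(r$residuals[1, 2], 0)
  expect_lt(r$residuals[1, 1], 0)
  withr::local_seed(71)
  for (i in 1:25) {
    m <- random_table(sample(2:3, 1), sample(2:4, 1))
    r <- chisq_residual_test(m)
    want <- oracle_chisq(m)
    expect_equal(r$statistic, want$chi2)
    expect_equal(unname(r$residuals), unname(want$adj))
    expect_equal(r$df, (nrow(m) - 1) * (ncol(m) - 1))
    # permutation invariance of the statistic
    perm <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
    expect_equal(chisq_residual_test(perm)$statistic, r$statistic)
  }
  expect_error(chisq_residual_test(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("Fisher's exact p equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  ext <- fisher_exact_2x2(matrix(c(0, 8, 8, 0), 2))
  expect_equal(ext$p_value, oracle_fisher_p(matrix(c(0, 8, 8, 0), 2)))
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2 x 2")
  withr::local_seed(73)
  for (i in 1:40) {
    m <- matrix(sample(0:12, 4, TRUE), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m)$p_value, oracle_fisher_p(m),
                 tolerance = 1e-10)
  }
  # odds ratio with half-correction on zero cells
  expect_equal(fisher_exact_2x2(matrix(c(4, 2, 1, 3), 2))$odds_ratio, 6)
  or0 <- fisher_exact_2x2(matrix(c(0, 5, 5, 5), 2))$odds_ratio
  expect_equal(or0, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("KS statistic hits its extremes and ANOVA F equals t-squared", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_error(ks_two_sample(numeric(), 1:3), "nonempty")
  withr::local_seed(79)
  for (i in 1:25) {
    a <- rnorm(sample(5:30, 1), 10, 1.5)
    b <- rnorm(sample(5:30, 1), 10, 1.5)
    res <- anova_oneway(list(g1 = a, g2 = b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
  expect_error(anova_oneway(list(a = 1:5)), "2 groups")
  expect_error(anova_oneway(list(a = c(1, 1), b = c(1, 1))), "undefined")
})

test_that("nuclear diameters across conditions are typically indistinguishable", {
  withr::local_seed(83)
  p <- replicate(20, {
    groups <- list(NPC = rnorm(60, 10.4, 1.5), `LIF+` = rnorm(60, 10.1, 1.1),
                   `LIF-` = rnorm(60, 10.2, 1.2))
    anova_oneway(groups)$p_value
  })
  # a ~0.3 micron spread in the means is usually undetectable at this n
  expect_gt(mean(p > 0.05), 0.6)
})

test_that("allele-level activity association builds the right margins", {
  cfg <- tiny_synth_config(n_nuclei = 150, seed = 85)
  fish <- simulate_fish(cfg, partners = "gX", conditions = "LIF+",
                        activity = TRUE, active_assoc_fraction = 0.9,
                        inactive_assoc_fraction = 0.05)
  res <- allele_activity_association(fish, bait = "bait", partner = "gX")
  expect_equal(sum(res$table), 300)  # two bait alleles per nucleus
  expect_equal(unname(rowSums(res$table)), c(150, 150))
  expect_gt(res$fisher$odds_ratio, 1)
  expect_lt(res$fisher$p_value, 0.01)
  expect_error(allele_activity_association(
    dplyr::mutate(fish, allele_active = NA), partner = "gX"), "activity")
})

test_that("shuffled activity labels give odds ratios centred at 1", {
  cfg <- tiny_synth_config(n_nuclei = 120, seed = 87)
  fish <- simulate_fish(cfg, partners = "gX", conditions = "LIF+",
                        activity = TRUE, active_assoc_fraction = 0.6,
                        inactive_assoc_fraction = 0.6)
  res <- allele_activity_association(fish, partner = "gX")
  # equal per-allele planting: no activity effect to detect
  expect_gt(res$fisher$p_value, 0.01)
})

test_that("triple colocalisation never exceeds any pairwise fraction", {
  tight <- unit_sphere_fish(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0)),
                            gene = c("A", "B", "C"))
  expect_equal(triple_colocalization(tight, c("A", "B", "C"))$fraction, 1)
  loose <- unit_sphere_fish(rbind(c(0, 0, 0), c(0.1, 0, 0), c(3, 0, 0)),
                            gene = c("A", "B", "C"))
  expect_equal(triple_colocalization(loose, c("A", "B", "C"))$fraction, 0)
  cfg <- tiny_synth_config(n_nuclei = 80, seed = 89)
  fish <- simulate_fish(cfg, partners = c("g1", "g2"), assoc_fraction = 0.5,
                        conditions = "LIF+")
  tri <- triple_colocalization(fish, c("bait", "g1", "g2"))
  for (p in list(c("bait", "g1"), c("bait", "g2"), c("g1", "g2"))) {
    af <- association_frequencies(fish, p[1], p[2])
    expect_lte(tri$fraction, af$frequencies$fraction)
  }
  expect_error(triple_colocalization(fish, c("a", "b")), "three")
})
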