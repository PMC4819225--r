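test_that("noiseless e4C arrays put planted probes exactly at the planted signal", {
  cfg <- tiny_synth_config(noise_sd = 0, spike_noise_sd = 0, interaction_signal_log2 = 3)
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), chrom = "chr1",
    start = c(100, 5000, 9000), end = c(160, 5060, 9060)
  )
  planted <- tibble::tibble(chrom = "chr1", start = 4900, end = 5100,
                            condition = "LIF+")
  arr <- simulate_e4c_arrays(probes, planted, cfg)
  r <- compute_probe_ratios(arr, pseudocount = 0)
  lifp <- r[r$condition == "LIF+", ]
  expect_equal(lifp$log2_ratio[lifp$probe_id == "p2"], c(3, 3))
  expect_equal(lifp$log2_ratio[lifp$probe_id != "p2"], rep(0, 4))
  # other conditions stay at background
  expect_equal(r$log2_ratio[r$condition == "NPC"], rep(0, 6))
  expect_true(all(arr$planted == (arr$probe_id == "p2" &
                                    arr$condition == "LIF+")))
})

test_that("replicates are distinct but share planted structure; seeds reproduce", {
  cfg <- tiny_synth_config(noise_sd = 0.5)
  probes <- tibble::tibble(probe_id = sprintf("p%02d", 1:50), chrom = "chr1",
                           start = (1:50) * 1000, end = (1:50) * 1000 + 60)
  planted <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000,
                            condition = "LIF+")
  a1 <- simulate_e4c_arrays(probes, planted, cfg)
  a2 <- simulate_e4c_arrays(probes, planted, cfg)
  expect_identical(a1, a2)
  r1 <- a1[a1$condition == "LIF+" & a1$replicate == 1, ]
  r2 <- a1[a1$condition == "LIF+" & a1$replicate == 2, ]
  expect_false(identical(r1$e4c, r2$e4c))
  expect_identical(r1$planted, r2$planted)
})

test_that("noiseless expression is linear in copies with a background floor", {
  cfg <- tiny_synth_config(noise_sd = 0, spike_noise_sd = 0, expr_gain = 10)
  genes <- tibble::tibble(gene_id = c("g1", "g2"))
  sim <- simulate_expression(genes, spikes = c(0, 5, 50), config = cfg)
  sp <- sim$intensities[sim$intensities$type == "spike" &
                          sim$intensities$condition == "NPC", ]
  expect_equal(sp$intensity[sp$known_copies == 5], 50)
  expect_equal(sp$intensity[sp$known_copies == 50], 500)
  # zero-dose spike sits at the background floor, not zero
  expect_gt(sp$intensity[sp$known_copies == 0], 0)
  expect_lt(sp$intensity[sp$known_copies == 0], 1)
  g <- sim$intensities[sim$intensities$type == "gene", ]
  truth <- tidyr::pivot_longer(
    sim$truth[1:4], dplyr::starts_with("copies_"),
    names_to = "condition", values_to = "copies", names_prefix = "copies_"
  )
  m <- dplyr::inner_join(g, truth,
                         by = c(feature_id = "gene_id", "condition"))
  expect_equal(m$intensity, pmax(10 * m$copies, 0.1))
})

test_that("planted expression folds respect the configured minimum", {
  cfg <- tiny_synth_config(noise_sd = 0, spike_noise_sd = 0, expr_fold_planted = 5)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:30))
  sim <- simulate_expression(genes, planted_lifplus = c("g01", "g02"),
                             planted_shared = "g03", config = cfg)
  tr <- sim$truth
  lp <- tr[tr$planted_lifplus, ]
  expect_true(all(lp$`copies_LIF+` / lp$copies_NPC >= 5))
  expect_true(all(lp$`copies_LIF-` / lp$copies_NPC < 2))
  sh <- tr[tr$planted_shared, ]
  expect_true(all(sh$`copies_LIF-` / sh$copies_NPC >= 5))
  expect_error(simulate_expression(genes, spikes = numeric(), config = cfg),
               "spike")
  expect_error(simulate_expression(genes, planted_lifplus = "nope",
                                   config = cfg), "subset")
})

test_that("FISH signals stay inside their nucleus and forced association saturates", {
  cfg <- tiny_synth_config(n_nuclei = 40)
  fish <- simulate_fish(cfg, partners = "geneX", assoc_fraction = 1,
                        conditions = "LIF+")
  r <- sqrt(fish$x_um^2 + fish$y_um^2 + fish$z_um^2)
  expect_true(all(r <= fish$nucleus_diameter_um / 2 + 1e-9))
  af <- association_frequencies(fish, "bait", "geneX")
  expect_equal(af$frequencies$fraction, 1)
  # max pairwise distance bounded by the diameter
  d <- min_pair_distance(fish, "bait", "geneX")
  expect_true(all(d$distance_um <= max(fish$nucleus_diameter_um)))
  expect_error(simulate_fish(cfg, "g", diameter_um = 0.8), "micron")
})

test_that("chance proximity at assoc_fraction = 0 matches a Monte-Carlo oracle", {
  cfg <- tiny_synth_config(n_nuclei = 1500, nucleus_diameter_um = 10,
                           nucleus_diameter_sd_um = 0, seed = 77)
  fish <- simulate_fish(cfg, partners = "geneX", assoc_fraction = 0,
                        conditions = "LIF+")
  af <- association_frequencies(fish, "bait", "geneX")
  obs <- af$frequencies$fraction

  # oracle: direct sampling of the same geometry, plain arithmetic
  withr::local_seed(78)
  n <- 2e5
  pt <- function(n) {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2)) * (5 * runif(n)^(1 / 3))
  }
  a1 <- pt(n); a2 <- pt(n); b1 <- pt(n); b2 <- pt(n)
  dd <- function(p, q) sqrt(rowSums((p - q)^2))
  mind <- pmin(dd(a1, b1), dd(a1, b2), dd(a2, b1), dd(a2, b2))
  p0 <- mean(mind <= 0.5)
  se <- sqrt(p0 * (1 - p0) / cfg$n_nuclei + p0 * (1 - p0) / n)
  expect_lt(abs(obs - p0), 4 * se + 1e-6)
})

test_that("activity mode labels one active bait allele per nucleus", {
  cfg <- tiny_synth_config(n_nuclei = 30)
  fish <- simulate_fish(cfg, partners = "geneX", conditions = "LIF+",
                        activity = TRUE, active_assoc_fraction = 1,
                        inactive_assoc_fraction = 0)
  bait <- fish[fish$gene == "bait", ]
  per_nuc <- tapply(bait$allele_active, bait$nucleus_id, sum)
  expect_true(all(per_nuc == 1))
})
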