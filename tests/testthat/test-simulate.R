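test_that("default configuration reproduces the experimental design", {
  sim <- simulate_burial_experiment(sim_config(rng_seed = 5))
  expect_equal(nrow(sim$records), 59 * 3 * 7)
  expect_equal(nrow(sim$traits), 59)
  expect_equal(sum(sim$traits$invasion_status == "invasive"), 21)
  expect_equal(sum(sim$traits$invasion_status == "naturalized"), 38)
  expect_equal(ape::Ntip(sim$tree), 59)
  expect_true(all(sim$records$n_buried == 100))
  expect_setequal(unique(sim$records$years_since_burial), seq(1.5, 7.5, 1))
  # every generated record passes the full bag validation by construction
  expect_s3_class(sim$records, "bag_records")
  # tip depths normalised to 1
  d <- ape::node.depth.edgelength(sim$tree)[1:59]
  expect_equal(d, rep(1, 59), tolerance = 1e-9)
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulate_burial_experiment(sim_config(n_invasive = 4,
                                              n_naturalized = 6,
                                              rng_seed = 33))
  s2 <- simulate_burial_experiment(sim_config(n_invasive = 4,
                                              n_naturalized = 6,
                                              rng_seed = 33))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$species_truth, s2$species_truth)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  s3 <- simulate_burial_experiment(sim_config(n_invasive = 4,
                                              n_naturalized = 6,
                                              rng_seed = 34))
  expect_false(identical(s1$records, s3$records))
})

test_that("no two members of a triplet share a row, rows hold six bags", {
  sim <- simulate_burial_experiment(sim_config(rng_seed = 8))
  key <- paste(sim$records$species_id, sim$records$years_since_burial)
  shared <- tapply(sim$records$row_number, key,
                   function(r) anyDuplicated(r) > 0)
  expect_false(any(shared))
  expect_true(all(sim$records$row_sequence %in% 1:6))
  per_row <- table(sim$records$row_number)
  expect_true(all(per_row <= 6))
})

test_that("bag viability converges to its generating curve for large bags", {
  cfg <- sim_config(n_invasive = 3, n_naturalized = 3,
                    seeds_per_bag = 10000, rng_seed = 14)
  sim <- simulate_burial_experiment(cfg)
  obs <- compute_viability(sim$records) / 100
  # mean bag viability at each time matches the generating curve within 1%
  yr <- sim$records$years_since_burial
  expect_true(all(abs(tapply(obs, yr, mean) -
                        tapply(sim$bag_truth$p_viable, yr, mean)) < 0.01))
  # and per-bag deviations are at the binomial sampling scale
  expect_lt(max(abs(obs - sim$bag_truth$p_viable)), 0.03)
})

test_that("zero species variances collapse each group onto one curve", {
  cfg <- sim_config(n_invasive = 4, n_naturalized = 4, sd_phylo = 0,
                    sd_species = 0, sd_slope = 0, rng_seed = 3)
  sim <- simulate_burial_experiment(cfg)
  tr <- sim$species_truth
  for (g in c("invasive", "naturalized")) {
    expect_equal(stats::sd(tr$intercept[tr$invasion_status == g]), 0)
    expect_equal(stats::sd(tr$slope[tr$invasion_status == g]), 0)
  }
  expect_equal(unique(tr$slope[tr$invasion_status == "invasive"]), -0.80)
  expect_equal(unique(tr$slope[tr$invasion_status == "naturalized"]), -0.55)
})

test_that("lambda_true shapes the cross-species effect correlation", {
  set.seed(70)
  cfg0 <- sim_config(n_invasive = 6, n_naturalized = 6, lambda_true = 0,
                     sd_phylo = 1.5, sd_slope = 0)
  tree <- simulate_tree(cfg0)
  C <- phylo_correlation(tree)[tree$tip.label, tree$tip.label]
  off <- C; diag(off) <- NA
  close_pair <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  far_pair <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]

  redraw <- function(cfg, n = 300) {
    t(replicate(n, simulate_species_params(tree, cfg)$intercept_dev))
  }
  d0 <- redraw(cfg0)
  r0_close <- stats::cor(d0[, close_pair[1]], d0[, close_pair[2]])
  r0_far <- stats::cor(d0[, far_pair[1]], d0[, far_pair[2]])
  expect_lt(abs(r0_close), 0.25)
  expect_lt(abs(r0_far), 0.25)

  cfg9 <- sim_config(n_invasive = 6, n_naturalized = 6, lambda_true = 0.9,
                     sd_phylo = 1.5, sd_slope = 0)
  d9 <- redraw(cfg9)
  r9_close <- stats::cor(d9[, close_pair[1]], d9[, close_pair[2]])
  r9_far <- stats::cor(d9[, far_pair[1]], d9[, far_pair[2]])
  expect_gt(r9_close, r9_far)
  expect_gt(r9_close, 0.5 * max(off, na.rm = TRUE) * 0.9 - 0.2)
})

test_that("species truth records the generating curve and its P50", {
  sim <- simulate_burial_experiment(sim_config(n_invasive = 3,
                                               n_naturalized = 3,
                                               rng_seed = 44))
  tr <- sim$species_truth
  expect_equal(tr$p50_true, ifelse(tr$slope < 0, -tr$intercept / tr$slope, Inf))
  # the noise-free curve crosses 50% at p50_true
  at50 <- stats::plogis(tr$intercept + tr$slope * tr$p50_true)
  expect_equal(at50[is.finite(tr$p50_true)],
               rep(0.5, sum(is.finite(tr$p50_true))))
  # bag truth links every record to its generating probabilities
  expect_equal(nrow(sim$bag_truth), nrow(sim$records))
})

test_that("saturated logit gives near-total viability in every bag", {
  cfg <- sim_config(n_invasive = 2, n_naturalized = 2,
                    intercept_mean = c(invasive = 10, naturalized = 10),
                    slope_mean = c(invasive = 0, naturalized = 0),
                    sd_phylo = 0, sd_species = 0, sd_bag = 0, sd_slope = 0,
                    rng_seed = 2)
  sim <- simulate_burial_experiment(cfg)
  expect_true(all(compute_viability(sim$records) > 99))
})
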