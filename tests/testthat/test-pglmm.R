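# small synthetic dataset shared by the model tests
small_sim <- function(n_inv = 5, n_nat = 7, seed = 202, ...) {
  simulate_burial_experiment(sim_config(n_invasive = n_inv,
                                        n_naturalized = n_nat,
                                        rng_seed = seed, ...))
}

test_that("build_model assembles binomial responses and designs", {
  sim <- small_sim()
  corr <- phylo_correlation(sim$tree)
  m <- build_model(sim$records, sim$traits, corr,
                   model_spec("viability", "status"))
  expect_equal(length(m$y), 12 * 3 * 7)
  expect_identical(colnames(m$X),
                   c("(Intercept)", "time", "statusnaturalized",
                     "time:statusnaturalized"))
  expect_true(all(m$y <= m$n))
  expect_setequal(names(m$re),
                  c("phylogeny", "species_identity", "triplet",
                    "row_sequence", "row_number"))
  expect_equal(nlevels(m$re$triplet), 12 * 7)

  # germinability drops bags with zero viable seeds
  viable <- with(sim$records, n_germ_spont + n_germ_ga + n_viable_stained)
  g <- build_model(sim$records, sim$traits, corr,
                   model_spec("germinability", "status"))
  expect_equal(length(g$y), sum(viable > 0))
  expect_true(all(g$n >= 1))
})

test_that("build_model validates inputs", {
  sim <- small_sim()
  corr <- phylo_correlation(sim$tree)
  expect_error(build_model(sim$records, sim$traits[-1, ], corr),
               "without traits")
  expect_error(build_model(sim$records, sim$traits, corr[-1, -1],
                           model_spec("viability", "status")),
               "missing from correlation")
  one <- sim$records[sim$records$species_id == "sp001", ]
  expect_error(build_model(bag_records(one), sim$traits, corr,
                           model_spec("viability", "status",
                                      random = "phylogeny")),
               "single species")
  dead <- sim$records
  dead$n_dead <- dead$n_buried
  dead$n_germ_spont <- dead$n_germ_ga <- dead$n_viable_stained <- 0L
  expect_error(build_model(bag_records(dead), sim$traits, corr,
                           model_spec("viability", "status")),
               "quasi-separation")
})

test_that("retained-sample bookkeeping is exact and seed-reproducible", {
  sim <- small_sim(3, 3, seed = 7)
  corr <- phylo_correlation(sim$tree)
  m <- build_model(sim$records, sim$traits, corr,
                   model_spec("viability", NULL,
                              random = c("phylogeny", "species_identity")))
  for (cfg in list(c(1000, 100, 7), c(900, 150, 20), c(2000, 200, 2))) {
    post <- sample_posterior(m, chain_config(cfg[1], cfg[2], cfg[3], seed = 5))
    expect_equal(post$n_retained, floor((cfg[1] - cfg[2]) / cfg[3]))
    expect_equal(nrow(post$beta), post$n_retained)
  }
  p1 <- sample_posterior(m, chain_config(1500, 300, 3, seed = 42))
  p2 <- sample_posterior(m, chain_config(1500, 300, 3, seed = 42))
  expect_identical(p1$beta, p2$beta)
  expect_identical(p1$V, p2$V)
  p3 <- sample_posterior(m, chain_config(1500, 300, 3, seed = 43))
  expect_false(identical(p1$beta, p3$beta))
})

test_that("with variances pinned the posterior matches ML logistic regression", {
  # single species, no random terms, overdispersion off: the posterior under
  # a vague prior should sit on the ML fit of the same binomial GLM
  set.seed(31)
  t <- rep(seq(1.5, 7.5, by = 1), each = 3)
  pv <- stats::plogis(2 - 0.6 * t)
  y <- stats::rbinom(length(t), 100, pv)
  rec <- bag_records(do.call(rbind, lapply(seq_along(t), function(i)
    bag_row("solo", rep = (i - 1) %% 3 + 1, year = t[i],
            stained = y[i], row_number = i))))
  m <- build_model(rec, tiny_traits("solo"), NULL,
                   model_spec("viability", NULL, random = character(0),
                              ve = 0))
  post <- sample_posterior(m, chain_config(20000, 2000, 20, seed = 9))
  ml <- stats::glm(cbind(y, 100 - y) ~ t, family = stats::binomial())
  bhat <- colMeans(post$beta)
  bsd <- apply(post$beta, 2, stats::sd)
  expect_lt(abs(bhat[1] - stats::coef(ml)[1]), 2 * bsd[1])
  expect_lt(abs(bhat[2] - stats::coef(ml)[2]), 2 * bsd[2])
})

test_that("pagel_lambda implements the latent-scale variance ratio", {
  V <- cbind(phylogeny = c(2, 2), species_identity = c(1, 1))
  post <- posterior_stub(V, ve = 1)
  lam <- pagel_lambda(post)
  expect_equal(lam$mean, 2 / (2 + 1 + 1 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(lam$mean, 0.273, tolerance = 0.005)
  # numerator zero -> lambda zero
  V0 <- cbind(phylogeny = c(0, 0), species_identity = c(1, 1))
  expect_equal(pagel_lambda(posterior_stub(V0))$mean, 0)
  # V_phylo dominating -> lambda -> 1
  Vb <- cbind(phylogeny = c(1e9, 1e9), species_identity = c(1, 1))
  expect_gt(pagel_lambda(posterior_stub(Vb))$mean, 0.999)
  # denominator scope and link-variance options
  lam_sp <- pagel_lambda(post, include_link_variance = FALSE,
                         include_residual = FALSE,
                         denom_terms = "species_identity")
  expect_equal(lam_sp$mean, 2 / 3, tolerance = 1e-12)
  no_phy <- posterior_stub(cbind(species_identity = c(1, 1)))
  expect_error(pagel_lambda(no_phy), "no phylogeny")
})

test_that("summarize_effects flags significance by CI exclusion of zero", {
  set.seed(12)
  b <- cbind(pos = stats::rnorm(1000, 1, 0.5),
             sym = stats::rnorm(1000, 0, 1),
             allpos = stats::rexp(1000) + 0.01)
  post <- posterior_stub(cbind(phylogeny = rep(1, 1000)))
  post$beta <- b
  eff <- summarize_effects(post)
  expect_identical(eff$term, c("pos", "sym", "allpos"))
  expect_true(eff$significant[1])    # CI ~ [0.02, 1.98]
  expect_gt(eff$ci_lower[1], -0.15)
  expect_lt(abs(eff$ci_lower[1] - 0.02), 0.15)
  expect_false(eff$significant[2])
  expect_true(eff$significant[3])
  expect_true(all(eff$ci_lower <= eff$posterior_mean &
                    eff$posterior_mean <= eff$ci_upper))
})

test_that("prediction curves behave as inverse-logit pushforwards", {
  sim <- small_sim(4, 4, seed = 77)
  corr <- phylo_correlation(sim$tree)
  m <- build_model(sim$records, sim$traits, corr,
                   model_spec("viability", "status",
                              random = c("phylogeny", "species_identity")))
  post <- sample_posterior(m, chain_config(4000, 500, 5, seed = 2))

  # hand-crafted posteriors exercise the analytic cases
  flat <- post
  flat$beta <- matrix(rep(c(1.2, 0, 0, 0), each = 50), 50, 4,
                      dimnames = list(NULL, colnames(post$beta)))
  crv <- predict_curve(flat, m, times = 0:10)
  expect_equal(unique(round(crv$fit_pct, 9)),
               round(100 * stats::plogis(1.2), 9))

  dec <- post
  dec$beta <- matrix(rep(c(0, -1, 0, 0), each = 50), 50, 4,
                     dimnames = list(NULL, colnames(post$beta)))
  crv <- predict_curve(dec, m, times = 0:10)
  for (g in unique(crv$group))
    expect_true(all(diff(crv$fit_pct[crv$group == g]) < 0))
  expect_equal(crv$fit_pct[crv$time == 0][1], 50)  # logit zero at t = 0

  # real posterior: band contains fit, values within [0, 100], both groups
  crv <- predict_curve(post, m)
  expect_setequal(unique(crv$group), c("invasive", "naturalized"))
  expect_true(all(crv$lo_pct <= crv$fit_pct & crv$fit_pct <= crv$hi_pct))
  expect_true(all(crv$lo_pct >= 0 & crv$hi_pct <= 100))
  expect_warning(predict_curve(post, m, times = c(5, 12)), "extrapolate")
})

test_that("diagnostics are reported for every parameter", {
  sim <- small_sim(3, 3, seed = 13)
  corr <- phylo_correlation(sim$tree)
  m <- build_model(sim$records, sim$traits, corr,
                   model_spec("viability", NULL,
                              random = c("phylogeny", "species_identity")))
  post <- sample_posterior(m, chain_config(3000, 500, 5, seed = 1))
  d <- post$diagnostics
  expect_setequal(d$parameter,
                  c("(Intercept)", "time", "phylogeny", "species_identity"))
  expect_true(all(is.finite(d$rhat)))
  expect_true(all(d$ess > 0))
  expect_output(print(post), "retained samples")
})
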