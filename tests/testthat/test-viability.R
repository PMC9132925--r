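fates_df <- function(species, years, v_pct) {
  data.frame(species_id = species, replicate_id = 1L,
             years_since_burial = years, viability_pct = v_pct,
             germinability_pct = NA_real_, germination_pct = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("probit is the normal equivalent deviate with bag-size clamping", {
  expect_equal(probit(50), 0)
  expect_equal(probit(97.7), 2.0, tolerance = 0.005)
  expect_equal(probit(2.3), -2.0, tolerance = 0.005)
  expect_equal(probit(100), stats::qnorm(1 - 0.5 / 100))
  expect_equal(probit(0), stats::qnorm(0.5 / 100))
  expect_equal(probit(100, n = 400), stats::qnorm(1 - 0.5 / 400))
})

test_that("noiseless probit-linear data are recovered exactly (free mode)", {
  p <- seq(1.5, 7.5, by = 1)
  v_pct <- 100 * stats::pnorm(1.6449 - p / 2)
  fit <- fit_viability(fates_df("s", p, v_pct), k_i_mode = "free")
  expect_equal(fit$sigma, 2.0, tolerance = 1e-6)
  expect_equal(fit$k_i, 1.6449, tolerance = 1e-6)
  expect_equal(p50(fit), 2 * 1.6449, tolerance = 1e-6)
  expect_identical(fit$flag, "ok")
  expect_lt(fit$rss, 1e-12)
})

test_that("non-decreasing viability flags and propagates infinite P50", {
  p <- seq(1.5, 7.5, by = 1)
  fit <- fit_viability(fates_df("s", p, rep(99.5, 7)))
  expect_identical(fit$flag, "non_decreasing")
  expect_identical(p50(fit), Inf)
  # increasing viability likewise
  fit2 <- fit_viability(fates_df("s", p, 50 + 5 * p), k_i_mode = "free")
  expect_identical(fit2$flag, "non_decreasing")
})

test_that("percent-scale reading gives the closed-form P50", {
  # K_i = 100 %, sigma = 0.0742 yr/% -> P50 = 0.0742 * (100 - 50) = 3.71 yr
  p <- c(1.5, 2.5, 3.5)
  v_pct <- 100 - p / 0.0742
  fit <- fit_viability(fates_df("s", p, pmax(v_pct, 0)), k_i_mode = "free",
                       scale = "percent")
  expect_equal(fit$sigma, 0.0742, tolerance = 1e-6)
  expect_equal(p50(fit), 3.71, tolerance = 1e-6)
})

test_that("fixed-intercept modes honour their K_i", {
  p <- seq(1.5, 7.5, by = 1)
  v_pct <- 100 * stats::pnorm(2.0 - p / 2)
  fit <- fit_viability(fates_df("s", p, v_pct), k_i_mode = "fixed_measured",
                       pre_burial_viability = 100 * stats::pnorm(2))
  expect_equal(fit$k_i, 2.0, tolerance = 1e-9)
  expect_equal(fit$sigma, 2.0, tolerance = 1e-9)
  fit2 <- fit_viability(fates_df("s", p, v_pct))  # fixed_full default
  expect_equal(fit2$k_i, probit(100))
  expect_error(fit_viability(fates_df("s", p, v_pct),
                             k_i_mode = "fixed_measured"),
               "pre_burial_viability")
  expect_error(fit_viability(fates_df("s", c(1.5, 1.5, 1.5), c(90, 80, 70))),
               ">= 2 distinct times")
})

test_that("P50 is monotone increasing in sigma at fixed K_i", {
  sig <- c(0.5, 1, 2, 4, 8)
  p <- vapply(sig, function(s) p50_closed_form(2.0, s, "probit"), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("closed-form P50 equals bisection on the fitted line", {
  set.seed(99)
  for (i in 1:20) {
    k <- runif(1, 0.5, 3)
    sig <- runif(1, 0.5, 10)
    p <- seq(1.5, 7.5, by = 1)
    v_pct <- 100 * stats::pnorm(k - p / sig)
    fit <- fit_viability(fates_df("s", p, v_pct), k_i_mode = "free")
    # oracle: bisection for the probit-zero crossing of the fitted line
    f <- function(t) fit$k_i - t / fit$sigma
    lo <- 0; hi <- 100
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    expect_equal(p50(fit), (lo + hi) / 2, tolerance = 0.01)
  }
})

test_that("probit and percent scales agree on mid-range linear data", {
  # percent-linear decline staying within [20, 80] over the window
  p <- seq(1.5, 7.5, by = 1)
  v_pct <- 75 - 7 * (p - 1.5)   # 75% down to 33%
  f1 <- fit_viability(fates_df("s", p, v_pct), k_i_mode = "free",
                      scale = "percent")
  f2 <- fit_viability(fates_df("s", p, v_pct), k_i_mode = "free",
                      scale = "probit")
  expect_lt(abs(p50(f1) - p50(f2)) / p50(f1), 0.05)
})

test_that("fit_viability_all and group_p50 summarise per group", {
  p <- seq(1.5, 7.5, by = 1)
  mk <- function(s, k, sig) fates_df(s, p, 100 * stats::pnorm(k - p / sig))
  # curves chosen so probit values stay inside the 0.5%/99.5% clamp window
  fates <- rbind(mk("i1", 2, 2), mk("i2", 2, 3), mk("i3", 2, 4),
                 mk("n1", 2, 2.5), mk("n2", 99, 1e9))
  fates$viability_pct[fates$species_id == "n2"] <- 99.4  # non-decreasing
  traits <- tiny_traits(c("i1", "i2", "i3", "n1", "n2"),
                        c("invasive", "invasive", "invasive",
                          "naturalized", "naturalized"))
  fits <- fit_viability_all(fates, traits, k_i_mode = "free")
  gp <- group_p50(fits, species_traits(traits))
  inv <- gp[gp$group == "invasive", ]
  expect_equal(inv$central, 6, tolerance = 1e-6)        # median of {4,6,8}
  expect_equal(c(inv$range_low, inv$range_high), c(4, 8), tolerance = 1e-6)
  nat <- gp[gp$group == "naturalized", ]
  expect_equal(nat$central, 5, tolerance = 1e-6)        # single finite fit
  expect_equal(nat$range_low, nat$range_high)
  expect_equal(nat$n_infinite, 1L)
})
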