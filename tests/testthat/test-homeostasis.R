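test_that("homeostasis slope hits the static and plastic limits exactly", {
  x <- c(1, 10, 100, 1000)
  # constant particulate N:P: strictly homeostatic, slope 0
  f0 <- fit_homeostasis(x, rep(4, 4))
  expect_equal(f0$slope_inv_h, 0)
  expect_equal(f0$intercept_log_c, log10(4), tolerance = 1e-12)
  # particulate tracks dissolved one-for-one: slope 1, intercept 0
  f1 <- fit_homeostasis(x, x)
  expect_equal(f1$slope_inv_h, 1, tolerance = 1e-12)
  expect_equal(f1$intercept_log_c, 0, tolerance = 1e-12)

  expect_error(fit_homeostasis(rep(2, 5), c(1, 2, 3, 4, 5)), "degenerate")
  expect_error(fit_homeostasis(c(1, 2), c(1, 2)), ">= 3")
})

test_that("the homeostasis estimator is unbiased on the generating model", {
  # log10 y = b0 + b1 log10 x + e; OLS estimates both without bias
  slopes <- numeric(200); ints <- numeric(200)
  set.seed(99)
  for (i in 1:200) {
    lx <- rnorm(5000, 1.7, 0.6)
    ly <- 0.434 + 0.096 * lx + rnorm(5000, 0, 0.3)
    f <- fit_homeostasis(10^lx, 10^ly)
    slopes[i] <- f$slope_inv_h; ints[i] <- f$intercept_log_c
  }
  expect_lt(abs(mean(slopes) - 0.096), 0.005)
  expect_lt(abs(mean(ints) - 0.434), 0.005)
})

test_that("1/H is invariant to rescaling the dissolved ratios", {
  set.seed(4)
  x <- rlnorm(200, 3, 1); y <- 10^(0.4 + 0.1 * log10(x) + rnorm(200, 0, 0.2))
  f <- fit_homeostasis(x, y)
  fk <- fit_homeostasis(1000 * x, y)
  expect_equal(fk$slope_inv_h, f$slope_inv_h, tolerance = 1e-10)
  expect_equal(fk$intercept_log_c,
               f$intercept_log_c - f$slope_inv_h * log10(1000),
               tolerance = 1e-10)
})

test_that("TP-binned fits exclude the middle band and recover bin-specific slopes", {
  # empty bins warn and yield NULL
  rec0 <- data.frame(np_dissolved = rlnorm(20, 3), np_particulate = rlnorm(20, 1),
                     tp = rep(0.05, 20))
  warns <- character(0)
  out0 <- withCallingHandlers(
    fit_homeostasis_by_tp_bin(rec0),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  expect_null(out0$low_tp)
  expect_null(out0$high_tp)
  expect_length(warns, 2L)

  # records exactly at the low edge stay out of the low bin
  rec_edge <- data.frame(np_dissolved = rlnorm(30, 3),
                         np_particulate = rlnorm(30, 1),
                         tp = rep(0.025, 30))
  out_edge <- suppressWarnings(fit_homeostasis_by_tp_bin(rec_edge))
  expect_null(out_edge$low_tp)

  set.seed(12)
  mk <- function(n, slope, tp) {
    lx <- rnorm(n, 1.7, 0.6)
    data.frame(np_dissolved = 10^lx,
               np_particulate = 10^(0.4 + slope * lx + rnorm(n, 0, 0.25)),
               tp = tp)
  }
  rec <- rbind(mk(2000, 0.0, 0.01), mk(2000, -0.04, 0.2))
  out <- fit_homeostasis_by_tp_bin(rec)
  expect_lt(abs(out$low_tp$slope_inv_h - 0.0), 0.02)
  expect_lt(abs(out$high_tp$slope_inv_h - -0.04), 0.02)
  expect_equal(out$low_tp$n, 2000L)
})

test_that("per-site fits apply the strict eligibility rule and rank site slopes", {
  set.seed(20)
  # a site with exactly min_n pairs is ineligible (strict >)
  d100 <- data.frame(site_id = "X", np_dissolved = rlnorm(100, 3, 1),
                     np_particulate = rlnorm(100, 1, 0.3),
                     np_total = rlnorm(100, 2, 0.5))
  out <- per_site_homeostasis(d100, min_n = 100)
  expect_null(out$fits)
  expect_equal(out$ineligible$site_id, "X")

  # constant particulate ratio: slope 0, median equals the constant
  dconst <- data.frame(site_id = "C", np_dissolved = rlnorm(150, 3, 1),
                       np_particulate = 3, np_total = rlnorm(150, 2, 0.5))
  fc <- per_site_homeostasis(dconst, min_n = 100)$fits
  expect_equal(fc$inv_h, 0)
  expect_equal(fc$pnpp_median, 3)

  # 13 sites with assigned slopes spanning -1..0.3: estimated order matches
  true_slopes <- seq(-1, 0.3, length.out = 13)
  panel <- do.call(rbind, lapply(1:13, function(i) {
    lx <- rnorm(120, 1.7, 0.6)
    data.frame(site_id = sprintf("S%02d", i),
               np_dissolved = 10^lx,
               np_particulate = 10^(0.4 + true_slopes[i] * lx +
                                      rnorm(120, 0, 0.3)),
               np_total = 10^(1 + 0.5 * lx))
  }))
  fits <- per_site_homeostasis(panel, min_n = 100)$fits
  fits <- fits[order(fits$site_id), ]
  expect_gt(cor(true_slopes, fits$inv_h, method = "spearman"), 0.9)
})

test_that("discharge power law recovers exact and simulated exponents", {
  q <- c(1, 3, 10, 30, 100, 300, 1000, 3000, 1e4, 3e4, 1e5, 3e5)
  # static ratios: b vanishes to numerical precision
  f0 <- fit_power_law(q, rep(7, 12))
  expect_lt(abs(f0$b_exp), 1e-14)
  # exact power law: slope and coefficient recovered to numerical precision
  f1 <- fit_power_law(q, 2 * q, "dissolved")
  expect_equal(f1$b_exp, 1, tolerance = 1e-10)
  expect_equal(f1$a_coeff, 2, tolerance = 1e-10)
  # eligibility is strict: 10 pairs are not enough
  expect_error(fit_power_law(q[1:10], q[1:10]), "strictly more than")

  # unit change (L/s -> m3/s) leaves b untouched
  set.seed(6)
  qq <- rlnorm(60, 4, 1); np <- 5 * qq^-0.3 * rlnorm(60, 0, 0.2)
  expect_equal(fit_power_law(qq / 1000, np)$b_exp, fit_power_law(qq, np)$b_exp,
               tolerance = 1e-10)

  # simulation: b = -0.3, lognormal q, log-noise 0.2, n = 50, 200 seeds
  set.seed(77)
  bhat <- replicate(200, {
    qi <- rlnorm(50, 4, 1)
    npi <- 10^(0.7 - 0.3 * log10(qi) + rnorm(50, 0, 0.2))
    fit_power_law(qi, npi)$b_exp
  })
  expect_lt(abs(mean(bhat) + 0.3), 0.03)
})

test_that("power-law exponents regress on land use with exact degenerate limits", {
  landuse <- data.frame(site_id = sprintf("S%02d", 1:15),
                        p_cro = seq(0, 0.6, length.out = 15), p_hay = 0.05,
                        p_urb = 0.1, p_for = seq(0.25, 0, length.out = 15))
  base <- data.frame(site_id = landuse$site_id, a_coeff = 1, b_se = 0.1,
                     p_value = 0.5, n = 20, ratio_kind = "total")
  # identical exponents: zero slope everywhere
  f0 <- cbind(base, b_exp = 0.2)
  out0 <- regress_b_on_landuse(f0, landuse)
  expect_equal(out0$slope[out0$predictor == "pct_agric"], 0, tolerance = 1e-12)
  # exponents exactly linear in % agriculture: slope recovered, p ~ 0
  pct_ag <- 100 * (landuse$p_cro + landuse$p_hay)
  f1 <- cbind(base, b_exp = -0.1 + 0.004 * pct_ag)
  out1 <- regress_b_on_landuse(f1, landuse)
  expect_equal(out1$slope[out1$predictor == "pct_agric"], 0.004,
               tolerance = 1e-10)
  expect_lt(out1$p_value[out1$predictor == "pct_agric"], 1e-10)
  expect_true(out1$degenerate[out1$predictor == "pct_urban"])

  expect_error(regress_b_on_landuse(f1[1:5, ], landuse), ">= 10")
})

test_that("site-level power-law fitting reports ineligible sites", {
  set.seed(30)
  d <- rbind(
    data.frame(site_id = "A", discharge_q = rlnorm(15, 4, 1),
               np_total = rlnorm(15, 3, 0.5)),
    data.frame(site_id = "B", discharge_q = rlnorm(8, 4, 1),
               np_total = rlnorm(8, 3, 0.5))
  )
  out <- fit_power_law_by_site(d, "total")
  expect_equal(out$fits$site_id, "A")
  expect_equal(out$ineligible$site_id, "B")
  expect_equal(out$ineligible$n_pairs, 8L)
})
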