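test_that("predictor standardization is an exact z-score with n-1 scaling", {
  tab <- data.frame(log10_q = c(0, 1), p_cro = c(0.2, 0.2))
  expect_warning(standardize_predictors(tab), "zero variance")
  out <- suppressWarnings(standardize_predictors(tab))
  expect_equal(out$log10_q, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_false("p_cro" %in% names(out))
  # idempotence on an already-standardized column
  z <- data.frame(log10_q = as.numeric(scale(rnorm(20))))
  expect_equal(standardize_predictors(z)$log10_q, z$log10_q, tolerance = 1e-12)
})

simulate_panel <- function(n_sites, obs, beta = c(q = 0.1, cro = 0.8,
                                                  hay = 0.2, forr = -0.7,
                                                  urb = 0.3),
                           site_sd = 0.3, resid_sd = 0.2, seed = 1) {
  set.seed(seed)
  lu <- data.frame(site_id = sprintf("S%03d", 1:n_sites),
                   p_cro = runif(n_sites, 0, 0.6),
                   p_hay = runif(n_sites, 0, 0.3),
                   p_for = runif(n_sites, 0, 0.8),
                   p_urb = runif(n_sites, 0, 0.4))
  idx <- rep(1:n_sites, each = obs)
  b0 <- rnorm(n_sites, 0, site_sd)
  lq <- rnorm(n_sites * obs, 2, 1)
  ly <- -0.5 + beta["q"] * lq + beta["cro"] * lu$p_cro[idx] +
    beta["hay"] * lu$p_hay[idx] + beta["forr"] * lu$p_for[idx] +
    beta["urb"] * lu$p_urb[idx] + b0[idx] + rnorm(n_sites * obs, 0, resid_sd)
  data.frame(site_id = lu$site_id[idx], discharge_q = 10^lq,
             lu[idx, -1], din = 10^ly, row.names = NULL)
}

test_that("the mixed model recovers simulated land-use effects", {
  tab <- simulate_panel(200, 20, seed = 42)
  fit <- fit_landuse_model(tab, "din")
  cc <- fit$coefficients
  g <- function(t) cc$estimate[cc$term == t]
  expect_lt(abs(g("p_cro") - 0.8), 0.1)
  expect_lt(abs(g("p_for") + 0.7), 0.1)
  expect_lt(abs(g("log10_q") - 0.1), 0.02)
  expect_equal(fit$n_obs, 4000L)
  expect_equal(fit$n_sites, 200L)
  expect_true(fit$r2_marginal <= fit$r2_conditional)
  # standardized coefficient identity: raw x sd(predictor)
  d <- tab[!is.na(tab$din) & tab$din > 0, ]
  d$log10_q <- log10(d$discharge_q)
  for (v in c("log10_q", "p_cro", "p_hay", "p_for", "p_urb")) {
    expect_equal(cc$std_estimate[cc$term == v],
                 cc$estimate[cc$term == v] * sd(d[[v]]), tolerance = 1e-8)
  }
})

test_that("Wald intervals cover null land-use effects at near-nominal rates", {
  covered <- 0L; total <- 0L
  for (seed in 1:40) {
    tab <- simulate_panel(60, 8, beta = c(q = 0.1, cro = 0, hay = 0,
                                          forr = 0, urb = 0), seed = seed)
    cc <- fit_landuse_model(tab, "din")$coefficients
    lud <- cc[cc$term %in% c("p_cro", "p_hay", "p_for", "p_urb"), ]
    covered <- covered + sum(lud$ci_lo <= 0 & lud$ci_hi >= 0)
    total <- total + nrow(lud)
  }
  expect_gte(covered / total, 0.90)
})

test_that("with one observation per site the fit collapses to OLS", {
  tab <- simulate_panel(150, 1, seed = 3)
  f <- suppressMessages(fit_landuse_model(tab, "din"))
  expect_true(f$singular)
  d <- tab; d$log10_q <- log10(d$discharge_q); d$.y <- log10(d$din)
  ols <- lm(.y ~ log10_q + p_cro + p_hay + p_for + p_urb, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("mixed-model R2 matches its variance decomposition", {
  # var(fixed) = 1, var(site) = 1, var(resid) = 2 -> (0.25, 0.50)
  set.seed(9)
  n_sites <- 400; obs <- 10
  idx <- rep(1:n_sites, each = obs)
  x <- rnorm(n_sites * obs)
  y <- x + rnorm(n_sites, 0, 1)[idx] + rnorm(n_sites * obs, 0, sqrt(2))
  d <- data.frame(y = y, x = x, site_id = sprintf("S%03d", idx))
  fit <- lme4::lmer(y ~ x + (1 | site_id), data = d, REML = TRUE)
  r2 <- r2_mixed(fit)
  expect_equal(unname(r2["marginal"]), 0.25, tolerance = 0.05)
  expect_equal(unname(r2["conditional"]), 0.50, tolerance = 0.05)

  # no fixed effects beyond an intercept: marginal R2 ~ 0
  fit0 <- lme4::lmer(y ~ 1 + (1 | site_id), data = d, REML = TRUE)
  expect_lt(r2_mixed(fit0)["marginal"], 1e-10)

  # no site variance: marginal equals conditional
  y2 <- x + rnorm(n_sites * obs, 0, sqrt(2))
  d2 <- data.frame(y = y2, x = x, site_id = d$site_id)
  fit2 <- suppressMessages(lme4::lmer(y2 ~ x + (1 | site_id), data = d2))
  r22 <- r2_mixed(fit2)
  expect_lt(abs(r22[["marginal"]] - r22[["conditional"]]), 0.02)
})

test_that("percent-particulate model handles constants and excludes zero totals", {
  tab <- simulate_panel(40, 10, seed = 7)
  tab$tn <- tab$din * 2
  tab$pn <- 0.5 * tab$tn
  f <- suppressMessages(fraction_particulate_model(tab, "N"))
  cc <- f$coefficients
  expect_equal(cc$estimate[cc$term == "(Intercept)"], 50, tolerance = 1e-6)
  for (t in c("pct_cro", "pct_hay", "pct_for", "pct_urb")) {
    expect_equal(cc$estimate[cc$term == t], 0, tolerance = 1e-6)
  }
  # a zero total cannot define a percentage
  tab$tn[1] <- 0
  f2 <- suppressMessages(fraction_particulate_model(tab, "N"))
  expect_equal(f2$n_excluded, 1L)
  expect_equal(f2$n_obs, nrow(tab) - 1L)
})

test_that("percent-particulate model recovers a small simulated decline", {
  set.seed(15)
  n_sites <- 300; obs <- 30
  idx <- rep(1:n_sites, each = obs)
  pcro <- runif(n_sites, 0, 0.8)
  pct <- 60 - 0.02 * (100 * pcro[idx]) + rnorm(n_sites, 0, 0.5)[idx] +
    rnorm(n_sites * obs, 0, 2)
  tab <- data.frame(
    site_id = sprintf("S%03d", idx), discharge_q = 10^rnorm(n_sites * obs, 2, 1),
    p_cro = pcro[idx], p_hay = runif(n_sites, 0, 0.2)[idx],
    p_for = runif(n_sites, 0, 0.2)[idx],
    p_urb = runif(n_sites, 0, 0.3)[idx],
    tn = 1, pn = pct / 100)
  f <- fraction_particulate_model(tab, "N")
  cc <- f$coefficients
  expect_lt(abs(cc$estimate[cc$term == "pct_cro"] - -0.02), 0.01)
})
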