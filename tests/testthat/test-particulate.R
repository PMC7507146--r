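test_that("DIN sums its components, flagging partial sums", {
  out <- compute_din(c(0, 0.01, NA, NA), c(0, 0.02, 0.02, NA),
                     c(0, 0.50, 0.50, NA))
  expect_equal(out$din, c(0, 0.53, 0.52, NA))
  expect_equal(out$partial, c(FALSE, FALSE, TRUE, FALSE))
  strict <- compute_din(NA, 0.02, 0.50, strict = TRUE)
  expect_true(is.na(strict$din))
  expect_error(compute_din(-0.1, 0, 0), "negative")
})

test_that("dissolved-organic proportions are the organic share of the residual", {
  paired <- data.frame(
    tn = c(1.0, 1.0, rep(1.0, 10)),
    tdn = c(0.8, 1.2, rep(0.7, 10)),
    din = c(0.6, 0.6, rep(0.5, 10))
  )
  d <- estimate_dom_proportions(paired, "N")
  expect_equal(d$proportions[1], 0.5)      # (0.8-0.6)/(1.0-0.6)
  expect_equal(d$n_excluded, 1L)           # proportion 1.5 excluded
  expect_equal(d$n_source_pairs, 11L)

  expect_error(estimate_dom_proportions(paired[1:5, ], "N"),
               "insufficient pairs")
  expect_error(estimate_dom_proportions(data.frame(tn = 1), "P"), "lacks")
})

test_that("proportions estimated from Beta-generated pairs recover the Beta mean", {
  set.seed(123)
  n <- 1000
  p_true <- rbeta(n, 2, 5)                  # mean 2/7
  din <- runif(n, 0.1, 1)
  resid <- runif(n, 0.1, 2)
  paired <- data.frame(tn = din + resid, tdn = din + p_true * resid, din = din)
  d <- estimate_dom_proportions(paired, "N")
  expect_equal(d$n_source_pairs, n)
  expect_lt(abs(mean(d$proportions) - 2 / 7), 0.03)
})

test_that("bootstrap particulate honors degenerate and two-point supports", {
  set.seed(1)
  expect_equal(bootstrap_particulate(0, dom_dist(c(0.3, 0.5))), 0)
  # point mass: IQR collapses, result is exact
  expect_equal(bootstrap_particulate(1.0, dom_dist(0.4)), 0.6)
  expect_error(bootstrap_particulate(-0.1, dom_dist(0.4)), "negative residual")

  # candidate support brute-forced: residual * (1 - p), p in {0.2, 0.4}
  draws <- replicate(500, bootstrap_particulate(1.0, dom_dist(c(0.2, 0.4)),
                                                n_boot = 1000))
  expect_true(all(draws >= 0.6 & draws <= 0.8))
})

test_that("particulate draws stay inside the candidate envelope on synthetic truth", {
  sc <- small_config(seed = 31L)
  out <- derive_synthetic(sc)
  d <- out$derived$records
  dist_n <- estimate_dom_proportions(
    within(d, din <- compute_din(nh3n, nh4n, no3no2n)$din), "N")
  env_lo <- (d$tn - d$din) * (1 - max(dist_n$proportions))
  env_hi <- (d$tn - d$din) * (1 - min(dist_n$proportions))
  ok <- !is.na(d$pn) & (d$tn - d$din) >= 0
  expect_true(all(d$pn[ok] >= env_lo[ok] - 1e-12))
  expect_true(all(d$pn[ok] <= env_hi[ok] + 1e-12))
})

test_that("mass of the proportion distribution near one raises particulate missingness", {
  sc <- small_config(seed = 32L)
  out <- derive_synthetic(sc)
  d <- out$derived$records
  resid <- pmax(d$tn - d$din, 0)
  resid <- resid[!is.na(resid)][1:50]
  count_missing <- function(dist) {
    n_na <- 0L
    for (i in seq_along(resid)) {
      set.seed(1000 + i)
      if (is.na(bootstrap_particulate(resid[i], dist, 300))) n_na <- n_na + 1L
    }
    n_na
  }
  low_mass <- dom_dist(rbeta(500, 2, 5))
  set.seed(99); high_mass <- dom_dist(c(rbeta(400, 2, 5), rep(1, 100)))
  expect_lte(count_missing(low_mass), count_missing(high_mass))
})

test_that("the consistency filter removes DIN/DIP violations with exact fractions", {
  toy <- data.frame(
    tn = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    din = c(0.5, 1.2, 0.4, 1.5, 0.3, 0.2, 0.9, 0.1, 0.6, 0.7),
    tp = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    dip = c(0.05, 0.02, 0.03, 0.04, 0.12, 0.01, 0.02, 0.05, 0.06, 0.03)
  )
  out <- filter_inconsistent(toy)
  expect_equal(nrow(out$records), 7L)
  expect_equal(out$report$fraction[out$report$analyte == "DIN"], 0.2)
  expect_equal(out$report$fraction[out$report$analyte == "DIP"], 0.1)
  expect_equal(out$report$n_removed, c(2L, 1L))
  # boundary: equality is not a violation
  eq <- filter_inconsistent(data.frame(tn = 1, din = 1, tp = 0.1, dip = 0.1))
  expect_equal(nrow(eq$records), 1L)
})

test_that("dissolved-organic share shows no land-use trend when none exists, and an exact one when it does", {
  landuse <- data.frame(site_id = sprintf("S%02d", 1:20),
                        p_cro = seq(0, 0.5, length.out = 20),
                        p_hay = 0.1, p_urb = seq(0.4, 0, length.out = 20),
                        p_for = 0.2)
  # constant proportions: degenerate response, slope 0, p = 1
  flat <- data.frame(site_id = landuse$site_id, proportion = 0.3)
  out <- check_dom_vs_landuse(flat, landuse)
  expect_equal(out$slope[out$predictor == "p_cro"], 0)
  expect_equal(out$p_value[out$predictor == "p_cro"], 1)
  expect_true(out$degenerate[out$predictor == "p_hay"])  # constant predictor

  # exactly linear in p_urb: slope recovered, p ~ 0
  lin <- data.frame(site_id = landuse$site_id,
                    proportion = 0.1 + 0.5 * landuse$p_urb)
  out2 <- check_dom_vs_landuse(lin, landuse)
  expect_equal(out2$slope[out2$predictor == "p_urb"], 0.5, tolerance = 1e-10)
  expect_lt(out2$p_value[out2$predictor == "p_urb"], 1e-12)
})

test_that("the derivation is reproducible and order-invariant under a fixed seed", {
  sc <- small_config(seed = 33L)
  out1 <- derive_synthetic(sc)
  out2 <- derive_synthetic(sc)
  expect_identical(out1$derived$records, out2$derived$records)

  # per-record substreams: permuting rows permutes, never changes, draws
  lu <- generate_landscape(sc)
  gen <- generate_samples(lu, sc)
  tab <- join_site_data(gen$records, lu)$table
  dist_n <- dom_dist(rbeta(200, 2, 5)); dist_p <- dom_dist(rbeta(200, 2, 5))
  a <- derive_nutrients(tab, dist_n, dist_p, n_boot = 200, seed = 4L)
  perm <- sample(nrow(tab))
  b <- derive_nutrients(tab[perm, ], dist_n, dist_p, n_boot = 200, seed = 4L)
  key <- function(d) paste(d$site_id, d$date)
  expect_equal(a$records$pn[match(key(b$records), key(a$records))],
               b$records$pn)
})
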