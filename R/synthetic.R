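# Synthetic multi-site stream chemistry generator with full ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# watershed land-use compositions drawn from a Dirichlet; lognormal
# discharge; log10 dissolved inorganic N and P following linear land-use +
# discharge models with site-level random intercepts; Beta-distributed
# dissolved-organic shares of the total-minus-inorganic residual; a
# controllable true coupling (1/H) between particulate and dissolved molar
# N:P; and injected "less-than"/"estimated" qualifiers. Mass closure
# TN = DIN + DON + PN and TP = DIP + DOP + PP holds exactly on every record.
#
# Generation order is fixed (dissolved -> DON share -> particulate N ->
# particulate ratio -> PP) so that the true 1/H is imposed on PN:PP versus
# DIN:DIP exactly as the homeostasis stage later measures it.

#' Configuration for the synthetic stream-panel generator
#'
#' Defaults are keyed to the effect sizes and noise scales typical of
#' continental stream monitoring panels: land-use and discharge effects on
#' log10 concentrations at the magnitudes reported for U.S. watershed
#' mixed-model fits, a particulate-dissolved N:P coupling with slope 0.096
#' and intercept 0.434 in log10 space, Beta(2, 5) dissolved-organic shares,
#' and a widely dispersed land-use composition (many near-end-member
#' watersheds), as monitoring networks deliberately sample land-use
#' extremes.
#'
#' @param n_sites Number of monitoring sites.
#' @param obs_per_site Samples per site.
#' @param landuse_concentration Dirichlet parameters over (crop, hay, urban,
#'   forest, other).
#' @param discharge_logmean,discharge_logsd Mean and sd of log10 discharge
#'   (L/s).
#' @param area_logmean,area_logsd Mean and sd of log10 watershed area (km2).
#' @param effects Named list of coefficient vectors for `din`, `dip`, `pn`;
#'   each has `intercept`, `q`, `p_cro`, `p_hay`, `p_for`, `p_urb` (log10
#'   mg/L per unit proportion, per log10 L/s for `q`).
#' @param site_sd,resid_sd Site-intercept and residual sd, log10 mg/L.
#' @param dom_beta_n,dom_beta_p Beta shape pairs for the DON and DOP shares.
#' @param true_inv_h,true_log_c,np_resid_sd Homeostasis truth: slope,
#'   intercept and residual sd of log10 PN:PP on log10 DIN:DIP.
#' @param din_split Fractions of DIN reported as (nh3n, nh4n, no3no2n).
#' @param detection_limits Named detection limits, mg/L; values below the
#'   limit are reported as "less than" the limit. Defaults follow typical
#'   published laboratory reporting limits for stream nutrients (ammonia
#'   0.01, nitrate+nitrite 0.04, orthophosphate-P 0.004 mg/L), under which
#'   the minor ammonia fractions are censored often and the dominant
#'   nitrate fraction rarely, as in real monitoring records; totals are
#'   uncensored.
#' @param censor_estimated_rate Fraction of remaining values flagged
#'   "estimated".
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_sites = 200L, obs_per_site = 20L,
    landuse_concentration = c(crop = 0.40, hay = 0.40, urban = 0.35,
                              forest = 0.60, other = 0.75),
    discharge_logmean = 2.0, discharge_logsd = 1.0,
    area_logmean = 2.85, area_logsd = 0.8,
    effects = list(
      din = c(intercept = -1.092, q = 0.162, p_cro = 1.183, p_hay = 1.205,
              p_for = -0.469, p_urb = 1.025),
      dip = c(intercept = -1.515, q = 0.003, p_cro = 0.399, p_hay = 0.346,
              p_for = -0.983, p_urb = 0.332),
      pn  = c(intercept = -1.561, q = 0.088, p_cro = 0.226, p_hay = 0.060,
              p_for = -0.979, p_urb = 0.111)
    ),
    site_sd = 0.3, resid_sd = 0.2,
    dom_beta_n = c(2, 5), dom_beta_p = c(2, 5),
    true_inv_h = 0.096, true_log_c = 0.434, np_resid_sd = 0.3,
    din_split = c(nh3n = 0.02, nh4n = 0.08, no3no2n = 0.90),
    detection_limits = c(nh3n = 0.01, nh4n = 0.01, no3no2n = 0.04,
                         dip = 0.004, tn = 0, tp = 0),
    censor_estimated_rate = 0.05,
    seed = 1L) {
  stopifnot(
    n_sites >= 1, obs_per_site >= 1,
    all(landuse_concentration > 0),
    site_sd >= 0, resid_sd >= 0, np_resid_sd >= 0,
    all(dom_beta_n > 0), all(dom_beta_p > 0),
    censor_estimated_rate >= 0, censor_estimated_rate <= 1,
    abs(sum(din_split) - 1) < 1e-9,
    all(detection_limits >= 0)
  )
  structure(as.list(environment()), class = "synthetic_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate watershed land-use profiles
#'
#' Site land-use proportions are drawn from the configured Dirichlet;
#' watershed areas are lognormal.
#'
#' @param config A [synthetic_config()].
#' @return Land-use data frame (`site_id`, `p_cro`, `p_hay`, `p_urb`,
#'   `p_for`, `p_other`, `watershed_area_km2`).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "landscape"))
  n <- config$n_sites
  p <- rdirichlet(n, config$landuse_concentration)
  data.frame(
    site_id = sprintf("S%04d", seq_len(n)),
    p_cro = p[, 1], p_hay = p[, 2], p_urb = p[, 3], p_for = p[, 4],
    p_other = p[, 5],
    watershed_area_km2 = 10^stats::rnorm(n, config$area_logmean,
                                         config$area_logsd),
    stringsAsFactors = FALSE
  )
}

#' Generate a sample panel with full ground truth
#'
#' For each record: log10 discharge is drawn; log10 DIN, DIP and PN follow
#' their linear models (land-use effects + discharge effect + site intercept
#' + residual); the DON and DOP shares of the residual are Beta draws;
#' the particulate molar ratio follows `log10(PN:PP) = true_log_c +
#' true_inv_h * log10(DIN:DIP) + N(0, np_resid_sd)` and PP is solved from PN
#' and that ratio; DON, DOP, TN, TP, TDN, TDP follow by exact mass closure.
#' All concentrations are strictly positive by construction.
#'
#' @param profiles Land-use profiles from [generate_landscape()].
#' @param config A [synthetic_config()].
#' @return List: `records` (analysis-table layout, all qualifiers
#'   `"measured"`), `truth` (per-record true components and per-site
#'   intercepts, plus the config).
#' @export
generate_samples <- function(profiles, config) {
  stopifnot(inherits(config, "synthetic_config"), nrow(profiles) >= 1)
  set.seed(substream_seed(config$seed, "samples"))
  ns <- nrow(profiles); m <- config$obs_per_site
  n <- ns * m
  idx <- rep(seq_len(ns), each = m)

  site_int <- list(
    din = stats::rnorm(ns, 0, config$site_sd),
    dip = stats::rnorm(ns, 0, config$site_sd),
    pn  = stats::rnorm(ns, 0, config$site_sd)
  )
  log10_q <- stats::rnorm(n, config$discharge_logmean, config$discharge_logsd)

  lin <- function(resp) {
    b <- config$effects[[resp]]
    b[["intercept"]] + b[["q"]] * log10_q +
      b[["p_cro"]] * profiles$p_cro[idx] + b[["p_hay"]] * profiles$p_hay[idx] +
      b[["p_for"]] * profiles$p_for[idx] + b[["p_urb"]] * profiles$p_urb[idx] +
      site_int[[resp]][idx] + stats::rnorm(n, 0, config$resid_sd)
  }
  din <- 10^lin("din")
  dip <- 10^lin("dip")
  pn <- 10^lin("pn")

  np_diss <- mass_to_molar_np(din, dip)
  np_part <- 10^(config$true_log_c + config$true_inv_h * log10(np_diss) +
                   stats::rnorm(n, 0, config$np_resid_sd))
  pp <- (pn / MOLAR_MASS_N) * MOLAR_MASS_P / np_part

  p_don <- stats::rbeta(n, config$dom_beta_n[1], config$dom_beta_n[2])
  p_dop <- stats::rbeta(n, config$dom_beta_p[1], config$dom_beta_p[2])
  don <- pn * p_don / (1 - p_don)
  dop <- pp * p_dop / (1 - p_dop)

  tn <- din + don + pn
  tp <- dip + dop + pp
  tdn <- din + don
  tdp <- dip + dop

  dates <- as.Date("2004-01-01") + unlist(lapply(seq_len(ns), function(s)
    sort(sample.int(3500L, m))))
  records <- data.frame(
    site_id = profiles$site_id[idx],
    date = dates,
    discharge_q = 10^log10_q,
    nh3n = config$din_split[["nh3n"]] * din,
    nh4n = config$din_split[["nh4n"]] * din,
    no3no2n = config$din_split[["no3no2n"]] * din,
    dip = dip, tn = tn, tp = tp, tdn = tdn, tdp = tdp,
    stringsAsFactors = FALSE
  )
  for (a in c("nh3n", "nh4n", "no3no2n", "dip", "tn", "tp", "tdn", "tdp")) {
    records[[paste0(a, "_qual")]] <- "measured"
  }
  truth <- list(
    site_intercepts = data.frame(site_id = profiles$site_id,
                                 din = site_int$din, dip = site_int$dip,
                                 pn = site_int$pn),
    records = data.frame(
      site_id = records$site_id, date = records$date, log10_q = log10_q,
      din = din, don = don, pn = pn, dip = dip, dop = dop, pp = pp,
      tn = tn, tp = tp, p_don = p_don, p_dop = p_dop,
      np_dissolved = np_diss, np_particulate = np_part
    ),
    config = config
  )
  list(records = records, truth = truth)
}

#' Inject "less-than" and "estimated" qualifiers
#'
#' Values below their analyte's detection limit are replaced by the limit
#' with qualifier `less_than`; a random fraction of the remaining values is
#' flagged `estimated` (value unchanged). True values stay available in the
#' generator's truth table.
#'
#' @param records Records from [generate_samples()].
#' @param config A [synthetic_config()].
#' @return The records with qualifiers set and less-than values masked at
#'   the reporting limit.
#' @export
inject_censoring <- function(records, config) {
  stopifnot(inherits(config, "synthetic_config"))
  for (a in names(config$detection_limits)) {
    if (!a %in% names(records)) next
    lim <- config$detection_limits[[a]]
    qcol <- paste0(a, "_qual")
    set.seed(substream_seed(config$seed, "censoring-inject", a))
    if (lim > 0) {
      below <- !is.na(records[[a]]) & records[[a]] < lim
      records[[a]][below] <- lim
      records[[qcol]][below] <- "less_than"
    }
    if (config$censor_estimated_rate > 0) {
      meas <- which(records[[qcol]] == "measured" & !is.na(records[[a]]))
      est <- meas[stats::runif(length(meas)) < config$censor_estimated_rate]
      records[[qcol]][est] <- "estimated"
    }
  }
  records
}

#' Write sample and land-use tables in the ingest CSV dialect
#'
#' Numeric values are written with 17 significant digits so a read-back
#' reproduces them bit-exactly; less-than records are encoded as
#' `"<limit"` strings with the `_qual` column carried alongside.
#'
#' @param records,landuse Tables from the generator.
#' @param sample_path,landuse_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_synthetic_tables <- function(records, landuse, sample_path, landuse_path) {
  out <- records
  out$date <- as.character(out$date)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, sample_path, row.names = FALSE, quote = FALSE)
  lu <- data.frame(
    site_id = landuse$site_id,
    pct_crop = 100 * landuse$p_cro, pct_hay = 100 * landuse$p_hay,
    pct_urban_low = 100 * landuse$p_urb, pct_urban_med = 0,
    pct_urban_high = 0,
    pct_forest_decid = 100 * landuse$p_for, pct_forest_mixed = 0,
    pct_forest_conif = 0,
    watershed_area_km2 = landuse$watershed_area_km2
  )
  for (col in names(lu)) {
    if (is.numeric(lu[[col]])) {
      lu[[col]] <- formatC(lu[[col]], digits = 17, format = "g")
    }
  }
  utils::write.csv(lu, landuse_path, row.names = FALSE, quote = FALSE)
  invisible(c(sample_path, landuse_path))
}
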