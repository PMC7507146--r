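# Stoichiometric homeostasis and concentration-discharge power laws.
#
# The homeostasis coefficient H measures how strongly particulate N:P is
# regulated against variation in dissolved inorganic N:P: 1/H is the slope
# of ordinary least squares of log10(particulate N:P) on log10(dissolved
# N:P). 1/H near 0 means static (chemostatic) particle stoichiometry; 1/H
# near 1 means particles track the dissolved pool proportionally
# (plastic, Redfield-like assimilation). The discharge dependence of N:P is
# summarised per site by the power law N:P = a * Q^b, fit as an OLS in
# log10-log10 space; b = 0 indicates static ratios across flows.

#' Fit the homeostasis regression (1/H)
#'
#' OLS of `log10(particulate N:P)` on `log10(dissolved N:P)`. The slope is
#' 1/H, the intercept is log10(c). Plain OLS is used (no errors-in-variables
#' correction), so the slope is attenuated if the dissolved ratio itself is
#' noisy; see the methods vignette.
#'
#' @param dissolved_np,particulate_np Molar ratios, `> 0`, equal length.
#' @param label Subset label carried into the result.
#' @return A `homeostasis_fit` list: `slope_inv_h`, `intercept_log_c`,
#'   `slope_se`, `p_value`, `n`, `subset_label`.
#' @export
fit_homeostasis <- function(dissolved_np, particulate_np, label = "all") {
  ok <- !is.na(dissolved_np) & !is.na(particulate_np) &
    dissolved_np > 0 & particulate_np > 0
  x <- log10(dissolved_np[ok]); y <- log10(particulate_np[ok])
  if (length(x) < 3L) abort("fit_homeostasis: need >= 3 complete pairs")
  if (stats::var(x) == 0) abort("degenerate dissolved N:P (zero variance)")
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients  # perfect fits warn
  structure(list(
    slope_inv_h = unname(cf["x", "Estimate"]),
    intercept_log_c = unname(cf["(Intercept)", "Estimate"]),
    slope_se = unname(cf["x", "Std. Error"]),
    p_value = unname(cf["x", "Pr(>|t|)"]),
    n = length(x),
    subset_label = label
  ), class = "homeostasis_fit")
}

#' @export
print.homeostasis_fit <- function(x, ...) {
  cat(sprintf(
    "Homeostasis fit [%s]: 1/H = %.3f (se %.3f), log10 c = %.3f, p = %.3g, n = %d\n",
    x$subset_label, x$slope_inv_h, x$slope_se, x$intercept_log_c,
    x$p_value, x$n))
  invisible(x)
}

#' Homeostasis fits in low- and high-TP subsets
#'
#' Refits the 1/H regression on records with `TP < tp_low` and `TP >
#' tp_high` (strict inequalities; the middle band is excluded), a proxy
#' contrast between low and high suspended autotrophic biomass.
#'
#' @param records Data frame with `np_dissolved`, `np_particulate`, `tp`.
#' @param tp_low,tp_high Bin edges, mg/L (defaults 0.025 and 0.10).
#' @param min_n Minimum records per bin.
#' @return Named list of `homeostasis_fit` (`low_tp`, `high_tp`); an empty
#'   or undersized bin yields `NULL` with a warning.
#' @export
fit_homeostasis_by_tp_bin <- function(records, tp_low = 0.025, tp_high = 0.10,
                                      min_n = 10L) {
  fit_bin <- function(keep, label) {
    keep <- keep & !is.na(records$np_dissolved) & !is.na(records$np_particulate)
    if (sum(keep, na.rm = TRUE) < min_n) {
      warning("TP bin '", label, "' has fewer than ", min_n,
              " records; fit omitted")
      return(NULL)
    }
    fit_homeostasis(records$np_dissolved[keep], records$np_particulate[keep],
                    label)
  }
  list(
    low_tp = fit_bin(!is.na(records$tp) & records$tp < tp_low,
                     sprintf("TP < %g", tp_low)),
    high_tp = fit_bin(!is.na(records$tp) & records$tp > tp_high,
                      sprintf("TP > %g", tp_high))
  )
}

#' Per-site homeostasis fits for densely sampled sites
#'
#' Computes a site-specific 1/H for every site with strictly more than
#' `min_n` complete (dissolved, particulate) ratio pairs, together with the
#' medians and interquartile ranges of DIN:DIP, PN:PP and TN:TP at that
#' site.
#'
#' @param records Derived table with `site_id`, `np_dissolved`,
#'   `np_particulate`, `np_total`.
#' @param min_n Eligibility threshold; a site needs `> min_n` pairs
#'   (default 100).
#' @return List: `fits` (data frame, one row per eligible site),
#'   `ineligible` (site ids with their pair counts).
#' @export
per_site_homeostasis <- function(records, min_n = 100L) {
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  }
  sites <- unique(records$site_id)
  rows <- list(); inel_id <- character(0); inel_n <- integer(0)
  for (s in sites) {
    d <- records[records$site_id == s, , drop = FALSE]
    ok <- !is.na(d$np_dissolved) & !is.na(d$np_particulate) &
      d$np_dissolved > 0 & d$np_particulate > 0
    n_pairs <- sum(ok)
    if (n_pairs <= min_n) {
      inel_id <- c(inel_id, s); inel_n <- c(inel_n, n_pairs)
      next
    }
    fit <- fit_homeostasis(d$np_dissolved, d$np_particulate, label = s)
    m_d <- med_iqr(d$np_dissolved); m_p <- med_iqr(d$np_particulate)
    m_t <- med_iqr(d$np_total)
    rows[[s]] <- data.frame(
      site_id = s, n = fit$n,
      dindip_median = m_d[1], dindip_q1 = m_d[2], dindip_q3 = m_d[3],
      pnpp_median = m_p[1], pnpp_q1 = m_p[2], pnpp_q3 = m_p[3],
      tntp_median = m_t[1], tntp_q1 = m_t[2], tntp_q3 = m_t[3],
      inv_h = fit$slope_inv_h, p_value = fit$p_value,
      stringsAsFactors = FALSE
    )
  }
  list(
    fits = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL,
    ineligible = data.frame(site_id = inel_id, n_pairs = inel_n,
                            stringsAsFactors = FALSE)
  )
}

#' Fit the discharge-N:P power law at one site
#'
#' Fits `N:P = a * Q^b` by OLS of `log10(N:P)` on `log10(Q)`; `b` is the
#' power-law exponent, `a = 10^intercept` is the ratio at unit discharge.
#'
#' @param q Discharge, L/s (`> 0`).
#' @param np Molar ratio (`> 0`), same length.
#' @param ratio_kind `"total"`, `"dissolved"`, or `"particulate"`.
#' @param site_id Optional identifier carried into the result.
#' @param min_n Eligibility: needs strictly more than `min_n` valid pairs
#'   (default 10).
#' @return A `power_law_fit` list: `site_id`, `a_coeff`, `b_exp`, `b_se`,
#'   `p_value`, `n`, `ratio_kind`; or `NULL` (with attribute-free warning-less
#'   skip) if ineligible — callers that need reporting use
#'   [fit_power_law_by_site()].
#' @export
fit_power_law <- function(q, np, ratio_kind = c("total", "dissolved", "particulate"),
                          site_id = NA_character_, min_n = 10L) {
  ratio_kind <- match.arg(ratio_kind)
  ok <- !is.na(q) & !is.na(np) & q > 0 & np > 0
  if (sum(ok) <= min_n) {
    abort("fit_power_law: needs strictly more than ", min_n,
          " valid (Q, N:P) pairs, got ", sum(ok))
  }
  x <- log10(q[ok]); y <- log10(np[ok])
  if (stats::var(x) == 0) abort("degenerate discharge (zero variance)")
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients  # perfect fits warn
  structure(list(
    site_id = site_id,
    a_coeff = 10^unname(cf["(Intercept)", "Estimate"]),
    b_exp = unname(cf["x", "Estimate"]),
    b_se = unname(cf["x", "Std. Error"]),
    p_value = unname(cf["x", "Pr(>|t|)"]),
    n = sum(ok),
    ratio_kind = ratio_kind
  ), class = "power_law_fit")
}

#' Site-specific power-law exponents across a table
#'
#' @param records Derived table with `site_id`, `discharge_q` and the ratio
#'   column for `ratio_kind` (`np_total`, `np_dissolved`, `np_particulate`).
#' @param ratio_kind Which molar ratio to model against discharge.
#' @param min_n Eligibility threshold (strictly more than `min_n` pairs).
#' @return List: `fits` (data frame: `site_id`, `a_coeff`, `b_exp`, `b_se`,
#'   `p_value`, `n`, `ratio_kind`), `ineligible` (site ids and counts).
#' @export
fit_power_law_by_site <- function(records,
                                  ratio_kind = c("total", "dissolved", "particulate"),
                                  min_n = 10L) {
  ratio_kind <- match.arg(ratio_kind)
  col <- paste0("np_", ratio_kind)
  rows <- list(); inel_id <- character(0); inel_n <- integer(0)
  for (s in unique(records$site_id)) {
    d <- records[records$site_id == s, , drop = FALSE]
    ok <- !is.na(d$discharge_q) & !is.na(d[[col]]) &
      d$discharge_q > 0 & d[[col]] > 0
    if (sum(ok) <= min_n) {
      inel_id <- c(inel_id, s); inel_n <- c(inel_n, sum(ok))
      next
    }
    f <- fit_power_law(d$discharge_q, d[[col]], ratio_kind, site_id = s,
                       min_n = min_n)
    rows[[s]] <- data.frame(site_id = s, a_coeff = f$a_coeff, b_exp = f$b_exp,
                            b_se = f$b_se, p_value = f$p_value, n = f$n,
                            ratio_kind = ratio_kind, stringsAsFactors = FALSE)
  }
  list(
    fits = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL,
    ineligible = data.frame(site_id = inel_id, n_pairs = inel_n,
                            stringsAsFactors = FALSE)
  )
}

#' Regress power-law exponents on watershed land use
#'
#' Simple linear regression of the site-specific exponent `b` on
#' % agriculture (crop + hay), % urban, and % forest separately.
#'
#' @param fits Data frame from [fit_power_law_by_site()]`$fits`.
#' @param landuse Land-use profiles (`site_id`, `p_cro`, `p_hay`, `p_urb`,
#'   `p_for`).
#' @param min_sites Minimum sites with fits (default 10).
#' @return Data frame: `ratio_kind`, `predictor`, `slope`, `p_value`, `n`,
#'   `degenerate`.
#' @export
regress_b_on_landuse <- function(fits, landuse, min_sites = 10L) {
  merged <- merge(fits, landuse, by = "site_id")
  if (nrow(merged) < min_sites) {
    abort("regress_b_on_landuse: need >= ", min_sites, " sites with fits")
  }
  merged$pct_agric <- 100 * (merged$p_cro + merged$p_hay)
  merged$pct_urban <- 100 * merged$p_urb
  merged$pct_forest <- 100 * merged$p_for
  out <- list()
  for (rk in unique(merged$ratio_kind)) {
    d <- merged[merged$ratio_kind == rk, , drop = FALSE]
    for (v in c("pct_agric", "pct_urban", "pct_forest")) {
      x <- d[[v]]; y <- d$b_exp
      if (stats::var(x) == 0) {
        out[[paste(rk, v)]] <- data.frame(
          ratio_kind = rk, predictor = v, slope = NA_real_,
          p_value = NA_real_, n = nrow(d), degenerate = TRUE)
        next
      }
      fit <- stats::lm(y ~ x)
      cf <- suppressWarnings(summary(fit))$coefficients
      slope <- if ("x" %in% rownames(cf)) cf["x", "Estimate"] else 0
      pv <- if ("x" %in% rownames(cf)) cf["x", "Pr(>|t|)"] else 1
      out[[paste(rk, v)]] <- data.frame(
        ratio_kind = rk, predictor = v, slope = slope, p_value = pv,
        n = nrow(d), degenerate = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
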