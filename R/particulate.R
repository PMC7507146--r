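# Derivation of particulate N and P. Dissolved inorganic N (DIN) is the sum
# of the ammonia and nitrate+nitrite fractions. Particulate N is the residual
# TN - DIN minus the dissolved organic share, whose proportion of the
# residual is estimated empirically from records pairing totals with total
# dissolved fractions (DON = TDN - DIN; proportion = DON / (TN - DIN)).
# Uncertainty in that share is propagated by bootstrap: for each record,
# n_boot proportions are resampled from the empirical distribution, the
# candidate particulate values residual * (1 - p) are formed, and one
# uniform draw from their interquartile range is kept. Phosphorus is
# analogous with DIP, TDP, DOP.

#' Dissolved inorganic nitrogen from its measured components
#'
#' DIN = NH3-N + NH4-N + (NO3-N + NO2-N). A missing component is treated as
#' zero and the record flagged as a partial sum (strict mode instead returns
#' missing). DIN is missing only when all components are missing.
#'
#' @param nh3n,nh4n,no3no2n Component concentrations, mg/L as N (vectorised).
#' @param strict If `TRUE`, any missing component makes DIN missing.
#' @return Data frame: `din`, `partial` (logical flag).
#' @export
compute_din <- function(nh3n, nh4n, no3no2n, strict = FALSE) {
  m <- cbind(nh3n, nh4n, no3no2n)
  if (any(m < 0, na.rm = TRUE)) abort("negative DIN component")
  n_missing <- rowSums(is.na(m))
  din <- rowSums(m, na.rm = TRUE)
  din[n_missing == ncol(m)] <- NA_real_
  partial <- n_missing > 0 & n_missing < ncol(m)
  if (strict) din[n_missing > 0] <- NA_real_
  data.frame(din = din, partial = partial)
}

#' Empirical distribution of the dissolved-organic share of the residual
#'
#' For records pairing totals with total dissolved fractions, the dissolved
#' organic proportion of the total-minus-inorganic residual is
#' `(TDN - DIN) / (TN - DIN)` for nitrogen and `(TDP - DIP) / (TP - DIP)`
#' for phosphorus. Proportions outside `[0, 1]` (measurement inconsistency)
#' are excluded and counted.
#'
#' @param paired Data frame with columns `tn`, `tdn`, `din` (for `"N"`) or
#'   `tp`, `tdp`, `dip` (for `"P"`).
#' @param analyte `"N"` or `"P"`.
#' @return A `dom_dist` object: `analyte`, `proportions` (retained sample),
#'   `n_source_pairs`, `n_excluded`.
#' @export
estimate_dom_proportions <- function(paired, analyte = c("N", "P")) {
  analyte <- match.arg(analyte)
  cols <- if (analyte == "N") c("tn", "tdn", "din") else c("tp", "tdp", "dip")
  missing <- setdiff(cols, names(paired))
  if (length(missing)) {
    abort("paired table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tot <- paired[[cols[1]]]; tdis <- paired[[cols[2]]]; inorg <- paired[[cols[3]]]
  ok <- !is.na(tot) & !is.na(tdis) & !is.na(inorg) & (tot - inorg) > 0
  p <- (tdis[ok] - inorg[ok]) / (tot[ok] - inorg[ok])
  keep <- p >= 0 & p <= 1
  if (sum(keep) < 10L) {
    abort("insufficient pairs: only ", sum(keep),
          " valid dissolved-organic proportions (need >= 10)")
  }
  structure(
    list(analyte = analyte, proportions = p[keep],
         n_source_pairs = sum(keep), n_excluded = sum(!keep) + sum(!ok)),
    class = "dom_dist"
  )
}

#' Point-mass dissolved-organic proportion distribution
#'
#' Convenience constructor, mostly for tests and sensitivity analyses.
#'
#' @param proportions Numeric vector in `[0, 1]`.
#' @param analyte `"N"` or `"P"`.
#' @return A `dom_dist` object.
#' @export
dom_dist <- function(proportions, analyte = "N") {
  stopifnot(all(proportions >= 0 & proportions <= 1))
  structure(list(analyte = analyte, proportions = proportions,
                 n_source_pairs = length(proportions), n_excluded = 0L),
            class = "dom_dist")
}

#' Bootstrap one particulate concentration from a residual
#'
#' Draws `n_boot` proportions from the empirical dissolved-organic
#' distribution (with replacement), forms the candidate particulate values
#' `residual * (1 - p)`, and returns one uniform draw from the candidates'
#' interquartile range. A non-positive draw is returned as `NA` (the record
#' drops out of particulate analyses) — except for the degenerate
#' `residual = 0`, which returns 0 exactly.
#'
#' @param residual `TN - DIN` (or `TP - DIP`), mg/L, `>= 0`.
#' @param dist A `dom_dist`.
#' @param n_boot Bootstrap draws per record (default 1000).
#' @return One particulate concentration, mg/L, or `NA`.
#' @export
bootstrap_particulate <- function(residual, dist, n_boot = 1000L) {
  stopifnot(inherits(dist, "dom_dist"), length(residual) == 1L)
  if (is.na(residual)) return(NA_real_)
  if (residual < 0) abort("negative residual; run filter_inconsistent first")
  if (residual == 0) return(0)
  p <- sample(dist$proportions, n_boot, replace = TRUE)
  candidates <- residual * (1 - p)
  iqr <- stats::quantile(candidates, c(0.25, 0.75), names = FALSE, type = 7)
  draw <- stats::runif(1, iqr[1], iqr[2])
  if (draw <= 0) NA_real_ else draw
}

#' Remove records whose dissolved inorganic fraction exceeds the total
#'
#' Records with `DIN > TN` or `DIP > TP` are physically inconsistent and are
#' removed; the report gives counts and fractions by analyte (a record
#' violating both is counted under both but removed once).
#'
#' @param records Data frame with `din`, `tn` and/or `dip`, `tp`.
#' @return List: `records` (retained), `report` (data frame: `analyte`,
#'   `n_checked`, `n_removed`, `fraction`).
#' @export
filter_inconsistent <- function(records) {
  viol_n <- viol_p <- rep(FALSE, nrow(records))
  report <- NULL
  if (all(c("din", "tn") %in% names(records))) {
    have <- !is.na(records$din) & !is.na(records$tn)
    viol_n <- have & records$din > records$tn
    report <- rbind(report, data.frame(
      analyte = "DIN", n_checked = sum(have), n_removed = sum(viol_n),
      fraction = if (sum(have)) sum(viol_n) / sum(have) else NA_real_))
  }
  if (all(c("dip", "tp") %in% names(records))) {
    have <- !is.na(records$dip) & !is.na(records$tp)
    viol_p <- have & records$dip > records$tp
    report <- rbind(report, data.frame(
      analyte = "DIP", n_checked = sum(have), n_removed = sum(viol_p),
      fraction = if (sum(have)) sum(viol_p) / sum(have) else NA_real_))
  }
  keep <- !(viol_n | viol_p)
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Regression gate: dissolved-organic proportions versus land use
#'
#' Mirrors the pooling check behind the bootstrap: site-mean dissolved
#' organic proportions are regressed on each land-use proportion by simple
#' linear regression. If no slope is significant, pooling proportions across
#' sites is defensible.
#'
#' @param site_props Data frame: `site_id`, `proportion` (site-mean DON or
#'   DOP share).
#' @param landuse Land-use profiles with `p_cro`, `p_hay`, `p_urb`, `p_for`.
#' @param predictors Land-use columns to test.
#' @return Data frame: `predictor`, `slope`, `p_value`, `n`, `degenerate`.
#' @export
check_dom_vs_landuse <- function(site_props, landuse,
                                 predictors = c("p_cro", "p_hay", "p_urb", "p_for")) {
  merged <- merge(site_props, landuse, by = "site_id")
  if (nrow(merged) < 3L) abort("need >= 3 sites with proportions and land use")
  out <- lapply(predictors, function(v) {
    x <- merged[[v]]; y <- merged$proportion
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      slope <- if (stats::var(y) == 0) 0 else NA_real_
      return(data.frame(predictor = v, slope = slope,
                        p_value = if (is.na(slope)) NA_real_ else 1,
                        n = nrow(merged), degenerate = TRUE))
    }
    fit <- stats::lm(y ~ x)
    cf <- suppressWarnings(summary(fit))$coefficients
    data.frame(predictor = v, slope = cf["x", "Estimate"],
               p_value = cf["x", "Pr(>|t|)"], n = nrow(merged),
               degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Derive DIN, DIP, particulate N and P, and molar ratios for a table
#'
#' Full derivation stage: computes DIN from its components, applies the
#' consistency filter, bootstraps particulate N and P for every record using
#' the supplied dissolved-organic proportion distributions, and attaches
#' molar ratios (`np_total`, `np_dissolved`, `np_particulate`). Each record's
#' bootstrap uses a substream seeded from `(seed, site, date, analyte)`, so
#' the derivation is reproducible record-by-record regardless of table
#' order.
#'
#' The consistency filter belongs on reported (pre-imputation) values, so
#' the default `apply_filter = TRUE` is meant for tables whose values are
#' the reported ones; pipelines that filter first and impute afterwards call
#' this with `apply_filter = FALSE`, and any record whose imputed dissolved
#' fraction exceeds its total simply yields a missing particulate value
#' (counted under the non-positive draws).
#'
#' @param records Analysis table with `nh3n`, `nh4n`, `no3no2n`, `dip`, `tn`,
#'   `tp`.
#' @param dist_n,dist_p `dom_dist` objects for N and P.
#' @param n_boot Bootstrap draws per record.
#' @param seed Integer global seed.
#' @param strict_din Passed to [compute_din()].
#' @param apply_filter Run [filter_inconsistent()] on the recomputed DIN/DIP
#'   before bootstrapping (default `TRUE`).
#' @return List: `records` (with `din`, `pn`, `pp`, ratio columns and flags),
#'   `filter_report`, `n_nonpositive_pn`, `n_nonpositive_pp`.
#' @export
derive_nutrients <- function(records, dist_n, dist_p, n_boot = 1000L,
                             seed = 1L, strict_din = FALSE,
                             apply_filter = TRUE) {
  din <- compute_din(records$nh3n, records$nh4n, records$no3no2n,
                     strict = strict_din)
  records$din <- din$din
  records$din_partial <- din$partial

  flt_report <- NULL
  if (apply_filter) {
    flt <- filter_inconsistent(records)
    records <- flt$records
    flt_report <- flt$report
  }

  n <- nrow(records)
  pn <- pp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    key_site <- records$site_id[i]
    key_date <- as.character(records$date[i])
    res_n <- records$tn[i] - records$din[i]
    if (!is.na(res_n) && res_n >= 0) {
      set.seed(substream_seed(seed, key_site, key_date, "PN"))
      pn[i] <- bootstrap_particulate(res_n, dist_n, n_boot)
    }
    res_p <- records$tp[i] - records$dip[i]
    if (!is.na(res_p) && res_p >= 0) {
      set.seed(substream_seed(seed, key_site, key_date, "PP"))
      pp[i] <- bootstrap_particulate(res_p, dist_p, n_boot)
    }
  }
  records$pn <- pn
  records$pp <- pp
  suppressWarnings({
    records$np_total <- mass_to_molar_np(records$tn, records$tp)
    records$np_dissolved <- mass_to_molar_np(records$din, records$dip)
    records$np_particulate <- mass_to_molar_np(records$pn, records$pp)
  })
  list(
    records = records,
    filter_report = flt_report,
    n_nonpositive_pn = sum(is.na(pn) & !is.na(records$tn - records$din)),
    n_nonpositive_pp = sum(is.na(pp) & !is.na(records$tp - records$dip))
  )
}
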