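# Molar-ratio computation, ecological threshold registry, exceedance
# summaries, descriptive statistics, and percentile loess curves along the
# developed-land-use gradient.

#' Atomic masses used for mass-to-molar conversion (g/mol)
#' @name molar-masses
#' @keywords internal
MOLAR_MASS_N <- 14.007
MOLAR_MASS_P <- 30.974

#' Convert a mass-based N:P ratio to a molar ratio
#'
#' Concentrations of N and P are reported in mg/L as N and as P; the molar
#' N:P ratio is `(cn / 14.007) / (cp / 30.974)`, i.e. the mass ratio times
#' about 2.211. The canonical Redfield molar ratio of 16:1 corresponds to a
#' mass ratio of about 7.2.
#'
#' @param cn Nitrogen concentration, mg/L as N (vectorised, `cn >= 0`).
#' @param cp Phosphorus concentration, mg/L as P (`cp > 0`; zero yields `NaN`
#'   with a warning rather than an error, so whole tables can be converted).
#' @return Molar N:P ratio (unitless), same length as the inputs.
#' @examples
#' mass_to_molar_np(1, 1)      # ~2.211
#' mass_to_molar_np(7.235, 1)  # ~16, the Redfield ratio
#' @export
mass_to_molar_np <- function(cn, cp) {
  stopifnot(is.numeric(cn), is.numeric(cp))
  if (any(cp == 0, na.rm = TRUE)) {
    warning("zero phosphorus concentration: molar N:P undefined (NaN)")
  }
  (cn / MOLAR_MASS_N) / (cp / MOLAR_MASS_P)
}

#' Built-in ecological response thresholds for stream N and P
#'
#' Registry of literature response thresholds against which observed
#' concentrations are compared: the most conservative (highest) reported
#' thresholds for structural change in benthic algae, macroinvertebrate and
#' fish communities (total nutrients), and the highest reported
#' half-saturation constants for leaf-litter breakdown and benthic algal
#' growth (dissolved inorganic nutrients).
#'
#' @return A data frame with columns `analyte` (TN, TP, DIN, DIP), `response`,
#'   `kind` (`structural` or `functional_half_saturation`), and `value_mg_l`.
#' @export
builtin_thresholds <- function() {
  data.frame(
    analyte = c("TN", "TP", "TN", "TP", "TN", "TP", "DIN", "DIP", "DIN", "DIP"),
    response = c(
      "benthic_algae", "benthic_algae",
      "macroinvertebrates", "macroinvertebrates",
      "fish", "fish",
      "litter_breakdown", "litter_breakdown",
      "algal_growth", "algal_growth"
    ),
    kind = c(rep("structural", 6), rep("functional_half_saturation", 4)),
    value_mg_l = c(1.162, 0.074, 1.92, 0.15, 1.83, 0.139,
                   0.052, 0.021, 0.186, 0.004),
    stringsAsFactors = FALSE
  )
}

#' Fraction of concentrations exceeding a response threshold
#'
#' Counts values strictly greater than the threshold ("above"); values equal
#' to the threshold do not count as exceedances. Missing values are dropped
#' before counting.
#'
#' @param values Concentrations, mg/L.
#' @param threshold One row of a threshold registry (see
#'   [builtin_thresholds()]), or a single numeric threshold in mg/L.
#' @return A one-row data frame: `analyte`, `response`, `threshold_mg_l`,
#'   `n`, `n_exceed`, `fraction`.
#' @export
exceedance_fraction <- function(values, threshold) {
  if (is.numeric(threshold)) {
    threshold <- data.frame(analyte = NA_character_, response = NA_character_,
                            value_mg_l = threshold)
  }
  stopifnot(nrow(threshold) == 1L, threshold$value_mg_l > 0)
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("exceedance_fraction: no non-missing values")
  n_exceed <- sum(values > threshold$value_mg_l)
  data.frame(
    analyte = threshold$analyte,
    response = threshold$response,
    threshold_mg_l = threshold$value_mg_l,
    n = length(values),
    n_exceed = n_exceed,
    fraction = n_exceed / length(values),
    stringsAsFactors = FALSE
  )
}

#' Exceedance summaries for every threshold in a registry
#'
#' @param records Data frame with (lower-case) concentration columns `tn`,
#'   `tp`, `din`, `dip` as available.
#' @param thresholds Threshold registry; defaults to [builtin_thresholds()].
#' @return Data frame with one row per threshold having data.
#' @export
exceedance_table <- function(records, thresholds = builtin_thresholds()) {
  out <- lapply(seq_len(nrow(thresholds)), function(i) {
    th <- thresholds[i, , drop = FALSE]
    col <- tolower(th$analyte)
    if (!col %in% names(records)) return(NULL)
    v <- records[[col]]
    if (all(is.na(v))) return(NULL)
    exceedance_fraction(v, th)
  })
  do.call(rbind, out)
}

#' Medians and interquartile ranges per analyte and molar ratio
#'
#' Quartiles use linear interpolation (R's default type-7 definition).
#' Optionally stratifies by bands of developed land use (% agriculture +
#' % urban), as used for comparing low- and high-development watersheds.
#'
#' @param records Data frame of derived records; all numeric columns among
#'   `tn, tp, din, dip, pn, pp, np_total, np_dissolved, np_particulate` that
#'   are present are summarised.
#' @param developed_pct Optional per-record developed-land percentage (crop +
#'   hay + urban), used with `bins`.
#' @param bins Optional list of `c(lo, hi)` percentage bands, e.g.
#'   `list(c(5, 15), c(85, 95))`.
#' @return Data frame: `group`, `variable`, `n`, `median`, `q1`, `q3`.
#' @export
summary_table <- function(records, developed_pct = NULL, bins = NULL) {
  vars <- intersect(
    c("tn", "tp", "din", "dip", "pn", "pp",
      "np_total", "np_dissolved", "np_particulate"),
    names(records)
  )
  one_group <- function(df, label) {
    rows <- lapply(vars, function(v) {
      x <- df[[v]]
      x <- x[!is.na(x)]
      if (length(x) == 0L) return(NULL)
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      data.frame(group = label, variable = v, n = length(x),
                 median = q[2], q1 = q[1], q3 = q[3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- one_group(records, "all")
  if (!is.null(developed_pct) && !is.null(bins)) {
    stopifnot(length(developed_pct) == nrow(records))
    for (b in bins) {
      keep <- !is.na(developed_pct) & developed_pct >= b[1] & developed_pct <= b[2]
      if (any(keep)) {
        out <- rbind(out, one_group(records[keep, , drop = FALSE],
                                    sprintf("developed_%g-%g", b[1], b[2])))
      }
    }
  }
  out
}

#' Smoothed percentile curves of concentration along a land-use gradient
#'
#' At each grid point along the developed-land axis, the empirical
#' percentiles of `y` are computed within a sliding window; each percentile
#' series is then smoothed with locally weighted regression (tricube weights,
#' degree 1). Grid points whose window holds fewer than `min_window_n` points
#' are omitted and logged. Smoothed curves are rearranged pointwise
#' (cumulative maximum across increasing percentile) so that higher
#' percentiles never cross below lower ones.
#'
#' @param x Developed land use, percent (crop + hay + urban).
#' @param y Concentration, mg/L.
#' @param percentiles Percentile levels; default `c(10, 25, 50, 75, 90)`.
#' @param window_halfwidth Half-width of the sliding window, in % units.
#' @param span Loess span applied to each percentile series.
#' @param grid_step Grid spacing along `x`, in % units.
#' @param min_window_n Minimum points required in a window.
#' @return List with `curves` (data frame: `percentile`, `x`, `y`) and
#'   `omitted` (grid points skipped for sparsity).
#' @export
percentile_loess <- function(x, y, percentiles = c(10, 25, 50, 75, 90),
                             window_halfwidth = 5, span = 0.75,
                             grid_step = 1, min_window_n = 10) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 30L) abort("percentile_loess: need at least 30 points")
  percentiles <- sort(percentiles)
  grid <- seq(floor(min(x)), ceiling(max(x)), by = grid_step)
  raw <- matrix(NA_real_, nrow = length(grid), ncol = length(percentiles))
  n_in <- integer(length(grid))
  for (i in seq_along(grid)) {
    w <- abs(x - grid[i]) <= window_halfwidth
    n_in[i] <- sum(w)
    if (n_in[i] >= min_window_n) {
      raw[i, ] <- stats::quantile(y[w], percentiles / 100, names = FALSE,
                                  type = 7)
    }
  }
  keep <- !is.na(raw[, 1])
  omitted <- grid[!keep]
  grid <- grid[keep]
  raw <- raw[keep, , drop = FALSE]
  if (length(grid) < 4L) abort("percentile_loess: gradient too sparse")
  sm <- raw
  for (j in seq_along(percentiles)) {
    fit <- stats::loess(raw[, j] ~ grid, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    sm[, j] <- stats::predict(fit, data.frame(grid = grid))
  }
  # non-crossing rearrangement: enforce ordering across percentile levels
  sm <- t(apply(sm, 1, cummax))
  curves <- data.frame(
    percentile = rep(percentiles, each = length(grid)),
    x = rep(grid, times = length(percentiles)),
    y = as.vector(sm)
  )
  list(curves = curves, omitted = omitted)
}
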