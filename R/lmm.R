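# Random-intercept land-use models. Each log10 nutrient concentration is
# modelled as a linear function of log10 discharge and the watershed
# proportions of row-crop, pasture (hay), forested, and urban land cover,
# with a random intercept per monitoring site, fit by REML. Raw coefficients
# are accompanied by standardized coefficients (predictors z-scored), Wald
# 95% confidence intervals and p-values, and Nakagawa-Schielzeth marginal /
# conditional R-squared.

LANDUSE_PREDICTORS <- c("log10_q", "p_cro", "p_hay", "p_for", "p_urb")

#' Z-score predictor columns
#'
#' Centers each predictor by its mean and divides by its sample standard
#' deviation (n - 1). The response is untouched. Zero-variance predictors
#' are dropped with a warning.
#'
#' @param table Data frame.
#' @param predictors Columns to standardize.
#' @return The table with the listed columns z-scored (zero-variance columns
#'   removed); the scaling factors are attached as attribute `"scales"`.
#' @export
standardize_predictors <- function(table, predictors = LANDUSE_PREDICTORS) {
  scales <- numeric(0)
  for (v in intersect(predictors, names(table))) {
    s <- stats::sd(table[[v]], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("predictor '", v, "' has zero variance; excluded")
      table[[v]] <- NULL
      next
    }
    table[[v]] <- (table[[v]] - mean(table[[v]], na.rm = TRUE)) / s
    scales[v] <- s
  }
  attr(table, "scales") <- scales
  table
}

#' Fit a random-intercept land-use model for one nutrient response
#'
#' Model: `log10(conc) ~ log10_q + p_cro + p_hay + p_for + p_urb +
#' (1 | site_id)`, REML. Complete cases only; records with non-positive
#' concentration (log undefined) are excluded. A singular fit (site variance
#' estimated at zero) is retained and flagged.
#'
#' @param table Analysis table with `site_id`, `discharge_q` (or `log10_q`),
#'   land-use proportions and the response concentration column.
#' @param response One of `"tn"`, `"din"`, `"pn"`, `"tp"`, `"dip"`, `"pp"`
#'   (the concentration column; modelled on the log10 scale).
#' @return A `landuse_fit` list: `response`, `coefficients` (data frame:
#'   `term`, `estimate`, `std_estimate`, `ci_lo`, `ci_hi`, `p_value`),
#'   `r2_marginal`, `r2_conditional`, `var_site`, `var_resid`, `n_obs`,
#'   `n_sites`, `singular`, and the underlying `lmerMod` as `model`.
#' @export
fit_landuse_model <- function(table, response) {
  stopifnot(response %in% names(table))
  if (!"log10_q" %in% names(table)) {
    table$log10_q <- log10(table$discharge_q)
  }
  y <- table[[response]]
  keep <- !is.na(y) & y > 0 &
    stats::complete.cases(table[, c(LANDUSE_PREDICTORS, "site_id")]) &
    is.finite(table$log10_q)
  d <- table[keep, , drop = FALSE]
  d$.y <- log10(d[[response]])
  if (length(unique(d$site_id)) < 2L) abort("need >= 2 sites")

  form <- stats::as.formula(paste(
    ".y ~", paste(LANDUSE_PREDICTORS, collapse = " + "), "+ (1 | site_id)"))
  # allow the one-observation-per-site limit, where the fit collapses to OLS
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.rankZ = "ignore")
  fit <- lme4::lmer(form, data = d, REML = TRUE, control = ctrl)
  singular <- lme4::isSingular(fit, tol = 1e-4)

  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  p <- 2 * stats::pnorm(-abs(est / se))        # Wald z
  sds <- vapply(LANDUSE_PREDICTORS, function(v) stats::sd(d[[v]]), 0)
  std <- est * c(`(Intercept)` = NA_real_, sds)[rownames(cf)]
  coefs <- data.frame(
    term = rownames(cf), estimate = unname(est),
    std_estimate = unname(std),
    ci_lo = unname(est - stats::qnorm(0.975) * se),
    ci_hi = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
  r2 <- r2_mixed(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    response = response, coefficients = coefs,
    r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
    var_site = vc$vcov[vc$grp == "site_id"],
    var_resid = vc$vcov[vc$grp == "Residual"],
    n_obs = nrow(d), n_sites = length(unique(d$site_id)),
    singular = singular, model = fit
  ), class = "landuse_fit")
}

#' @export
print.landuse_fit <- function(x, ...) {
  cat(sprintf("Land-use mixed model for log10 %s (n = %d obs, %d sites%s)\n",
              toupper(x$response), x$n_obs, x$n_sites,
              if (x$singular) ", singular" else ""))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R-squared for a Gaussian mixed model
#'
#' Nakagawa-Schielzeth decomposition for an identity-link Gaussian model:
#' the fixed-effect variance is the variance of the linear predictor from
#' the fixed effects; marginal R2 divides it by the sum of fixed, random
#' intercept, and residual variances, and conditional R2 adds the random
#' intercept variance to the numerator.
#'
#' @param fit A fitted `lmerMod` (or a `landuse_fit` wrapper).
#' @return Named numeric: `marginal`, `conditional`.
#' @export
r2_mixed <- function(fit) {
  if (inherits(fit, "landuse_fit")) fit <- fit$model
  var_fixed <- stats::var(as.vector(
    lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  denom <- var_fixed + var_rand + var_resid
  c(marginal = var_fixed / denom,
    conditional = (var_fixed + var_rand) / denom)
}

#' Mixed model for the percent-particulate fraction
#'
#' Response is `100 * PN / TN` (or `100 * PP / TP`): the percentage of the
#' total nutrient carried in particles. Same random-intercept structure as
#' the concentration models, with land-use covariates expressed in percent
#' so a coefficient reads as the change in percent-particulate per
#' percentage-point of land use.
#'
#' @param table Derived analysis table.
#' @param analyte `"N"` or `"P"`.
#' @return A `landuse_fit` (response `pct_particulate_N` or `_P`); records
#'   with zero or missing totals are excluded and counted in `n_excluded`.
#' @export
fraction_particulate_model <- function(table, analyte = c("N", "P")) {
  analyte <- match.arg(analyte)
  part <- if (analyte == "N") table$pn else table$pp
  tot <- if (analyte == "N") table$tn else table$tp
  bad <- is.na(part) | is.na(tot) | tot == 0
  d <- table[!bad, , drop = FALSE]
  d$.pct <- 100 * (if (analyte == "N") d$pn / d$tn else d$pp / d$tp)
  if (!"log10_q" %in% names(d)) d$.log10_q <- log10(d$discharge_q) else d$.log10_q <- d$log10_q
  d$.pcro <- 100 * d$p_cro; d$.phay <- 100 * d$p_hay
  d$.pfor <- 100 * d$p_for; d$.purb <- 100 * d$p_urb
  fit <- lme4::lmer(
    .pct ~ .log10_q + .pcro + .phay + .pfor + .purb + (1 | site_id),
    data = d, REML = TRUE)
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  p <- 2 * stats::pnorm(-abs(est / se))
  preds <- c(".log10_q", ".pcro", ".phay", ".pfor", ".purb")
  sds <- vapply(preds, function(v) stats::sd(d[[v]]), 0)
  std <- est * c(`(Intercept)` = NA_real_, sds)[rownames(cf)]
  terms <- c("(Intercept)", "log10_q", "pct_cro", "pct_hay", "pct_for", "pct_urb")
  coefs <- data.frame(
    term = terms, estimate = unname(est), std_estimate = unname(std),
    ci_lo = unname(est - stats::qnorm(0.975) * se),
    ci_hi = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(p), stringsAsFactors = FALSE
  )
  r2 <- r2_mixed(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    response = paste0("pct_particulate_", analyte), coefficients = coefs,
    r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
    var_site = vc$vcov[vc$grp == "site_id"],
    var_resid = vc$vcov[vc$grp == "Residual"],
    n_obs = nrow(d), n_sites = length(unique(d$site_id)),
    n_excluded = sum(bad),
    singular = lme4::isSingular(fit, tol = 1e-4), model = fit
  ), class = "landuse_fit")
}

#' Table-style summary across the six concentration responses
#'
#' Fits [fit_landuse_model()] for every requested response and assembles one
#' row per response with raw (standardized) coefficients and model fits.
#'
#' @param table Derived analysis table.
#' @param responses Concentration columns to model.
#' @return List: `fits` (named list of `landuse_fit`), `table` (data frame,
#'   one row per response).
#' @export
landuse_model_table <- function(table,
                                responses = c("tn", "din", "pn", "tp", "dip", "pp")) {
  fits <- list()
  rows <- list()
  for (r in intersect(responses, names(table))) {
    f <- fit_landuse_model(table, r)
    fits[[r]] <- f
    cc <- f$coefficients
    grab <- function(term, what) cc[cc$term == term, what]
    rows[[r]] <- data.frame(
      response = paste0("log10_", r),
      intercept = grab("(Intercept)", "estimate"),
      q = grab("log10_q", "estimate"), q_std = grab("log10_q", "std_estimate"),
      p_cro = grab("p_cro", "estimate"), p_cro_std = grab("p_cro", "std_estimate"),
      p_hay = grab("p_hay", "estimate"), p_hay_std = grab("p_hay", "std_estimate"),
      p_for = grab("p_for", "estimate"), p_for_std = grab("p_for", "std_estimate"),
      p_urb = grab("p_urb", "estimate"), p_urb_std = grab("p_urb", "std_estimate"),
      r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
      n_obs = f$n_obs, n_sites = f$n_sites,
      stringsAsFactors = FALSE
    )
  }
  list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}
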