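# Monte Carlo imputation of "estimated" and "less-than" qualified
# concentrations. Reported concentrations near analytical detection limits
# carry qualifier flags; rather than discarding or substituting them, each
# qualified value is replaced by a random draw that expresses its
# uncertainty: a truncated normal around "estimated" values, a uniform below
# the reporting limit for "less-than" values.

#' Censoring / qualification imputation policy
#'
#' @param cv_estimated Coefficient of variation of the normal used for
#'   "estimated" values (sd = `cv_estimated * value`). Default 0.10, a
#'   typical analytical relative error; results should be reported as robust
#'   to this knob.
#' @param lower_bound_lt Floor of the uniform used for "less-than" values,
#'   mg/L. Default 0 (maximally agnostic below the reporting limit).
#' @return A `censoring_policy` list.
#' @export
censoring_policy <- function(cv_estimated = 0.10, lower_bound_lt = 0) {
  stopifnot(cv_estimated >= 0, lower_bound_lt >= 0)
  structure(list(cv_estimated = cv_estimated, lower_bound_lt = lower_bound_lt),
            class = "censoring_policy")
}

#' Impute one vector of qualified concentrations
#'
#' Measured values pass through unchanged. "Estimated" values are replaced by
#' a draw from Normal(value, cv * value) truncated at zero by resampling
#' (clipping would create a point mass at zero). "Less-than" values, whose
#' `value` is the reporting limit, are replaced by a draw from
#' Uniform(lower_bound, limit). Draws use the current RNG state; seed the
#' stream with [set.seed()] or [substream_seed()] for reproducibility.
#'
#' @param value Concentrations, mg/L (`value >= 0`).
#' @param qualifier Character vector in `measured`, `estimated`, `less_than`;
#'   `NA` treated as measured.
#' @param policy A [censoring_policy()].
#' @return Imputed concentrations, always `>= 0`, never above the reporting
#'   limit for less-than records.
#' @export
impute_qualified_value <- function(value, qualifier, policy = censoring_policy()) {
  stopifnot(inherits(policy, "censoring_policy"),
            length(qualifier) == length(value))
  out <- value
  qualifier[is.na(qualifier)] <- "measured"

  est <- which(qualifier == "estimated" & !is.na(value))
  if (length(est) && policy$cv_estimated > 0) {
    mu <- value[est]
    sd <- policy$cv_estimated * mu
    draw <- stats::rnorm(length(est), mu, sd)
    bad <- which(draw <= 0 & sd > 0)
    tries <- 0L
    while (length(bad)) {   # truncate at 0 by resampling
      draw[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
      bad <- bad[draw[bad] <= 0]
      tries <- tries + 1L
      if (tries > 1000L) { draw[bad] <- mu[bad]; break }
    }
    draw[sd == 0] <- mu[sd == 0]
    out[est] <- draw
  }

  lt <- which(qualifier == "less_than" & !is.na(value))
  if (length(lt)) {
    lo <- pmin(policy$lower_bound_lt, value[lt])
    out[lt] <- stats::runif(length(lt), lo, value[lt])
  }
  out
}

#' Impute every qualified value in an analysis table
#'
#' Applies [impute_qualified_value()] to each analyte column that has a
#' companion `_qual` column, drawing one realization per qualified value.
#' Each analyte column uses a substream seeded from `(seed, "censoring",
#' analyte)`, so realizations are reproducible and independent across
#' analytes.
#'
#' @param records Analysis table with analyte and `_qual` columns.
#' @param policy A [censoring_policy()].
#' @param seed Integer seed for the imputation substreams.
#' @return List: `records` (imputed; `_qual` columns retained), `log`
#'   (data frame of counts by analyte and qualifier).
#' @export
impute_table <- function(records, policy = censoring_policy(), seed = 1L) {
  qcols <- grep("_qual$", names(records), value = TRUE)
  log <- NULL
  for (qc in qcols) {
    a <- sub("_qual$", "", qc)
    if (!a %in% names(records)) next
    qual <- records[[qc]]
    counts <- table(factor(qual, levels = c("estimated", "less_than")))
    log <- rbind(log, data.frame(
      analyte = a,
      n_estimated = as.integer(counts[["estimated"]]),
      n_less_than = as.integer(counts[["less_than"]]),
      stringsAsFactors = FALSE
    ))
    if (sum(counts) == 0L) next
    set.seed(substream_seed(seed, "censoring", a))
    records[[a]] <- impute_qualified_value(records[[a]], qual, policy)
  }
  list(records = records, log = log)
}
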