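# Reading, validating, and joining sample, land-use, and paired
# total/total-dissolved tables into one analysis table.
#
# Canonical analyte codes (lower-case column names in the analysis table):
#   nh3n, nh4n, no3no2n, dip, tn, tp, tdn, tdp     -- all mg/L as N or P
# Each analyte column may be accompanied by "<analyte>_qual" holding one of
# "measured", "estimated", "less_than". A value written as "<0.001" in the
# concentration column itself is parsed as (0.001, less_than).

ANALYTES <- c("nh3n", "nh4n", "no3no2n", "dip", "tn", "tp", "tdn", "tdp")
QUALIFIERS <- c("measured", "estimated", "less_than")

#' Default schema for sample tables
#'
#' Maps canonical field names to the column names found in the file. The
#' default assumes columns already carry canonical names (the dialect the
#' synthetic generator writes); Water Quality Portal style exports can be
#' accommodated by overriding entries. `format` may be `"wide"` (one column
#' per analyte) or `"long"` (`analyte`/`value`/`qualifier` columns).
#'
#' @param ... Overrides, e.g. `site = "MonitoringLocationIdentifier"`.
#' @param format `"wide"` or `"long"`.
#' @param unit_factor Multiplier applied to all concentrations on read, e.g.
#'   `1e-3` for files reporting micrograms per litre. Never guessed.
#' @return A schema list used by [read_sample_table()].
#' @export
sample_schema <- function(..., format = c("wide", "long"), unit_factor = 1) {
  format <- match.arg(format)
  schema <- list(
    site = "site_id", date = "date", discharge = "discharge_q",
    analytes = stats::setNames(ANALYTES, ANALYTES),
    qual_suffix = "_qual",
    analyte_col = "analyte", value_col = "value", qualifier_col = "qualifier",
    format = format, unit_factor = unit_factor
  )
  utils::modifyList(schema, list(...))
}

parse_qualified <- function(raw) {
  # returns list(value, qualifier) from a character or numeric vector;
  # "<x" encodes a less-than reporting limit
  raw_chr <- trimws(as.character(raw))
  lt <- !is.na(raw_chr) & startsWith(raw_chr, "<")
  num <- suppressWarnings(as.numeric(sub("^<", "", raw_chr)))
  qual <- ifelse(lt, "less_than", "measured")
  qual[is.na(num)] <- NA_character_
  list(value = num, qualifier = qual)
}

#' Read a water-quality sample table
#'
#' Parses a CSV of site-by-date nutrient samples into the canonical analysis
#' layout. Unparseable or invalid rows are collected in a rejects report with
#' a reason code, never silently dropped. Negative concentrations reject the
#' row; `"<limit"` strings become less-than qualified values at the reporting
#' limit.
#'
#' @param path CSV file path.
#' @param schema Column-name map from [sample_schema()].
#' @return List with `records` (data frame: `site_id`, `date`, `discharge_q`,
#'   one value and one `_qual` column per analyte present) and `rejects`
#'   (data frame: `row`, `reason`).
#' @export
read_sample_table <- function(path, schema = sample_schema()) {
  if (!file.exists(path)) abort("sample table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (req in c(schema$site, schema$date)) {
    if (!req %in% names(raw)) {
      abort("sample table is missing required column '", req, "'")
    }
  }
  if (schema$format == "long") raw <- long_to_wide(raw, schema)

  n <- nrow(raw)
  rej_row <- integer(0); rej_reason <- character(0)
  reject <- function(i, why) {
    rej_row <<- c(rej_row, i); rej_reason <<- c(rej_reason, why)
  }

  date <- as.Date(raw[[schema$date]], format = "%Y-%m-%d")
  bad_date <- is.na(date) & !is.na(raw[[schema$date]]) & raw[[schema$date]] != ""
  q <- rep(NA_real_, n)
  if (schema$discharge %in% names(raw)) {
    q <- suppressWarnings(as.numeric(raw[[schema$discharge]]))
  }
  bad_q <- !is.na(q) & q < 0

  rec <- data.frame(site_id = as.character(raw[[schema$site]]),
                    date = date, discharge_q = q,
                    stringsAsFactors = FALSE)
  bad_conc <- rep(FALSE, n)
  for (a in names(schema$analytes)) {
    col <- schema$analytes[[a]]
    if (!col %in% names(raw)) next
    parsed <- parse_qualified(raw[[col]])
    qcol <- paste0(col, schema$qual_suffix)
    if (qcol %in% names(raw)) {
      explicit <- raw[[qcol]]
      use <- !is.na(explicit) & explicit %in% QUALIFIERS
      parsed$qualifier[use] <- explicit[use]
      bad_qual <- !is.na(explicit) & explicit != "" & !explicit %in% QUALIFIERS
      bad_conc <- bad_conc | bad_qual
    }
    parsed$value <- parsed$value * schema$unit_factor
    bad_conc <- bad_conc | (!is.na(parsed$value) & parsed$value < 0)
    rec[[a]] <- parsed$value
    rec[[paste0(a, "_qual")]] <- parsed$qualifier
  }

  drop <- bad_date | bad_q | bad_conc
  for (i in which(bad_date)) reject(i, "unparseable date")
  for (i in which(bad_q & !bad_date)) reject(i, "negative discharge")
  for (i in which(bad_conc & !bad_date & !bad_q)) reject(i, "negative or invalid concentration")

  list(
    records = rec[!drop, , drop = FALSE],
    rejects = data.frame(row = rej_row, reason = rej_reason,
                         stringsAsFactors = FALSE)
  )
}

long_to_wide <- function(raw, schema) {
  need <- c(schema$analyte_col, schema$value_col)
  if (!all(need %in% names(raw))) {
    abort("long-format sample table needs columns: ", paste(need, collapse = ", "))
  }
  key_cols <- c(schema$site, schema$date,
                intersect(schema$discharge, names(raw)))
  qual <- if (schema$qualifier_col %in% names(raw)) {
    raw[[schema$qualifier_col]]
  } else rep("measured", nrow(raw))
  ana <- tolower(raw[[schema$analyte_col]])
  keys <- unique(raw[, key_cols, drop = FALSE])
  wide <- keys
  for (a in unique(ana)) {
    sel <- ana == a
    idx <- match(
      do.call(paste, c(keys, sep = "\x1f")),
      do.call(paste, c(raw[sel, key_cols, drop = FALSE], sep = "\x1f"))
    )
    wide[[a]] <- raw[[schema$value_col]][sel][idx]
    wide[[paste0(a, schema$qual_suffix)]] <- qual[sel][idx]
  }
  wide
}

#' Read and aggregate a watershed land-use table
#'
#' Input columns are NLCD-class percentages: `pct_crop`, `pct_hay`,
#' `pct_urban_low`, `pct_urban_med`, `pct_urban_high`, `pct_forest_decid`,
#' `pct_forest_mixed`, `pct_forest_conif`, plus `site_id` and
#' `watershed_area_km2`. Urban intensities and forest types are summed,
#' percentages divided by 100, and the remainder assigned to `p_other`.
#'
#' @param path CSV file path.
#' @return Data frame: `site_id`, `p_cro`, `p_hay`, `p_urb`, `p_for`,
#'   `p_other`, `watershed_area_km2`.
#' @export
read_landuse_table <- function(path) {
  if (!file.exists(path)) abort("land-use table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "pct_crop", "pct_hay", "pct_urban_low",
            "pct_urban_med", "pct_urban_high", "pct_forest_decid",
            "pct_forest_mixed", "pct_forest_conif")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort("land-use table missing columns: ", paste(missing, collapse = ", "))
  }
  classes <- raw[, setdiff(need, "site_id")]
  if (any(classes < 0, na.rm = TRUE)) abort("negative land-use percentage")
  total <- rowSums(classes)
  if (any(total > 100.5, na.rm = TRUE)) {
    abort("land-use class percentages sum to more than 100.5 for site(s): ",
          paste(raw$site_id[which(total > 100.5)], collapse = ", "))
  }
  out <- data.frame(
    site_id = as.character(raw$site_id),
    p_cro = raw$pct_crop / 100,
    p_hay = raw$pct_hay / 100,
    p_urb = (raw$pct_urban_low + raw$pct_urban_med + raw$pct_urban_high) / 100,
    p_for = (raw$pct_forest_decid + raw$pct_forest_mixed +
               raw$pct_forest_conif) / 100,
    stringsAsFactors = FALSE
  )
  out$p_other <- pmax(0, 1 - (out$p_cro + out$p_hay + out$p_urb + out$p_for))
  out$watershed_area_km2 <-
    if ("watershed_area_km2" %in% names(raw)) raw$watershed_area_km2 else NA_real_
  out
}

#' Join sample records to watershed land-use profiles
#'
#' Inner join on `site_id`; samples at sites without a land-use profile are
#' counted as orphans and reported. Output is sorted chronologically within
#' site.
#'
#' @param samples Sample records (from [read_sample_table()] or the
#'   synthetic generator).
#' @param landuse Land-use profiles (from [read_landuse_table()]).
#' @return List: `table` (joined, sorted), `n_orphans`, `orphan_sites`.
#' @export
join_site_data <- function(samples, landuse) {
  stopifnot(is.data.frame(samples), is.data.frame(landuse))
  hit <- samples$site_id %in% landuse$site_id
  orphan_sites <- sort(unique(samples$site_id[!hit]))
  joined <- merge(samples[hit, , drop = FALSE], landuse, by = "site_id",
                  sort = FALSE)
  if (nrow(joined) == 0L) {
    abort("no samples match any land-use profile; sample sites: ",
          paste(utils::head(unique(samples$site_id), 5), collapse = ", "),
          " ... land-use sites: ",
          paste(utils::head(landuse$site_id, 5), collapse = ", "))
  }
  joined <- joined[order(joined$site_id, joined$date), , drop = FALSE]
  rownames(joined) <- NULL
  list(table = joined, n_orphans = sum(!hit), orphan_sites = orphan_sites)
}
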