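# Configuration-driven end-to-end runner: ingest -> censoring imputation ->
# particulate derivation and consistency filter -> threshold and summary
# metrics -> homeostasis and discharge power laws -> land-use mixed models.
# All outputs are plain CSV plus a JSON manifest; re-running with the same
# config and seed reproduces every output byte-for-byte (no timestamps are
# written).

PIPELINE_VERSION <- "0.1.0"

default_config <- function() {
  list(
    seed = NULL,
    synthetic = NULL,
    inputs = NULL,
    censoring = list(cv_estimated = 0.10, lower_bound_lt = 0),
    bootstrap = list(n_boot = 1000L),
    realizations = 1L,
    homeostasis = list(tp_low = 0.025, tp_high = 0.10, min_site_n = 100L),
    power_law = list(min_n = 10L),
    loess = list(window_halfwidth = 5, span = 0.75, grid_step = 1)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Unknown keys are rejected; defaults
#' are materialized; `seed` is mandatory and exactly one of `synthetic` /
#' `inputs` must be present; `n_boot` must be at least 1.
#'
#' @param config YAML path or config list.
#' @return The validated, fully materialized config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) abort("config must set a seed")
  if (!is_count(cfg$seed)) abort("seed must be a nonnegative integer")
  has_syn <- !is.null(cfg$synthetic); has_real <- !is.null(cfg$inputs)
  if (has_syn == has_real) {
    abort("config must set exactly one of 'synthetic' or 'inputs'")
  }
  if (cfg$bootstrap$n_boot < 1) abort("bootstrap n_boot must be >= 1")
  if (cfg$realizations < 1) abort("realizations must be >= 1")
  if (has_real) {
    need <- c("samples", "landuse")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing)) {
      abort("inputs block missing: ", paste(missing, collapse = ", "))
    }
  }
  cfg
}

config_hash <- function(cfg) {
  # stable content hash of the materialized config (used to stamp outputs)
  substream_seed(0L, yaml::as.yaml(cfg))
}

write_output_csv <- function(df, path, stamp) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(stamp, con)
  if (is.null(df) || nrow(df) == 0L) {
    writeLines("# (no rows)", con)
    return(invisible(path))
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either synthetic or file inputs and writes the
#' report bundle under `out_dir`: descriptive summaries, threshold
#' exceedances, percentile loess curves, the land-use mixed-model table, the
#' percent-particulate models, homeostasis fits (global, TP bins, per-site),
#' discharge power-law exponents and their land-use regressions, stage
#' record-count ledger, and a JSON run manifest.
#'
#' @param config YAML path or config list (see [validate_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with every intermediate and fitted object.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# streamstoich %s config_hash %d seed %d",
                   PIPELINE_VERSION, config_hash(cfg), cfg$seed)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  counts <- list()

  # --- ingest ---------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    syn_cfg <- do.call(synthetic_config, c(cfg$synthetic, list(seed = cfg$seed)))
    landuse <- generate_landscape(syn_cfg)
    gen <- generate_samples(landuse, syn_cfg)
    records <- inject_censoring(gen$records, syn_cfg)
    truth <- gen$truth
    say("generated %d records at %d synthetic sites", nrow(records),
        nrow(landuse))
  } else {
    smp <- read_sample_table(cfg$inputs$samples)
    landuse <- read_landuse_table(cfg$inputs$landuse)
    records <- smp$records
    say("read %d records (%d rejects) and %d land-use profiles",
        nrow(records), nrow(smp$rejects), nrow(landuse))
    counts$rejects <- nrow(smp$rejects)
  }
  joined <- join_site_data(records, landuse)
  table <- joined$table
  counts$records_in <- nrow(records)
  counts$records_joined <- nrow(table)
  counts$orphans <- joined$n_orphans
  say("joined %d records (%d orphans)", nrow(table), joined$n_orphans)

  # --- consistency filter on reported values --------------------------
  # The filter precedes the Monte Carlo step: inconsistent records are
  # identified from the reported concentrations (less-than values at their
  # reporting limits), not from imputed draws.
  face_din <- compute_din(table$nh3n, table$nh4n, table$no3no2n)$din
  table$din <- face_din
  flt <- filter_inconsistent(table)
  filter_report <- flt$report
  table <- flt$records
  table$din <- NULL
  counts$records_filtered_out <- counts$records_joined - nrow(table)
  say("consistency filter removed %d of %d records",
      counts$records_filtered_out, counts$records_joined)

  # --- censoring imputation + derivation (per realization) ------------
  policy <- censoring_policy(cfg$censoring$cv_estimated,
                             cfg$censoring$lower_bound_lt)
  realizations <- vector("list", cfg$realizations)
  for (r in seq_len(cfg$realizations)) {
    rseed <- substream_seed(cfg$seed, "realization", r)
    imp <- impute_table(table, policy, seed = rseed)
    din0 <- compute_din(imp$records$nh3n, imp$records$nh4n,
                        imp$records$no3no2n)
    paired <- imp$records
    paired$din <- din0$din
    dist_n <- estimate_dom_proportions(paired, "N")
    dist_p <- estimate_dom_proportions(paired, "P")
    der <- derive_nutrients(imp$records, dist_n, dist_p,
                            n_boot = cfg$bootstrap$n_boot, seed = rseed,
                            apply_filter = FALSE)
    der$records$realization <- r
    realizations[[r]] <- list(imputation_log = imp$log, dist_n = dist_n,
                              dist_p = dist_p, derivation = der)
  }
  der1 <- realizations[[1]]$derivation
  derived <- do.call(rbind, lapply(realizations, function(z) z$derivation$records))
  counts$nonpositive_pn <- der1$n_nonpositive_pn
  counts$nonpositive_pp <- der1$n_nonpositive_pp
  say("non-positive particulate draws: %d PN, %d PP",
      der1$n_nonpositive_pn, der1$n_nonpositive_pp)

  # DOM-vs-landuse pooling gate on realization 1
  p1 <- realizations[[1]]
  site_prop_n <- stats::aggregate(
    proportion ~ site_id,
    data = data.frame(site_id = der1$records$site_id,
                      proportion = with(der1$records,
                                        (tdn - din) / (tn - din))),
    FUN = mean)
  dom_gate <- tryCatch(check_dom_vs_landuse(site_prop_n, landuse),
                       error = function(e) NULL)

  # --- metrics --------------------------------------------------------
  developed_pct <- 100 * (derived$p_cro + derived$p_hay + derived$p_urb)
  summaries <- summary_table(derived, developed_pct,
                             bins = list(c(5, 15), c(85, 95)))
  exceed <- exceedance_table(derived)
  loess_curves <- tryCatch(
    percentile_loess(developed_pct, derived$din,
                     window_halfwidth = cfg$loess$window_halfwidth,
                     span = cfg$loess$span, grid_step = cfg$loess$grid_step),
    error = function(e) list(curves = NULL, omitted = numeric(0)))

  # --- homeostasis and power laws -------------------------------------
  hfit <- fit_homeostasis(derived$np_dissolved, derived$np_particulate, "all")
  hbins <- withCallingHandlers(
    fit_homeostasis_by_tp_bin(derived, cfg$homeostasis$tp_low,
                              cfg$homeostasis$tp_high),
    warning = function(w) invokeRestart("muffleWarning"))
  hsite <- per_site_homeostasis(der1$records, cfg$homeostasis$min_site_n)
  say("global 1/H = %.4f (p = %.3g, n = %d)", hfit$slope_inv_h,
      hfit$p_value, hfit$n)

  pl <- list()
  for (rk in c("total", "dissolved", "particulate")) {
    pl[[rk]] <- fit_power_law_by_site(der1$records, rk, cfg$power_law$min_n)
  }
  pl_fits <- do.call(rbind, lapply(pl, function(z) z$fits))
  b_landuse <- if (!is.null(pl_fits) && nrow(pl_fits) >= 10) {
    regress_b_on_landuse(pl_fits, landuse)
  } else NULL

  # --- land-use mixed models ------------------------------------------
  lmm <- landuse_model_table(der1$records)
  frac_n <- fraction_particulate_model(der1$records, "N")
  frac_p <- fraction_particulate_model(der1$records, "P")
  say("fit %d land-use mixed models plus 2 percent-particulate models",
      length(lmm$fits))

  # --- outputs --------------------------------------------------------
  hrows <- function(f) if (is.null(f)) NULL else data.frame(
    subset = f$subset_label, inv_h = f$slope_inv_h, se = f$slope_se,
    intercept_log_c = f$intercept_log_c, p_value = f$p_value, n = f$n)
  homeo_tbl <- do.call(rbind, c(
    list(hrows(hfit), hrows(hbins$low_tp), hrows(hbins$high_tp)),
    make.row.names = FALSE))
  frac_rows <- function(f) {
    cc <- f$coefficients
    data.frame(response = f$response, term = cc$term, estimate = cc$estimate,
               ci_lo = cc$ci_lo, ci_hi = cc$ci_hi, p_value = cc$p_value)
  }
  outputs <- list(
    summary = summaries,
    exceedance = exceed,
    percentile_loess = loess_curves$curves,
    homeostasis = homeo_tbl,
    homeostasis_by_site = hsite$fits,
    power_law = pl_fits,
    power_law_vs_landuse = b_landuse,
    landuse_models = lmm$table,
    fraction_particulate = rbind(frac_rows(frac_n), frac_rows(frac_p)),
    dom_vs_landuse = dom_gate,
    filter_report = filter_report,
    imputation_log = p1$imputation_log,
    derived = derived
  )
  for (nm in names(outputs)) {
    write_output_csv(outputs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     stamp)
  }
  manifest <- list(
    pipeline_version = PIPELINE_VERSION,
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_boot = cfg$bootstrap$n_boot,
    realizations = cfg$realizations,
    counts = counts,
    global_inv_h = hfit$slope_inv_h
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(logline, file.path(out_dir, "run.log"))

  invisible(c(outputs, list(
    manifest = manifest, config = cfg, truth = truth, landuse = landuse,
    homeostasis_fit = hfit, homeostasis_bins = hbins,
    lmm_fits = lmm$fits, fraction_particulate_fits = list(N = frac_n, P = frac_p),
    realizations = realizations
  )))
}
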