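# Shared fixtures, all built in code.

# small synthetic world used by several tests
small_config <- function(seed = 11L, ...) {
  synthetic_config(n_sites = 30L, obs_per_site = 12L, seed = seed, ...)
}

uncensored <- function() {
  list(censor_estimated_rate = 0,
       detection_limits = c(nh3n = 0, nh4n = 0, no3no2n = 0, dip = 0,
                            tn = 0, tp = 0))
}

# generate -> censor -> join -> face-value filter -> impute -> derive,
# mirroring the pipeline's stage order, returning the derived table
derive_synthetic <- function(config, n_boot = 400L) {
  lu <- generate_landscape(config)
  gen <- generate_samples(lu, config)
  rec <- inject_censoring(gen$records, config)
  tab <- join_site_data(rec, lu)$table
  tab$din <- compute_din(tab$nh3n, tab$nh4n, tab$no3no2n)$din
  tab <- filter_inconsistent(tab)$records
  tab$din <- NULL
  imp <- impute_table(tab, censoring_policy(), seed = config$seed)$records
  imp$din <- compute_din(imp$nh3n, imp$nh4n, imp$no3no2n)$din
  dist_n <- estimate_dom_proportions(imp, "N")
  dist_p <- estimate_dom_proportions(imp, "P")
  imp$din <- NULL
  der <- derive_nutrients(imp, dist_n, dist_p, n_boot = n_boot,
                          seed = config$seed, apply_filter = FALSE)
  list(derived = der, landuse = lu, truth = gen$truth)
}

write_sample_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
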