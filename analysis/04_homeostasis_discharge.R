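#!/usr/bin/env Rscript
# Stage 4: stoichiometric homeostasis and discharge power laws.
#
# The global 1/H regression (log10 PN:PP on log10 DIN:DIP) over the spatial
# panel, refit within low- and high-TP bins; per-site 1/H for the densely
# sampled temporal panel (strictly more than 100 pairs per site); and
# site-specific N:P-discharge power-law exponents related to land use.

suppressMessages(library(streamstoich))

d <- utils::read.csv("results/derived_spatial.csv")
dt <- utils::read.csv("results/derived_temporal.csv")
lu <- read_landuse_table("results/data/landuse_spatial.csv")

hfit <- fit_homeostasis(d$np_dissolved, d$np_particulate, "all")
print(hfit)
hbins <- fit_homeostasis_by_tp_bin(d)
for (f in Filter(Negate(is.null), hbins)) print(f)
hrow <- function(f) data.frame(subset = f$subset_label, inv_h = f$slope_inv_h,
                               se = f$slope_se, log_c = f$intercept_log_c,
                               p_value = f$p_value, n = f$n)
utils::write.csv(do.call(rbind, lapply(Filter(Negate(is.null),
                                              c(list(hfit), hbins)), hrow)),
                 "results/homeostasis_global.csv", row.names = FALSE)

per_site <- per_site_homeostasis(dt, min_n = 100L)
utils::write.csv(per_site$fits, "results/homeostasis_by_site.csv",
                 row.names = FALSE)
cat(sprintf("per-site 1/H: %d eligible sites; range %.3f to %.3f\n",
            nrow(per_site$fits), min(per_site$fits$inv_h),
            max(per_site$fits$inv_h)))

pl <- do.call(rbind, lapply(c("total", "dissolved", "particulate"),
                            function(rk) fit_power_law_by_site(d, rk)$fits))
utils::write.csv(pl, "results/power_law_by_site.csv", row.names = FALSE)
for (rk in unique(pl$ratio_kind)) {
  b <- pl$b_exp[pl$ratio_kind == rk]
  cat(sprintf("b (%s N:P): median %+.3f, %d of %d sites with b > 0\n",
              rk, median(b), sum(b > 0), length(b)))
}

bl <- regress_b_on_landuse(pl, lu)
utils::write.csv(bl, "results/power_law_vs_landuse.csv", row.names = FALSE)
sig <- bl[!is.na(bl$p_value) & bl$p_value < 0.05, ]
cat(sprintf("b-vs-land-use regressions: %d of %d significant at 0.05\n",
            nrow(sig), nrow(bl)))
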