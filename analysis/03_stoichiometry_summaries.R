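#!/usr/bin/env Rscript
# Stage 3: descriptive stoichiometry and ecological threshold exceedance.
#
# Medians and IQRs per analyte and molar ratio, overall and in the 5-15%
# and 85-95% developed-land bands; the fraction of concentrations above
# each literature response threshold; and smoothed percentile curves of
# DIN along the developed-land gradient.

suppressMessages(library(streamstoich))

d <- utils::read.csv("results/derived_spatial.csv")

developed_pct <- 100 * (d$p_cro + d$p_hay + d$p_urb)
summaries <- summary_table(d, developed_pct, bins = list(c(5, 15), c(85, 95)))
utils::write.csv(summaries, "results/summary_stoichiometry.csv",
                 row.names = FALSE)
med <- function(v) summaries$median[summaries$group == "all" &
                                      summaries$variable == v]
cat(sprintf("medians: TN %.3f, DIN %.3f, TP %.4f, DIP %.4f mg/L\n",
            med("tn"), med("din"), med("tp"), med("dip")))
cat(sprintf("median molar ratios: TN:TP %.1f, DIN:DIP %.1f, PN:PP %.1f\n",
            med("np_total"), med("np_dissolved"), med("np_particulate")))

exceed <- exceedance_table(d)
utils::write.csv(exceed, "results/threshold_exceedance.csv", row.names = FALSE)
for (i in seq_len(nrow(exceed))) {
  cat(sprintf("%s > %.3f mg/L (%s): %.0f%% of %d values\n",
              exceed$analyte[i], exceed$threshold_mg_l[i],
              exceed$response[i], 100 * exceed$fraction[i], exceed$n[i]))
}

curves <- percentile_loess(developed_pct, d$din)
utils::write.csv(curves$curves, "results/percentile_loess_din.csv",
                 row.names = FALSE)
cat(sprintf("percentile loess: %d grid points retained, %d omitted as sparse\n",
            length(unique(curves$curves$x)), length(curves$omitted)))
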