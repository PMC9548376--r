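#!/usr/bin/env Rscript
# Ancillary assays over the fixtures from 01_simulate.R: PI DNA-content
# gating, 2^-ddCt fold changes, and the two-group nuclear-intensity
# comparison.

suppressMessages(library(fuccitrack))

ev <- read.csv("results/data/pi_events_wt.csv")
fr <- gate_dna_content(ev)
print(fr)

ct <- read.csv("results/data/ct_table.csv")
for (probe in c("CHD8_proximal", "CHD8_distal")) {
  print(ddct_fold_change(ct, probe))
}

fld <- simulate_nuclei_field(c(100, 57), c(114, 101), noise_sd = 19,
                             seed = 303)   # same seed as 01_simulate.R
qa <- quantify_rois(fld$images[[1]], fld$labels[[1]], group = "wt")
qb <- quantify_rois(fld$images[[2]], fld$labels[[2]], group = "mut")
pc <- percent_change(qa$mean_intensity, qb$mean_intensity)
message(sprintf(
  "nuclear intensity decrease: %.0f%% +/- %.0f%% (n = %d vs %d)",
  pc$percent_decrease, pc$sd, pc$n_a, pc$n_b))
t_res <- welch_t(qa$mean_intensity, qb$mean_intensity)
message(sprintf("unpaired t-test: t = %.1f, p = %.3g", t_res$t,
                t_res$p_value))

out <- list(
  flow = list(f_g0g1 = fr$f_g0g1, f_s = fr$f_s, f_g2m = fr$f_g2m,
              g2m_over_g0g1 = fr$g2m_over_g0g1),
  qpcr = lapply(c(proximal = "CHD8_proximal", distal = "CHD8_distal"),
                function(p) {
                  r <- ddct_fold_change(ct, p)
                  list(mean_fold = r$mean_fold, sd_fold = r$sd_fold,
                       percent_change = r$percent_change)
                }),
  chd8_if = list(percent_decrease = pc$percent_decrease, sd = pc$sd,
                 t = t_res$t, p = t_res$p_value))
jsonlite::write_json(out, "results/assays.json", auto_unbox = TRUE,
                     digits = NA)
message("report at results/assays.json")
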