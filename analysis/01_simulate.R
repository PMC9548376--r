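#!/usr/bin/env Rscript
# Simulate one wild-type and one CHD8+/- NPC FUCCI movie with exported
# ground truth, plus the ancillary assay fixtures (PI events, Ct tables,
# nuclei fields, allele sets). Movies go to results/data/ as multi-page
# TIFFs with JSON sidecars; tables as CSV; alleles as FASTA.

suppressMessages(library(fuccitrack))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

imaging <- imaging_config(n_frames = 280)   # 70 h at 15 min/frame, 256x256

for (gt in c("wt", "mut")) {
  model <- npc_model(gt)
  truth <- sample_lineages(model, n_founders = 12, t_total_min = 4200,
                           seed = if (gt == "wt") 101 else 102)
  rnd <- render_movie(truth, imaging, seed = if (gt == "wt") 201 else 202)
  stem <- file.path("results/data", paste0("npc_", gt))
  write_movie(rnd$movie, stem)
  write.csv(rnd$frames, paste0(stem, "_truth.csv"), row.names = FALSE)
  write_click_script(oracle_clicks(rnd), paste0(stem, "_clicks.csv"))
  message(sprintf("%s: %d cells, %d divisions in truth; movie at %s_*.tif",
                  model$genotype_label, nrow(truth$cells),
                  sum(!truth$cells$censored_end), stem))
}

# flow cytometry fixture: wt-like 2N/4N mixture
# 2% peak CV: the regime where strict threshold gating can return the
# generating fractions (see the methods vignette)
ev <- simulate_pi_events(c(0.55, 0.2, 0.25), cv = 0.02, n_events = 10000,
                         seed = 301)
write.csv(ev, "results/data/pi_events_wt.csv", row.names = FALSE)

# qPCR fixture: proximal probe at fold 0.51, distal at 0.66
ct <- simulate_ct_table(c(CHD8_proximal = 0.51, CHD8_distal = 0.66),
                        n_experiments = 3, replicates = 4, noise_sd = 0.05,
                        seed = 302)
write.csv(ct, "results/data/ct_table.csv", row.names = FALSE)

# immunofluorescence fixture: CHD8 staining contrast, wt vs mutant nuclei
fld <- simulate_nuclei_field(c(100, 57), c(114, 101), noise_sd = 19,
                             seed = 303)
write.csv(fld$truth, "results/data/nuclei_truth.csv", row.names = FALSE)

# allele fixture: 34 single-allele amplicons at the heterozygous composition,
# on an amplicon engineered so the +1 insertion creates a premature stop
amp <- example_amplicon()
alleles <- simulate_alleles(amp$ref,
                            list(type = "insertion", pos = amp$cut_site,
                                 seq = "C"),
                            n_wt = 15, n_mut = 19, seed = 304)
write_alleles(alleles, "results/data/alleles.fa")
writeLines(amp$ref, "results/data/amplicon_ref.txt")
message("assay fixtures written under results/data/")
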