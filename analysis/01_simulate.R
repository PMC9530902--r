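#!/usr/bin/env Rscript
# Stage 1 — simulate the raw study dataset.
#
# Builds the default strain panel (MDS mutators on the reduced-genome
# MDS42 background, KHK reduced genomes, MG mutators), draws true growth
# and mutation rates per medium from the trade-off law, and simulates the
# raw measurements: ~30-culture fluctuation assays with CFU dilution
# plates (3 replicates per condition) and 48-h OD595 growth curves
# (6 wells). Writes the raw CSVs and the generative truth under results/.

library(mutgrowth)

cfg <- default_config(seed = 1)
dir.create("results", showWarnings = FALSE)
write_config(cfg, "results/config.yaml")

panel <- make_strain_panel(cfg$panel_sizes, seed = stage_seed(cfg$seed, "panel"))
truth <- sample_true_rates(panel, medium_specs(cfg$media),
                           sigma_log10 = cfg$sigma_log10,
                           seed = stage_seed(cfg$seed, "rates"))
dataset <- simulate_dataset(truth, n_cultures = cfg$n_cultures,
                            n_replicates = cfg$n_replicates,
                            target_size_bp = cfg$target_size_bp,
                            m_target = cfg$m_target, n_plates = cfg$n_plates,
                            growth_noise_sd = cfg$growth_noise_sd,
                            n_wells = cfg$n_wells, duration_h = cfg$duration_h,
                            interval_h = cfg$interval_h,
                            seed = stage_seed(cfg$seed, "dataset"))

write.csv(truth, "results/true_rates.csv", row.names = FALSE)
write_assay_files(dataset, "results/fluctuation_counts.csv",
                  "results/cfu_plates.csv")
write_plate_reader_csv(dataset, "results/plate_reader.csv")

message(sprintf("Simulated %d strains x %d media: %d fluctuation assays, %d growth curves.",
                nrow(panel), length(cfg$media),
                length(dataset$assays) * cfg$n_replicates,
                length(dataset$curves) * cfg$n_wells))
message("True mutation rates span ",
        sprintf("%.1e - %.1e bp^-1 division^-1.",
                min(truth$m_true), max(truth$m_true)))
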