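#!/usr/bin/env Rscript
# Stage 4 — multiple linear regression.
#
# OLS of log10 mutation rate on (growth rate, medium code, genotype) and
# of growth rate on (log10 mutation rate, medium code, genotype), with the
# genotype coded interactively (flags multiplied) or additively (added).

library(mutgrowth)

tab <- read_rate_table("results/rate_table.csv")

unlink("results/mlr_coefficients.csv")  # rebuilt below
reports <- list()
for (resp in c("mutation", "growth")) {
  for (mode in c("interactive", "additive")) {
    rows <- encode_features(tab, mode)
    rep <- fit_mlr(rows, resp, mode)
    reports[[paste(resp, mode, sep = ".")]] <- rep
    co <- rep$coefficients
    co$response <- resp; co$mode <- mode
    co$adj_r_squared <- rep$adj_r_squared
    write.table(co, "results/mlr_coefficients.csv", sep = ",",
                append = file.exists("results/mlr_coefficients.csv"),
                col.names = !file.exists("results/mlr_coefficients.csv"),
                row.names = FALSE)
  }
}

message("Adjusted R2 of the four regressions:")
for (nm in names(reports)) {
  message(sprintf("  %-22s %.3f%s", nm, reports[[nm]]$adj_r_squared,
                  if (!reports[[nm]]$genotype_informative)
                    "  (genotype column non-informative)" else ""))
}
gt <- reports$mutation.additive$coefficients
message(sprintf("Additive-mode genotype effect on log10 mutation rate: %+0.2f per disturbance (p = %.2g).",
                gt$estimate[gt$term == "genotype_value"],
                gt$p[gt$term == "genotype_value"]))
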