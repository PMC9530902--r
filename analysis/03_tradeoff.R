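#!/usr/bin/env Rscript
# Stage 3 — the trade-off analysis.
#
# Per-medium OLS fits of log10(mutation rate) on growth rate (slope alpha
# and maximal rate M_inf), paired medium-shift tests on the mutation-rate
# distributions, cross-media rate correlations, parent-vs-derivative fold
# changes, and the mutations-per-genome arithmetic.

library(mutgrowth)

tab <- read_rate_table("results/rate_table.csv")
media <- medium_specs()

fits <- lapply(media$name, function(m) fit_tradeoff(tab, m))
names(fits) <- media$name
fit_tab <- tradeoff_fit_table(fits)
write.csv(fit_tab, "results/tradeoff_fits.csv", row.names = FALSE)

message("Per-medium trade-off fits (alpha, M_inf, Pearson r):")
for (i in seq_len(nrow(fit_tab))) {
  message(sprintf("  %-4s alpha %7.2f (true %6.1f)  M_inf %8.2e (true %8.2e)  r = %.3f, p = %.2g",
                  fit_tab$medium[i], fit_tab$alpha[i], media$alpha_true[i],
                  fit_tab$m_inf[i], media$m_inf_true[i],
                  fit_tab$pearson_r[i], fit_tab$p_value[i]))
}
mpg <- mutations_per_genome(fit_tab$m_inf, 4e6)
message(sprintf("Mutations per genome per division at the fitted M_inf: %s (LB exceeds 1,000: %s).",
                paste(sprintf("%s %.0f", fit_tab$medium, mpg), collapse = ", "),
                mpg[fit_tab$medium == "LB"] > 1000))

# medium shifts of the mutation-rate distributions, per collection
shifts <- do.call(rbind, lapply(c("MDS", "KHK", "MG"), function(cl) {
  sub <- tab[tab$collection == cl, ]
  s <- compare_media_distributions(sub, "LB", "M63")
  data.frame(collection = cl, medium_a = "LB", medium_b = "M63",
             median_log10_shift = s$median_log10_shift, p_value = s$p_value,
             n_pairs = s$n_pairs)
}))
write.csv(shifts, "results/medium_shifts.csv", row.names = FALSE)
message("LB-vs-M63 mutation-rate shifts by collection (positive = higher in LB):")
for (i in seq_len(nrow(shifts))) {
  message(sprintf("  %-3s shift %+0.2f decades, p = %.2g (n = %d)",
                  shifts$collection[i], shifts$median_log10_shift[i],
                  shifts$p_value[i], shifts$n_pairs[i]))
}

cm <- rbind(cbind(kind = "growth", cross_media_correlation(tab, "growth")),
            cbind(kind = "mutation", cross_media_correlation(tab, "mutation")))
write.csv(cm, "results/cross_media_correlations.csv", row.names = FALSE)
pooled <- cm[cm$collection == "pooled", ]
message(sprintf("Cross-media correlations (pooled): all positive = %s; range %.2f-%.2f.",
                all(pooled$r > 0), min(pooled$r), max(pooled$r)))

panel <- unique(tab[, c("strain_id", "collection")])
pm <- c(MDS = "MDS42", KHK = "W3110", MG = "MG1655")
parent_map <- setNames(pm[panel$collection[!(panel$strain_id %in% pm)]],
                       panel$strain_id[!(panel$strain_id %in% pm)])
fc <- disturbance_fold_changes(tab, parent_map)
write.csv(fc, "results/fold_changes.csv", row.names = FALSE)
message(sprintf("Fold changes vs parent (LB): median mutation %+0.2f decades, median growth %+0.2f decades.",
                median(fc$log10_mutation_ratio[fc$medium == "LB"]),
                median(fc$log10_growth_ratio[fc$medium == "LB"])))
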