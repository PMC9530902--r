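#!/usr/bin/env Rscript
# Stage 5 — medium and genotype classification.
#
# Support vector machines (linear and RBF kernels) on the two features
# (growth rate, log10 mutation rate): per repeat a stratified 60/40
# train/test split, hyperparameters from 5-fold nested cross-validation
# over the 0.001-100 grid scored by macro-averaged recall, accuracy from
# the test confusion matrix; five repeats. Also exports an RBF decision
# landscape over the rate plane.

library(mutgrowth)

tab <- read_rate_table("results/rate_table.csv")
rows <- encode_features(tab, "interactive")

res <- list()
for (target in c("medium", "genotype")) {
  for (kernel in c("linear", "rbf")) {
    res[[paste(target, kernel, sep = ".")]] <-
      classify(rows, target, kernel, n_repeats = 5, seed = 1)
  }
}

summary_tab <- do.call(rbind, lapply(names(res), function(nm) {
  r <- res[[nm]]
  data.frame(target = r$target, kernel = r$kernel,
             mean_accuracy = r$mean_accuracy,
             min_accuracy = min(r$accuracies),
             max_accuracy = max(r$accuracies),
             C = r$hyperparameters[[5]]$C,
             gamma = r$hyperparameters[[5]]$gamma)
}))
write.csv(summary_tab, "results/svm_accuracy.csv", row.names = FALSE)

message("Test accuracy (mean over 5 repeats):")
for (i in seq_len(nrow(summary_tab))) {
  message(sprintf("  %-8s %-6s %.3f (range %.2f-%.2f)",
                  summary_tab$target[i], summary_tab$kernel[i],
                  summary_tab$mean_accuracy[i], summary_tab$min_accuracy[i],
                  summary_tab$max_accuracy[i]))
}
message(sprintf("RBF >= linear for medium classification: %s.",
                res$medium.rbf$mean_accuracy >= res$medium.linear$mean_accuracy))

land <- decision_landscape(res$medium.rbf,
                           mu_range = range(rows$mu),
                           log10_m_range = range(rows$log10_m),
                           grid_n = 120)
write.csv(land, "results/medium_decision_landscape.csv", row.names = FALSE)
message(sprintf("Decision landscape: %d nodes, classes present: %s.",
                nrow(land), paste(sort(unique(land$label)), collapse = ", ")))

conf <- res$genotype.rbf$confusion
write.csv(as.data.frame.matrix(conf), "results/genotype_confusion.csv")
message(sprintf("Genotype RBF confusion: %.0f%% of test rows on the diagonal.",
                100 * sum(diag(conf)) / sum(conf)))
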