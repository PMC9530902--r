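test_that("feature encoding follows the fixed medium and genotype rules", {
  tab <- manual_rate_table(c("a", "b", "c"), c("LB", "MAA", "M63"),
                           growth = 0.5, mutation = 1e-8)
  tab$genome_reduced <- rep(c(1L, 0L, 1L), 3)
  tab$mmr_deficient <- rep(c(0L, 1L, 1L), 3)
  tab$genotype_class <- genotype_class(tab$genome_reduced, tab$mmr_deficient)

  inter <- encode_features(tab, "interactive")
  addi <- encode_features(tab, "additive")
  expect_equal(unique(inter$medium_code[inter$medium_label == "LB"]), 1)
  expect_equal(unique(inter$medium_code[inter$medium_label == "MAA"]), 0)
  expect_equal(unique(inter$medium_code[inter$medium_label == "M63"]), -1)
  # reduced genome, non-mutator: 1 x 0 = 0 interactive, 1 + 0 = 1 additive
  expect_equal(inter$genotype_value[1], 0)
  expect_equal(addi$genotype_value[1], 1)
  # doubly disturbed: 1 x 1 = 1, 1 + 1 = 2
  expect_equal(inter$genotype_value[3], 1)
  expect_equal(addi$genotype_value[3], 2)
  expect_equal(inter$log10_m, rep(-8, 9))
  # the two modes differ only in genotype_value
  expect_identical(inter[setdiff(names(inter), "genotype_value")],
                   addi[setdiff(names(addi), "genotype_value")])
})

test_that("MLR recovers generating coefficients exactly on noiseless data", {
  panel <- make_strain_panel(seed = 2)
  tab <- truth_as_rate_table(sample_true_rates(panel, sigma_log10 = 0.1,
                                               seed = 2))
  rows <- encode_features(tab, "additive")
  # construct the response as a known linear combination
  rows$log10_m <- -4 + 2 * rows$mu - 1.5 * rows$medium_code +
    0.25 * rows$genotype_value
  rep <- fit_mlr(rows, "mutation", "additive")
  est <- setNames(rep$coefficients$estimate, rep$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), -4, tolerance = 1e-9)
  expect_equal(unname(est["mu"]), 2, tolerance = 1e-9)
  expect_equal(unname(est["medium_code"]), -1.5, tolerance = 1e-9)
  expect_equal(unname(est["genotype_value"]), 0.25, tolerance = 1e-9)
  expect_equal(rep$adj_r_squared, 1, tolerance = 1e-9)
})

test_that("MLR on the default synthetic panel explains the mutation rate", {
  panel <- make_strain_panel(seed = 5)
  tab <- truth_as_rate_table(sample_true_rates(panel, sigma_log10 = 0.2,
                                               seed = 5))
  for (mode in c("interactive", "additive")) {
    rep <- fit_mlr(encode_features(tab, mode), "mutation", mode)
    expect_gt(rep$adj_r_squared, 0.8)
    expect_equal(rep$n, nrow(tab))
  }
})

test_that("a constant genotype column is flagged, not fatal", {
  # KHK-only panel: no doubly disturbed strains, so interactive coding is 0
  panel <- make_strain_panel(c(KHK = 10), seed = 3)
  tab <- truth_as_rate_table(sample_true_rates(panel, sigma_log10 = 0.2,
                                               seed = 3))
  rows <- encode_features(tab, "interactive")
  expect_true(all(rows$genotype_value == 0))
  rep <- fit_mlr(rows, "mutation", "interactive")
  expect_false(rep$genotype_informative)
  expect_false("genotype_value" %in% rep$coefficients$term)
})

test_that("degenerate designs raise a singularity error naming the column", {
  panel <- make_strain_panel(c(MDS = 10), seed = 4)
  tab <- truth_as_rate_table(sample_true_rates(panel, medium_specs("LB"),
                                               sigma_log10 = 0.2, seed = 4))
  rows <- encode_features(tab, "additive")
  expect_error(fit_mlr(rows, "mutation", "additive"), "medium_code")
})

test_that("well-separated clusters are classified perfectly by both kernels", {
  n <- 20
  mk <- function(medium, mu0, lm0, seed) {
    manual_rate_table(paste0(medium, 1:n), medium,
                      growth = mu0 + runif_seeded(n, -0.01, 0.01, seed),
                      mutation = 10^(lm0 + runif_seeded(n, -0.05, 0.05,
                                                        seed + 1)))
  }
  tab <- rbind(mk("LB", 0.7, -7, 1), mk("MAA", 0.4, -8.5, 3),
               mk("M63", 0.15, -10, 5))
  rows <- encode_features(tab, "interactive")
  for (kernel in c("linear", "rbf")) {
    rep <- classify(rows, "medium", kernel, seed = 11)
    expect_equal(rep$mean_accuracy, 1.0)
    expect_length(rep$accuracies, 5)
    # confusion-matrix rows sum to the per-class test counts over repeats
    expect_equal(unname(rowSums(rep$confusion)), rep(5 * 8, 3))
  }
})

test_that("shuffled labels score at the chance floor", {
  n <- 60
  tab <- manual_rate_table(paste0("s", 1:n), "LB",
                           growth = runif_seeded(n, 0.1, 0.8, seed = 7),
                           mutation = 10^runif_seeded(n, -10, -7, seed = 8))
  rows <- encode_features(tab, "interactive")
  rows$medium_label <- withr::with_seed(15,
    sample(rep(c("LB", "MAA", "M63"), each = n / 3)))
  rep <- classify(rows, "medium", "linear", seed = 19)
  n_test <- n * 0.4
  se <- sqrt((1 / 3) * (2 / 3) / (5 * n_test))
  expect_lt(abs(rep$mean_accuracy - 1 / 3), 3 * se)
})

test_that("classification protocol is deterministic for a fixed seed", {
  tab <- truth_as_rate_table(sample_true_rates(make_strain_panel(seed = 6),
                                               sigma_log10 = 0.2, seed = 6))
  rows <- encode_features(tab, "interactive")
  r1 <- classify(rows, "medium", "linear", seed = 33)
  r2 <- classify(rows, "medium", "linear", seed = 33)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  r3 <- classify(rows, "medium", "linear", seed = 34)
  expect_false(identical(r1$splits, r3$splits))
})

test_that("fixed-hyperparameter mode uses the reference values", {
  expect_equal(reference_hyperparameters("medium", "linear")$C, 10)
  expect_equal(reference_hyperparameters("genotype", "linear")$C, 100)
  expect_equal(reference_hyperparameters("medium", "rbf"), list(C = 10, gamma = 1))
  expect_equal(reference_hyperparameters("genotype", "rbf"),
               list(C = 100, gamma = 0.01))
  tab <- truth_as_rate_table(sample_true_rates(make_strain_panel(seed = 6),
                                               sigma_log10 = 0.2, seed = 6))
  rows <- encode_features(tab, "interactive")
  rep <- classify(rows, "genotype", "rbf", fixed = TRUE, seed = 1)
  expect_true(all(vapply(rep$hyperparameters, function(h) h$C, 1) == 100))
  expect_true(all(vapply(rep$hyperparameters, function(h) h$gamma, 1) == 0.01))
})

test_that("classification refuses a single-class target", {
  tab <- manual_rate_table(paste0("s", 1:10), "LB",
                           growth = runif_seeded(10, 0.2, 0.8, 1),
                           mutation = 1e-8)
  expect_error(classify(encode_features(tab, "interactive"), "medium"),
               ">= 2 classes")
})

test_that("a linear decision landscape changes label monotonically", {
  n <- 15
  tab <- rbind(
    manual_rate_table(paste0("a", 1:n), "LB",
                      growth = runif_seeded(n, 0.55, 0.8, 2),
                      mutation = 10^runif_seeded(n, -8, -7, 3)),
    manual_rate_table(paste0("b", 1:n), "M63",
                      growth = runif_seeded(n, 0.1, 0.35, 4),
                      mutation = 10^runif_seeded(n, -10.5, -9.5, 5)))
  rows <- encode_features(tab, "interactive")
  rep <- classify(rows, "medium", "linear", seed = 3)
  land <- decision_landscape(rep, mu_range = c(0, 1),
                             log10_m_range = c(-11, -6), grid_n = 40)
  expect_equal(nrow(land), 1600)
  # along every horizontal grid line the 2-class label flips at most once
  for (lm_val in unique(land$log10_m)) {
    lab <- land$label[land$log10_m == lm_val]
    expect_lte(sum(lab[-1] != lab[-length(lab)]), 1)
  }
  single <- decision_landscape(rep, grid_n = 1)
  expect_equal(nrow(single), 1)
  expect_true(single$label %in% c("LB", "M63"))
})
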