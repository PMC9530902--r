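test_that("noiseless tables are fitted exactly", {
  tab <- noiseless_rate_table(n_strains = 8)
  media <- medium_specs()
  for (i in seq_len(nrow(media))) {
    fit <- fit_tradeoff(tab, media$name[i])
    expect_equal(fit$alpha, media$alpha_true[i], tolerance = 1e-9)
    expect_equal(log10(fit$m_inf), log10(media$m_inf_true[i]),
                 tolerance = 1e-9)
    expect_equal(fit$pearson_r, -1, tolerance = 1e-9)
    expect_equal(fit$n_points, 8)
  }
})

test_that("three collinear points give a perfect negative correlation", {
  tab <- manual_rate_table(c("a", "b", "c"), "LB",
                           growth = c(0.2, 0.5, 0.8),
                           mutation = 10^(-3 - 9.5 * c(0.2, 0.5, 0.8)))
  fit <- fit_tradeoff(tab, "LB")
  expect_equal(fit$pearson_r, -1, tolerance = 1e-9)
  expect_lt(fit$alpha, 0)
})

test_that("fit_tradeoff validates its inputs", {
  tab <- manual_rate_table(c("a", "b"), "LB", growth = c(0.2, 0.5),
                           mutation = c(1e-8, 1e-9))
  expect_error(fit_tradeoff(tab, "LB"), ">= 3 strains")
  tab3 <- manual_rate_table(c("a", "b", "c"), "LB", growth = rep(0.5, 3),
                            mutation = c(1e-8, 1e-9, 1e-10))
  expect_error(fit_tradeoff(tab3, "LB"), "degenerate")
})

test_that("slope recovery is unbiased and its CI well-calibrated", {
  # 50 seeded replicates of the 20-strain recovery protocol per medium:
  # the median recovered slope should sit within 5% of the generative value
  # and the 95% CI should cover it at a nominal rate
  media <- medium_specs()
  n_rep <- 50
  alpha_hat <- m_inf_err <- matrix(NA_real_, n_rep, nrow(media))
  covered <- matrix(NA, n_rep, nrow(media))
  for (r in seq_len(n_rep)) {
    panel <- make_strain_panel(c(MDS = 7, KHK = 7, MG = 6), seed = r)
    tab <- truth_as_rate_table(sample_true_rates(panel, sigma_log10 = 0.2,
                                                 seed = 1000 + r))
    for (i in seq_len(nrow(media))) {
      fit <- fit_tradeoff(tab, media$name[i])
      alpha_hat[r, i] <- fit$alpha
      m_inf_err[r, i] <- log10(fit$m_inf) - log10(media$m_inf_true[i])
      covered[r, i] <- media$alpha_true[i] >= fit$alpha_ci[1] &&
        media$alpha_true[i] <= fit$alpha_ci[2]
    }
  }
  for (i in seq_len(nrow(media))) {
    expect_lt(abs(median(alpha_hat[, i]) - media$alpha_true[i]) /
                abs(media$alpha_true[i]), 0.05)
    expect_lt(abs(median(m_inf_err[, i])), 0.3)
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("the fit is invariant to row order and strain relabeling", {
  tab <- truth_as_rate_table(sample_true_rates(
    make_strain_panel(c(KHK = 10), seed = 8), sigma_log10 = 0.2, seed = 8))
  f1 <- fit_tradeoff(tab, "MAA")
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  f2 <- fit_tradeoff(shuffled, "MAA")
  relabeled <- tab; relabeled$strain_id <- paste0("x", relabeled$strain_id)
  f3 <- fit_tradeoff(relabeled, "MAA")
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
  expect_equal(f1$alpha, f3$alpha, tolerance = 1e-12)
})

test_that("prediction inverts the fitted line", {
  fit <- structure(list(alpha = -9.5, m_inf = 1e-3), class = "tradeoff_fit")
  expect_equal(predict_mutation_rate(fit, 0), 1e-3)
  expect_equal(predict_mutation_rate(fit, 0.5), 10^(-3 - 4.75),
               tolerance = 1e-12)
  # invert the prediction for mu and recover the input
  mu <- 0.37
  m <- predict_mutation_rate(fit, mu)
  expect_equal((log10(m) - log10(fit$m_inf)) / fit$alpha, mu,
               tolerance = 1e-9)
})

test_that("mutations-per-genome arithmetic matches the rate decades", {
  expect_equal(mutations_per_genome(1e-3, 4e6), 4000)
  expect_gt(mutations_per_genome(1e-3, 4e6), 1000)
  expect_equal(mutations_per_genome(7e-6, 4e6), 28)
  expect_equal(mutations_per_genome(1e-3, 0), 0)
})

test_that("identical distributions give zero shift and p = 1", {
  tab <- manual_rate_table(letters[1:5], c("LB", "M63"),
                           growth = rep(c(0.6, 0.2), each = 5),
                           mutation = rep(10^-(5:9), 2))
  res <- compare_media_distributions(tab, "LB", "M63")
  expect_equal(res$median_log10_shift, 0)
  expect_equal(res$p_value, 1)
})

test_that("medium shifts carry the collection-specific sign", {
  # mutator-like panel: rates elevated in rich medium by half a decade
  n <- 13
  mut_m63 <- 10^runif_seeded(n, -9, -7, seed = 41)
  tab_up <- rbind(
    manual_rate_table(paste0("s", 1:n), "LB", growth = 0.6,
                      mutation = mut_m63 * 10^0.5, md = 1L),
    manual_rate_table(paste0("s", 1:n), "M63", growth = 0.2,
                      mutation = mut_m63, md = 1L))
  up <- compare_media_distributions(tab_up, "LB", "M63")
  expect_equal(up$median_log10_shift, 0.5, tolerance = 1e-9)
  expect_lt(up$p_value, 0.05)

  # reduced-genome-like panel: rates higher in the poor medium
  tab_down <- rbind(
    manual_rate_table(paste0("s", 1:n), "LB", growth = 0.6,
                      mutation = mut_m63 / 3, gr = 1L),
    manual_rate_table(paste0("s", 1:n), "M63", growth = 0.2,
                      mutation = mut_m63, gr = 1L))
  down <- compare_media_distributions(tab_down, "LB", "M63")
  expect_lt(down$median_log10_shift, 0)
})

test_that("cross-media correlations detect preserved orderings", {
  # identical rates across media correlate perfectly
  base <- 10^-(4:8)
  tab <- do.call(rbind, lapply(c("LB", "MAA", "M63"), function(m)
    manual_rate_table(letters[1:5], m, growth = seq(0.2, 0.6, by = 0.1),
                      mutation = base)))
  cm <- cross_media_correlation(tab, "mutation")
  expect_true(all(abs(cm$r - 1) < 1e-9))

  # 2 shared strains only: every pair is skipped with a warning
  tab2 <- tab[tab$strain_id %in% c("a", "b") | tab$medium == "LB", ]
  w <- capture_warnings(res <- cross_media_correlation(tab2, "mutation"))
  expect_true(any(grepl("fewer than 3 shared strains", w)))
  expect_null(res)
})

test_that("fold changes are log10 ratios against the mapped parent", {
  tab <- manual_rate_table(c("P", "D1", "D2"), c("LB", "M63"),
                           growth = c(0.6, 0.3, 0.6, 0.2, 0.1, 0.2),
                           mutation = c(1e-9, 1e-7, 1e-9, 1e-8, 1e-6, 1e-8))
  fc <- disturbance_fold_changes(tab, c(D1 = "P", D2 = "P"))
  d1_lb <- fc[fc$strain_id == "D1" & fc$medium == "LB", ]
  expect_equal(d1_lb$log10_mutation_ratio, 2)          # 100x the parent
  expect_equal(d1_lb$log10_growth_ratio, log10(0.5))   # half the parent
  d2 <- fc[fc$strain_id == "D2", ]
  expect_true(all(d2$log10_mutation_ratio == 0))
  expect_error(disturbance_fold_changes(tab, c(D1 = "missing")),
               "missing")
})

test_that("synthetic mutators show raised mutation and lowered growth vs parent", {
  panel <- make_strain_panel(c(MDS = 10), seed = 9)
  tab <- truth_as_rate_table(sample_true_rates(panel, sigma_log10 = 0.1,
                                               seed = 9))
  fc <- disturbance_fold_changes(tab, default_parent_map(panel))
  lb <- fc[fc$medium == "LB", ]
  expect_gt(median(lb$log10_mutation_ratio), 0)
  expect_lt(median(lb$log10_growth_ratio), 0)
})
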