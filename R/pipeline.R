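#' Default pipeline configuration
#'
#' All knobs of the end-to-end synthetic run in one flat list: panel sizes,
#' per-medium trade-off parameters (via [medium_specs()]), generative noise,
#' fluctuation-assay and growth-assay settings, estimator options, and the
#' global seed from which every stage seed is derived.
#'
#' @param seed global integer seed.
#' @return named list (class `mutgrowth_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    panel_sizes = c(MDS = 14, KHK = 10, MG = 10),
    media = c("LB", "MAA", "M63"),
    sigma_log10 = 0.2,
    n_cultures = 30,
    n_replicates = 3,
    target_size_bp = 30,
    m_target = 2,
    n_plates = 4,
    growth_noise_sd = 0.002,
    n_wells = 6,
    duration_h = 48,
    interval_h = 0.5,
    window_points = 7,
    r2_min = 0.98,
    mle_n_max = 500,
    genome_size_bp = 4e6,
    svm_repeats = 5,
    svm_split = 0.6,
    cv_grid = 10^(-3:2)
  ), class = "mutgrowth_config")
}

#' Write / read a pipeline configuration
#'
#' Flat key/value YAML; a config round-trips unchanged.
#'
#' @param config configuration list.
#' @param path file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$panel_sizes <- as.list(cfg$panel_sizes)  # keep names through YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$panel_sizes <- unlist(cfg$panel_sizes)
  cfg$media <- unlist(cfg$media)
  cfg$cv_grid <- as.numeric(unlist(cfg$cv_grid))
  structure(cfg, class = "mutgrowth_config")
}

#' Assemble the tidy rate table from a raw synthetic dataset
#'
#' Runs the estimation layer over every strain x medium condition:
#' fluctuation assays through the MSS maximum-likelihood estimator and CFU
#' sizing (replicates averaged, SE over replicates), growth curves through
#' the windowed log-linear fitter (wells aggregated).
#'
#' @param dataset list from [simulate_dataset()].
#' @param mle_n_max pmf truncation used by the MLE.
#' @param window_points,r2_min growth-fitter settings.
#' @return tidy rate table: one row per (strain, medium) with columns
#'   `collection`, `strain_id`, `genome_reduced`, `mmr_deficient`,
#'   `genotype_class`, `medium`, `growth_rate`, `growth_se`,
#'   `mutation_rate`, `mutation_se`, `n_replicates`.
#' @export
assemble_rate_table <- function(dataset, mle_n_max = 500,
                                window_points = 7, r2_min = 0.98) {
  rates <- dataset$rates
  out <- rates[, c("collection", "strain_id", "genome_reduced",
                   "mmr_deficient", "genotype_class", "medium")]
  out$growth_rate <- out$growth_se <- NA_real_
  out$mutation_rate <- out$mutation_se <- NA_real_
  out$n_replicates <- NA_integer_
  for (i in seq_len(nrow(rates))) {
    reps <- dataset$assays[[i]]
    per_rep <- vapply(reps, function(rp) {
      mutation_rate_from_assay(rp$assay, plates = rp$plates,
                               n_max = mle_n_max)$mutation_rate
    }, numeric(1))
    mu_est <- combine_replicates(per_rep)
    gfit <- growth_rate_replicates(dataset$curves[[i]],
                                   window_points = window_points,
                                   r2_min = r2_min)
    out$mutation_rate[i] <- mu_est$mean
    out$mutation_se[i] <- mu_est$se
    out$growth_rate[i] <- gfit$rate
    out$growth_se[i] <- gfit$se
    out$n_replicates[i] <- mu_est$n
  }
  out
}

#' Write / read the tidy rate table
#'
#' CSV with the canonical header `collection,strain,genome_reduced,
#' mmr_deficient,medium,growth_rate,growth_se,mutation_rate,mutation_se,
#' n_replicates`.
#'
#' @param table rate table.
#' @param path file path.
#' @return `read_rate_table` returns the table with internal column names.
#' @export
write_rate_table <- function(table, path) {
  out <- data.frame(collection = table$collection, strain = table$strain_id,
                    genome_reduced = table$genome_reduced,
                    mmr_deficient = table$mmr_deficient,
                    medium = table$medium,
                    growth_rate = table$growth_rate,
                    growth_se = table$growth_se,
                    mutation_rate = table$mutation_rate,
                    mutation_se = table$mutation_se,
                    n_replicates = table$n_replicates)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "strain"] <- "strain_id"
  tab$genotype_class <- genotype_class(tab$genome_reduced, tab$mmr_deficient)
  tab
}

#' Write raw fluctuation-assay records
#'
#' Two CSVs: per-culture mutant counts (`assay_id,culture_index,
#' mutant_count`) and CFU plates (`assay_id,plate_index,dilution,
#' colony_count`).
#'
#' @param dataset list from [simulate_dataset()].
#' @param counts_path,plates_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_assay_files <- function(dataset, counts_path, plates_path) {
  counts <- list(); plates <- list()
  for (cond in names(dataset$assays)) {
    reps <- dataset$assays[[cond]]
    for (r in seq_along(reps)) {
      id <- paste(cond, r, sep = ".")
      cts <- reps[[r]]$assay$mutant_counts
      counts[[id]] <- data.frame(assay_id = id,
                                 culture_index = seq_along(cts),
                                 mutant_count = cts)
      pl <- reps[[r]]$plates
      plates[[id]] <- data.frame(assay_id = id, pl)
    }
  }
  utils::write.csv(do.call(rbind, counts), counts_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, plates), plates_path, row.names = FALSE)
  invisible(c(counts_path, plates_path))
}

#' Write plate-reader growth curves
#'
#' One CSV per strain x medium is wasteful at panel scale, so all wells go
#' in one long CSV: first column `time_h`, then one column per well named
#' `<strain>.<medium>.<well>`.
#'
#' @param dataset list from [simulate_dataset()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_plate_reader_csv <- function(dataset, path) {
  t <- dataset$curves[[1]][[1]]$times
  cols <- list(time_h = t)
  for (cond in names(dataset$curves)) {
    for (cv in dataset$curves[[cond]]) {
      cols[[paste(cond, cv$well_id, sep = ".")]] <- cv$od
    }
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' simulate -> estimate (fluctuation + growth) -> rate table -> per-medium
#' trade-off fits -> multiple linear regression (both genotype modes, both
#' responses) -> classification (both kernels, both targets) -> report.
#' Deterministic for a fixed config (all stage seeds derive from
#' `config$seed`).
#'
#' @param config configuration from [default_config()].
#' @param outdir optional directory; when given, the rate table, raw assay
#'   files, plate-reader CSV, fit report and fold-change CSVs are written
#'   there and listed in the report manifest.
#' @param quiet suppress per-stage log lines.
#' @return list of class `run_report`: `config`, `truth` (true rates),
#'   `rate_table`, `tradeoff_fits`, `recovery` (true vs recovered alpha and
#'   log10 m_inf per medium), `shift_tests`, `cross_media`, `fold_changes`,
#'   `mlr` (4 reports), `svm` (list or NULL with `svm_skipped` reason),
#'   `mutations_per_genome`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    if (!quiet) {
      message(sprintf("[%s] %s (%.1fs elapsed)", stage, msg,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  media <- medium_specs(config$media)

  panel <- make_strain_panel(config$panel_sizes,
                             seed = stage_seed(config$seed, "panel"))
  truth <- sample_true_rates(panel, media, sigma_log10 = config$sigma_log10,
                             seed = stage_seed(config$seed, "rates"))
  log_stage("simulate", sprintf("%d strains x %d media", nrow(panel),
                                nrow(media)))
  dataset <- simulate_dataset(truth, n_cultures = config$n_cultures,
                              n_replicates = config$n_replicates,
                              target_size_bp = config$target_size_bp,
                              m_target = config$m_target,
                              n_plates = config$n_plates,
                              growth_noise_sd = config$growth_noise_sd,
                              n_wells = config$n_wells,
                              duration_h = config$duration_h,
                              interval_h = config$interval_h,
                              seed = stage_seed(config$seed, "dataset"))
  log_stage("simulate", sprintf("%d assays, %d growth curves",
                                length(dataset$assays) * config$n_replicates,
                                length(dataset$curves) * config$n_wells))

  rate_table <- assemble_rate_table(dataset, mle_n_max = config$mle_n_max,
                                    window_points = config$window_points,
                                    r2_min = config$r2_min)
  log_stage("estimate", sprintf("rate table with %d rows", nrow(rate_table)))

  fits <- lapply(media$name, function(m) fit_tradeoff(rate_table, m))
  names(fits) <- media$name
  recovery <- data.frame(
    medium = media$name,
    alpha_true = media$alpha_true,
    alpha_hat = vapply(fits, function(f) f$alpha, numeric(1)),
    log10_m_inf_true = log10(media$m_inf_true),
    log10_m_inf_hat = vapply(fits, function(f) log10(f$m_inf), numeric(1)),
    row.names = NULL)
  log_stage("tradeoff", paste("alpha =", paste(
    sprintf("%.2f", recovery$alpha_hat), collapse = ", ")))

  shift_tests <- NULL
  cross_media <- NULL
  if (nrow(media) >= 2L) {
    prs <- utils::combn(media$name, 2, simplify = FALSE)
    shift_tests <- lapply(prs, function(pr) {
      c(list(medium_a = pr[1], medium_b = pr[2]),
        compare_media_distributions(rate_table, pr[1], pr[2]))
    })
    cross_media <- list(
      growth = cross_media_correlation(rate_table, "growth"),
      mutation = cross_media_correlation(rate_table, "mutation"))
  }
  fold_changes <- disturbance_fold_changes(rate_table,
                                           default_parent_map(panel))

  mlr <- list(); mlr_skipped <- NULL
  for (resp in c("mutation", "growth")) {
    for (mode in c("interactive", "additive")) {
      key <- paste(resp, mode, sep = ".")
      rows <- encode_features(rate_table, mode)
      res <- tryCatch(fit_mlr(rows, resp, mode), error = function(e) e)
      if (inherits(res, "error")) {
        # e.g. a single-medium run makes medium_code constant
        mlr_skipped <- c(mlr_skipped,
                         stats::setNames(conditionMessage(res), key))
      } else {
        mlr[[key]] <- res
      }
    }
  }
  if (length(mlr) > 0L) {
    log_stage("regression", paste("adjusted R2:", paste(
      sprintf("%s %.3f", names(mlr),
              vapply(mlr, function(m) m$adj_r_squared, numeric(1))),
      collapse = ", ")))
  }

  svm <- NULL; svm_skipped <- NULL
  rows <- encode_features(rate_table, "interactive")
  for (target in c("medium", "genotype")) {
    for (kernel in c("linear", "rbf")) {
      key <- paste(target, kernel, sep = ".")
      res <- tryCatch(
        classify(rows, target, kernel, split_fraction = config$svm_split,
                 n_repeats = config$svm_repeats, cv_grid = config$cv_grid,
                 seed = stage_seed(config$seed, paste0("svm.", key))),
        error = function(e) e)
      if (inherits(res, "error")) {
        svm_skipped <- c(svm_skipped, stats::setNames(conditionMessage(res),
                                                      key))
      } else {
        svm[[key]] <- res
      }
    }
  }
  if (!is.null(svm)) {
    log_stage("classify", paste(names(svm), sprintf(
      "%.2f", vapply(svm, function(s) s$mean_accuracy, numeric(1))),
      collapse = ", "))
  }

  manifest <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      rate_table = file.path(outdir, "rate_table.csv"),
      counts = file.path(outdir, "fluctuation_counts.csv"),
      plates = file.path(outdir, "cfu_plates.csv"),
      reader = file.path(outdir, "plate_reader.csv"),
      fits = file.path(outdir, "tradeoff_fits.csv"),
      folds = file.path(outdir, "fold_changes.csv"))
    write_rate_table(rate_table, paths["rate_table"])
    write_assay_files(dataset, paths["counts"], paths["plates"])
    write_plate_reader_csv(dataset, paths["reader"])
    utils::write.csv(tradeoff_fit_table(fits), paths["fits"],
                     row.names = FALSE)
    utils::write.csv(fold_changes, paths["folds"], row.names = FALSE)
    manifest <- paths
  }

  structure(list(config = config, truth = truth, rate_table = rate_table,
                 tradeoff_fits = fits, recovery = recovery,
                 shift_tests = shift_tests, cross_media = cross_media,
                 fold_changes = fold_changes, mlr = mlr,
                 mlr_skipped = mlr_skipped, svm = svm,
                 svm_skipped = svm_skipped,
                 mutations_per_genome = stats::setNames(
                   mutations_per_genome(media$m_inf_true,
                                        config$genome_size_bp),
                   media$name),
                 manifest = manifest),
            class = "run_report")
}

#' Flatten trade-off fits into a report table
#'
#' @param fits list of `tradeoff_fit` objects.
#' @return data.frame with one row per medium.
#' @export
tradeoff_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    medium = f$medium, alpha = f$alpha, m_inf = f$m_inf,
    pearson_r = f$pearson_r, p_value = f$p_value, n = f$n_points)))
}

#' Human-readable summary of a pipeline run
#'
#' A pure function of the report (no recomputation): per-medium true vs
#' recovered trade-off parameters, regression accuracy, classifier
#' accuracies, and the mutations-per-genome arithmetic.
#'
#' @param report `run_report` from [run_pipeline()].
#' @return character vector of summary lines (also usable via `cat`).
#' @export
summarize <- function(report) {
  lines <- c("== mutation-growth trade-off pipeline ==", "",
             "Per-medium trade-off law  log10(M) = log10(M_inf) + alpha * mu:")
  rec <- report$recovery
  for (i in seq_len(nrow(rec))) {
    lines <- c(lines, sprintf(
      "  %-4s alpha true %6.1f  recovered %6.2f (err %+5.1f%%) | log10 M_inf true %6.2f  recovered %6.2f",
      rec$medium[i], rec$alpha_true[i], rec$alpha_hat[i],
      100 * (rec$alpha_hat[i] - rec$alpha_true[i]) / abs(rec$alpha_true[i]),
      rec$log10_m_inf_true[i], rec$log10_m_inf_hat[i]))
  }
  lines <- c(lines, "", "Expected mutations per genome per division at M_inf:")
  mpg <- report$mutations_per_genome
  lines <- c(lines, sprintf("  %-4s %.3g", names(mpg), mpg))
  lines <- c(lines, "", "Multiple linear regression (adjusted R2):")
  for (nm in names(report$mlr)) {
    r <- report$mlr[[nm]]
    lines <- c(lines, sprintf("  %-22s %.3f%s", nm, r$adj_r_squared,
                              if (!r$genotype_informative)
                                "  [genotype column non-informative]" else ""))
  }
  if (!is.null(report$mlr_skipped)) {
    lines <- c(lines, sprintf("  %-22s skipped: %s",
                              names(report$mlr_skipped),
                              report$mlr_skipped))
  }
  lines <- c(lines, "", "Classification (mean test accuracy over repeats):")
  if (is.null(report$svm)) {
    lines <- c(lines, "  skipped")
  } else {
    for (nm in names(report$svm)) {
      lines <- c(lines, sprintf("  %-18s %.3f", nm,
                                report$svm[[nm]]$mean_accuracy))
    }
  }
  if (!is.null(report$svm_skipped)) {
    lines <- c(lines, sprintf("  %-18s skipped: %s",
                              names(report$svm_skipped),
                              report$svm_skipped))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(summarize(x), sep = "\n")
  invisible(x)
}
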