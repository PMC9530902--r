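#' Encode a rate table into regression/classification features
#'
#' One row per strain x medium with: growth rate `mu`, `log10_m` (log10
#' mutation rate), the ordinal `medium_code` (LB = 1, MAA = 0, M63 = -1),
#' the binary disturbance flags `gr` (genome reduction) and `md` (MMR
#' deficiency), and the composite `genotype_value`: their product in
#' interactive mode (1 only for doubly disturbed strains) or their sum in
#' additive mode (0, 1 or 2).
#'
#' @param table rate table with columns `strain_id`, `medium`,
#'   `genome_reduced`, `mmr_deficient`, `growth_rate`, `mutation_rate`
#'   (and optionally `genotype_class`).
#' @param mode "interactive" (multiply the flags) or "additive" (add them).
#' @return data.frame of feature rows with `medium_label` and
#'   `genotype_label` retained for classification.
#' @export
encode_features <- function(table, mode = c("interactive", "additive")) {
  mode <- match.arg(mode)
  gr <- table$genome_reduced
  md <- table$mmr_deficient
  stopifnot(all(gr %in% 0:1), all(md %in% 0:1),
            all(table$mutation_rate > 0))
  gv <- if (mode == "interactive") gr * md else gr + md
  data.frame(
    strain_id = table$strain_id,
    mu = table$growth_rate,
    log10_m = log10(table$mutation_rate),
    medium_code = medium_code(table$medium),
    gr = gr, md = md,
    genotype_value = gv,
    medium_label = table$medium,
    genotype_label = if ("genotype_class" %in% names(table))
      table$genotype_class else genotype_class(gr, md),
    stringsAsFactors = FALSE)
}

#' Multiple linear regression of mutation or growth rate
#'
#' Ordinary least squares with intercept. For `response = "mutation"` the
#' model is `log10(M) ~ mu + medium_code + genotype_value`; for
#' `response = "growth"` it is `mu ~ log10(M) + medium_code +
#' genotype_value`. Reports per-coefficient estimates, standard errors and
#' two-sided t-test p-values, plus the adjusted R-squared.
#'
#' When the genotype column is constant — e.g. interactive coding on a
#' panel with no doubly disturbed strain — it carries no information; it is
#' flagged (`genotype_informative = FALSE`) and dropped from the design
#' rather than producing a singular fit. A constant or collinear remaining
#' predictor is an error naming the offending columns.
#'
#' @param rows feature rows from [encode_features()].
#' @param response "mutation" or "growth".
#' @param mode genotype coding used (recorded in the report).
#' @return list of class `mlr_report`: `response`, `mode`, `coefficients`
#'   (data.frame term/estimate/se/t/p), `adj_r_squared`, `n`,
#'   `genotype_informative`, `fit` (the `lm` object).
#' @export
fit_mlr <- function(rows, response = c("mutation", "growth"),
                    mode = c("interactive", "additive")) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  preds <- if (response == "mutation") c("mu", "medium_code", "genotype_value")
           else c("log10_m", "medium_code", "genotype_value")
  yvar <- if (response == "mutation") "log10_m" else "mu"
  if (nrow(rows) <= length(preds) + 1L) {
    stop("need more observations than predictors + 1")
  }

  genotype_informative <- stats::sd(rows$genotype_value) > 0
  if (!genotype_informative) preds <- setdiff(preds, "genotype_value")

  const <- preds[vapply(preds, function(p) stats::sd(rows[[p]]) == 0,
                        logical(1))]
  if (length(const) > 0L) {
    stop("singular design: constant predictor column(s): ",
         paste(const, collapse = ", "))
  }
  form <- stats::reformulate(preds, response = yvar)
  fit <- stats::lm(form, data = rows)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  # noiseless fixtures fit perfectly; the resulting summary warning is benign
  sm <- suppressWarnings(summary(fit))
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  structure(list(response = response, mode = mode, coefficients = co,
                 adj_r_squared = sm$adj.r.squared, n = nrow(rows),
                 genotype_informative = genotype_informative, fit = fit),
            class = "mlr_report")
}

#' Reference classifier hyperparameters
#'
#' The fixed values settled on after the nested grid search:
#' linear kernel C = 10 (medium) / C = 100 (genotype); RBF kernel
#' (C = 10, gamma = 1) for medium and (C = 100, gamma = 0.01) for genotype.
#'
#' @param target "medium" or "genotype".
#' @param kernel "linear" or "rbf".
#' @return list with `C` and `gamma` (gamma NA for linear).
#' @export
reference_hyperparameters <- function(target = c("medium", "genotype"),
                                  kernel = c("linear", "rbf")) {
  target <- match.arg(target)
  kernel <- match.arg(kernel)
  if (kernel == "linear") {
    list(C = if (target == "medium") 10 else 100, gamma = NA_real_)
  } else {
    if (target == "medium") list(C = 10, gamma = 1)
    else list(C = 100, gamma = 0.01)
  }
}

# stratified train/test split; guarantees every class appears in both
# splits when it has >= 2 members (resplit with a derived sub-seed if a
# random draw still leaves a split empty)
stratified_split <- function(labels, train_fraction, seed, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    idx_train <- withr::with_seed(stage_seed(seed, paste0("split", try)), {
      unlist(lapply(split(seq_along(labels), labels), function(ix) {
        n_tr <- max(1L, round(length(ix) * train_fraction))
        if (length(ix) > 1L) n_tr <- min(n_tr, length(ix) - 1L)
        sample(ix, n_tr)
      }), use.names = FALSE)
    })
    tr <- labels[idx_train]; te <- labels[-idx_train]
    if (all(unique(labels) %in% tr) && all(unique(labels) %in% te)) {
      return(sort(idx_train))
    }
  }
  sort(idx_train)  # classes with a single member cannot be in both splits
}

macro_recall <- function(truth, pred) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

svm_fit <- function(x, y, kernel, C, gamma) {
  e1071::svm(x = x, y = factor(y), kernel = if (kernel == "rbf") "radial"
             else "linear",
             cost = C, gamma = if (is.na(gamma)) 1 / ncol(x) else gamma,
             scale = FALSE)
}

# inner 5-fold stratified CV over the hyperparameter grid, scored by
# macro-averaged recall; ties break toward the smallest (C, gamma)
svm_tune <- function(x, y, kernel, grid, n_folds, seed) {
  folds <- withr::with_seed(stage_seed(seed, "cvfolds"), {
    f <- integer(length(y))
    for (ix in split(seq_along(y), y)) {
      f[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
    f
  })
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sc <- numeric(0)
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L || !any(!tr)) next
      fit <- svm_fit(x[tr, , drop = FALSE], y[tr], kernel,
                     grid$C[g], grid$gamma[g])
      pred <- as.character(stats::predict(fit, x[!tr, , drop = FALSE]))
      sc <- c(sc, macro_recall(y[!tr], pred))
    }
    scores[g] <- mean(sc)
  }
  best <- which.max(scores)  # first max: smallest C (and gamma) wins ties
  list(C = grid$C[best], gamma = grid$gamma[best], cv_score = scores[best])
}

#' Classify medium or genotype from the two rate features
#'
#' Maximum-margin (support vector machine) classification of the growth
#' medium (3 classes) or the genotype (4 classes) from the two features
#' (growth rate, log10 mutation rate) only. Protocol: per repeat, a random
#' stratified split into 60% training / 40% test; hyperparameters C (and
#' gamma for the RBF kernel) selected by 5-fold nested cross-validation
#' over a 10-fold-increment grid from 0.001 to 100, scored by
#' macro-averaged recall; the tuned model's test accuracy is read off the
#' confusion matrix. Five repeats by default. Features are standardised
#' (z-score) using training-split statistics, recorded in the report.
#'
#' Setting `fixed = TRUE` skips the grid search and uses the fixed reference
#' hyperparameters ([reference_hyperparameters()]).
#'
#' @param rows feature rows from [encode_features()].
#' @param target "medium" or "genotype".
#' @param kernel "linear" or "rbf".
#' @param split_fraction training fraction (default 0.6).
#' @param n_repeats independent train/test repeats (default 5).
#' @param cv_grid numeric vector of grid values for C and gamma.
#' @param n_folds inner CV folds.
#' @param fixed use the fixed reference hyperparameters instead of tuning.
#' @param seed integer seed; splits and accuracies are reproducible.
#' @return list of class `svm_report`: `target`, `kernel`, `accuracies`
#'   (one per repeat), `mean_accuracy`, `confusion` (summed over repeats),
#'   `hyperparameters` (per repeat), `cv_scores`, `splits` (training row
#'   indices per repeat), `scaling`, `model` (the last repeat's trained
#'   svm, for decision landscapes), `n`.
#' @export
classify <- function(rows, target = c("medium", "genotype"),
                     kernel = c("linear", "rbf"),
                     split_fraction = 0.6, n_repeats = 5,
                     cv_grid = 10^(-3:2), n_folds = 5,
                     fixed = FALSE, seed = 1L) {
  target <- match.arg(target)
  kernel <- match.arg(kernel)
  y <- if (target == "medium") rows$medium_label else rows$genotype_label
  x <- as.matrix(rows[, c("mu", "log10_m")])
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("classification of ", target, " needs >= 2 classes; found ",
         length(classes), " (", paste(classes, collapse = ", "), ")")
  }
  grid <- if (kernel == "rbf") expand.grid(C = cv_grid, gamma = cv_grid)
          else data.frame(C = cv_grid, gamma = NA_real_)

  acc <- cv_sc <- numeric(n_repeats)
  hp <- splits <- vector("list", n_repeats)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  model <- NULL; scaling <- NULL
  for (r in seq_len(n_repeats)) {
    rs <- stage_seed(seed, paste0("repeat", r))
    idx_tr <- stratified_split(y, split_fraction, rs)
    splits[[r]] <- idx_tr
    x_tr <- x[idx_tr, , drop = FALSE]; y_tr <- y[idx_tr]
    x_te <- x[-idx_tr, , drop = FALSE]; y_te <- y[-idx_tr]
    ctr <- colMeans(x_tr); scl <- apply(x_tr, 2, stats::sd)
    scl[scl == 0] <- 1
    x_tr <- scale(x_tr, ctr, scl); x_te <- scale(x_te, ctr, scl)

    if (fixed) {
      p <- reference_hyperparameters(target, kernel)
      tune <- list(C = p$C, gamma = p$gamma, cv_score = NA_real_)
    } else {
      tune <- svm_tune(x_tr, y_tr, kernel, grid, n_folds, rs)
    }
    fit <- svm_fit(x_tr, y_tr, kernel, tune$C, tune$gamma)
    pred <- as.character(stats::predict(fit, x_te))
    acc[r] <- mean(pred == y_te)
    cv_sc[r] <- tune$cv_score
    hp[[r]] <- list(C = tune$C, gamma = tune$gamma)
    confusion <- confusion + table(factor(y_te, classes),
                                   factor(pred, classes))
    model <- fit; scaling <- list(center = ctr, scale = scl)
  }
  structure(list(target = target, kernel = kernel, accuracies = acc,
                 mean_accuracy = mean(acc), confusion = confusion,
                 hyperparameters = hp, cv_scores = cv_sc, splits = splits,
                 scaling = scaling, model = model, n = nrow(rows)),
            class = "svm_report")
}

#' Decision landscape of a trained classifier
#'
#' Evaluates a trained two-feature classifier on a regular lattice over the
#' (growth rate, log10 mutation rate) plane, for region plotting of the
#' medium or genotype clusters.
#'
#' @param report `svm_report` from [classify()] (its last trained model and
#'   feature scaling are used), or a list with `model` and `scaling`.
#' @param mu_range,log10_m_range plot bounds on the two raw features.
#' @param grid_n lattice points per axis (>= 1).
#' @return data.frame with `mu`, `log10_m`, `label` (grid_n^2 rows).
#' @export
decision_landscape <- function(report, mu_range = c(0, 1),
                               log10_m_range = c(-11, -6), grid_n = 100) {
  stopifnot(grid_n >= 1)
  gx <- if (grid_n == 1L) mean(mu_range) else
    seq(mu_range[1], mu_range[2], length.out = grid_n)
  gy <- if (grid_n == 1L) mean(log10_m_range) else
    seq(log10_m_range[1], log10_m_range[2], length.out = grid_n)
  grid <- expand.grid(mu = gx, log10_m = gy)
  xs <- scale(as.matrix(grid), report$scaling$center, report$scaling$scale)
  grid$label <- as.character(stats::predict(report$model, xs))
  grid
}
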