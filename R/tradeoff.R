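#' Fit the per-medium mutation-growth trade-off law
#'
#' Ordinary least squares of log10(mutation rate) on growth rate, pooled
#' across all genotypes and collections present in the medium:
#' \deqn{\log_{10} M_i = \log_{10} M_\infty + \alpha \mu_i.}
#' `alpha` is the fitted slope and `m_inf = 10^intercept` is the maximal
#' mutation rate as the growth rate drops to zero. The Pearson correlation
#' of log10(M) with mu (with its two-sided p-value) is computed on the same
#' pairs. The fit is unweighted.
#'
#' @param table rate table: data.frame with columns `medium`,
#'   `growth_rate`, `mutation_rate` (plus strain metadata).
#' @param medium medium name to fit.
#' @return list of class `tradeoff_fit`: `medium`, `alpha`, `m_inf`,
#'   `alpha_se`, `alpha_ci` (95%), `pearson_r`, `p_value`, `n_points`.
#' @export
fit_tradeoff <- function(table, medium) {
  rows <- table[table$medium == medium, , drop = FALSE]
  rows <- rows[is.finite(rows$growth_rate) & is.finite(rows$mutation_rate) &
                 rows$mutation_rate > 0, , drop = FALSE]
  if (nrow(rows) < 3L) {
    stop("need >= 3 strains with both rates in medium ", medium)
  }
  mu <- rows$growth_rate
  y <- log10(rows$mutation_rate)
  if (stats::sd(mu) == 0) {
    stop("degenerate fit in medium ", medium, ": growth rate is constant")
  }
  fit <- stats::lm(y ~ mu)
  # noiseless tables interpolate exactly; the perfect-fit warning is benign
  co <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(stats::confint(fit, "mu", level = 0.95))
  ct <- suppressWarnings(stats::cor.test(mu, y, method = "pearson"))
  structure(list(medium = medium,
                 alpha = unname(co["mu", "Estimate"]),
                 m_inf = 10^unname(co["(Intercept)", "Estimate"]),
                 alpha_se = unname(co["mu", "Std. Error"]),
                 alpha_ci = c(ci[1], ci[2]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n_points = nrow(rows)),
            class = "tradeoff_fit")
}

#' Predict a mutation rate from a trade-off fit
#'
#' Evaluates `10^(log10(m_inf) + alpha * mu)`; at `mu = 0` this returns the
#' maximal mutation rate `m_inf`.
#'
#' @param fit `tradeoff_fit` (or any list with `alpha`, `m_inf`).
#' @param mu growth rate(s), h^-1, >= 0.
#' @return predicted mutation rate(s), bp^-1 division^-1.
#' @export
predict_mutation_rate <- function(fit, mu) {
  stopifnot(all(mu >= 0))
  10^(log10(fit$m_inf) + fit$alpha * mu)
}

#' Expected mutations per genome per division
#'
#' The product of a per-bp per-division mutation rate and the genome size;
#' with the maximal rate in rich medium this exceeds 1,000 mutations per
#' genome, while the poor-medium maximum allows only a few.
#'
#' @param m_inf mutation rate, bp^-1 division^-1.
#' @param genome_size_bp genome size in bp (default 4e6).
#' @return expected mutations per genome per division.
#' @export
mutations_per_genome <- function(m_inf, genome_size_bp = 4e6) {
  stopifnot(m_inf >= 0, genome_size_bp >= 0)
  m_inf * genome_size_bp
}

#' Paired shift of mutation-rate distributions between two media
#'
#' Paired two-sided Wilcoxon signed-rank test on per-strain log10 mutation
#' rates across two media; reports the median log10 shift (medium_a minus
#' medium_b) and the p-value. A positive shift means rates are higher in
#' `medium_a`.
#'
#' @param table rate table (one row per strain x medium).
#' @param medium_a,medium_b the two media compared.
#' @return list with `median_log10_shift`, `p_value`, `n_pairs`, `test`.
#' @export
compare_media_distributions <- function(table, medium_a, medium_b) {
  a <- table[table$medium == medium_a, c("strain_id", "mutation_rate")]
  b <- table[table$medium == medium_b, c("strain_id", "mutation_rate")]
  common <- intersect(a$strain_id, b$strain_id)
  if (length(common) < 3L) {
    stop("insufficient data: fewer than 3 strains present in both media")
  }
  la <- log10(a$mutation_rate[match(common, a$strain_id)])
  lb <- log10(b$mutation_rate[match(common, b$strain_id)])
  d <- la - lb
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(la, lb, paired = TRUE,
                                        exact = NULL)$p.value)
  list(median_log10_shift = stats::median(d), p_value = p,
       n_pairs = length(common), test = "paired Wilcoxon signed-rank")
}

#' Cross-media correlation of per-strain rates
#'
#' Pearson correlation of per-strain rates between every pair of media
#' (log10 scale for mutation rates, raw scale for growth rates), per
#' collection and pooled.
#'
#' @param table rate table.
#' @param rate_kind "growth" or "mutation".
#' @param log10_mutation correlate mutation rates on the plotted log10
#'   scale (default) or raw.
#' @return data.frame with columns `collection` ("pooled" included),
#'   `medium_a`, `medium_b`, `r`, `p_value`, `n`; pairs with fewer than 3
#'   shared strains are skipped with a warning.
#' @export
cross_media_correlation <- function(table, rate_kind = c("growth", "mutation"),
                                    log10_mutation = TRUE) {
  rate_kind <- match.arg(rate_kind)
  col <- if (rate_kind == "growth") "growth_rate" else "mutation_rate"
  media <- unique(table$medium)
  if (length(media) < 2L) stop("need at least 2 media")
  pairs <- utils::combn(media, 2, simplify = FALSE)
  groups <- c("pooled", unique(table$collection))
  out <- list()
  for (g in groups) {
    sub <- if (g == "pooled") table else
      table[table$collection == g, , drop = FALSE]
    for (pr in pairs) {
      a <- sub[sub$medium == pr[1], c("strain_id", col)]
      b <- sub[sub$medium == pr[2], c("strain_id", col)]
      common <- intersect(a$strain_id, b$strain_id)
      if (length(common) < 3L) {
        warning(sprintf("skipping pair %s-%s in %s: fewer than 3 shared strains",
                        pr[1], pr[2], g))
        next
      }
      va <- a[[col]][match(common, a$strain_id)]
      vb <- b[[col]][match(common, b$strain_id)]
      if (rate_kind == "mutation" && log10_mutation) {
        va <- log10(va); vb <- log10(vb)
      }
      ct <- stats::cor.test(va, vb, method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        collection = g, medium_a = pr[1], medium_b = pr[2],
        r = unname(ct$estimate), p_value = ct$p.value, n = length(common),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fold changes of rates due to genetic disturbance
#'
#' For every derivative strain and medium, the log10 ratio of its rate to
#' its parent's rate in the same medium, emitted separately for mutation
#' and growth rates.
#'
#' @param table rate table.
#' @param parent_map named character vector: derivative strain_id -> parent
#'   strain_id.
#' @return data.frame with columns `strain_id`, `parent`, `collection`,
#'   `medium`, `log10_mutation_ratio`, `log10_growth_ratio`.
#' @export
disturbance_fold_changes <- function(table, parent_map) {
  stopifnot(length(parent_map) >= 1, !is.null(names(parent_map)))
  missing_parents <- setdiff(unique(parent_map), table$strain_id)
  if (length(missing_parents) > 0L) {
    stop("parent strain(s) missing from the table: ",
         paste(missing_parents, collapse = ", "))
  }
  key <- function(s, m) paste(s, m, sep = "\r")
  idx <- stats::setNames(seq_len(nrow(table)),
                         key(table$strain_id, table$medium))
  out <- list()
  for (d in names(parent_map)) {
    p <- parent_map[[d]]
    med_d <- table$medium[table$strain_id == d]
    for (m in med_d) {
      i <- idx[[key(d, m)]]; j <- idx[[key(p, m)]]
      if (is.null(j) || is.na(j)) next  # parent not measured in this medium
      out[[length(out) + 1L]] <- data.frame(
        strain_id = d, parent = p, collection = table$collection[i],
        medium = m,
        log10_mutation_ratio = log10(table$mutation_rate[i] /
                                       table$mutation_rate[j]),
        log10_growth_ratio = log10(table$growth_rate[i] /
                                     table$growth_rate[j]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Slope-recovery experiment for the trade-off law
#'
#' The standard parameter-recovery protocol: generate `n_strains` strains
#' (mixed genotypes across the three collections), draw true rates from
#' each medium's generative law with noise `sigma_log10` on log10 mutation
#' rate, and refit the trade-off line per medium, returning true and
#' recovered parameters side by side.
#'
#' @param seed integer seed.
#' @param n_strains panel size (split across MDS/KHK/MG).
#' @param sigma_log10 generative noise SD on log10 mutation rate.
#' @param media medium spec data.frame ([medium_specs()]).
#' @return data.frame with one row per medium: `medium`, `alpha_true`,
#'   `alpha_hat`, `log10_m_inf_true`, `log10_m_inf_hat`, `pearson_r`, `n`.
#' @export
tradeoff_recovery <- function(seed = 1L, n_strains = 20,
                              sigma_log10 = 0.2, media = medium_specs()) {
  n3 <- c(MDS = ceiling(n_strains / 3), KHK = ceiling(n_strains / 3))
  n3 <- c(n3, MG = n_strains - sum(n3))
  panel <- make_strain_panel(n3, seed = seed)
  tr <- sample_true_rates(panel, media, sigma_log10 = sigma_log10,
                          seed = seed)
  tab <- tr
  tab$growth_rate <- tab$mu_true
  tab$mutation_rate <- tab$m_true
  do.call(rbind, lapply(seq_len(nrow(media)), function(i) {
    fit <- fit_tradeoff(tab, media$name[i])
    data.frame(medium = media$name[i],
               alpha_true = media$alpha_true[i],
               alpha_hat = fit$alpha,
               log10_m_inf_true = log10(media$m_inf_true[i]),
               log10_m_inf_hat = log10(fit$m_inf),
               pearson_r = fit$pearson_r,
               n = fit$n_points)
  }))
}

#' Default derivative-to-parent map for a synthetic panel
#'
#' @param panel strain panel from [make_strain_panel()].
#' @return named character vector derivative -> parent.
#' @export
default_parent_map <- function(panel) {
  parents <- c(MDS = "MDS42", KHK = "W3110", MG = "MG1655")
  der <- panel[!(panel$strain_id %in% parents), , drop = FALSE]
  stats::setNames(unname(parents[der$collection]), der$strain_id)
}
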