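#' Lea-Coulson probability mass function via the Ma-Sandri-Sarkar recursion
#'
#' Computes the exact distribution of mutant counts in a fluctuation test
#' under the Lea-Coulson model with expected mutations per culture `m`:
#' \deqn{p_0 = e^{-m}, \qquad
#'       p_n = \frac{m}{n} \sum_{j=0}^{n-1} \frac{p_j}{n-j+1}.}
#' This is the compound-Poisson (Panjer) recursion for clone sizes
#' distributed as \eqn{q_k = 1/(k(k+1))}, using the weight
#' \eqn{k q_k = 1/(k+1)}.
#'
#' @param m expected mutations per culture (> 0).
#' @param n_max largest count computed; the returned vector has length
#'   `n_max + 1` (counts 0..n_max). Mass above `n_max` is the truncated
#'   jackpot tail, `1 - sum(p)`.
#' @return numeric vector `p[k+1] = P(count = k)`.
#' @export
#' @examples
#' p <- mss_pmf(1, 10)
#' p[1]  # exp(-1)
mss_pmf <- function(m, n_max) {
  if (!is.finite(m) || m <= 0) stop("'m' must be positive and finite")
  n_max <- as.integer(n_max)
  if (n_max < 0L) stop("'n_max' must be >= 0")
  p <- numeric(n_max + 1L)
  p[1L] <- exp(-m)
  if (n_max >= 1L) {
    k <- seq_len(n_max)
    w <- 1 / (k + 1)                # Panjer weight k*q_k for lag k = n - j
    for (n in k) {
      p[n + 1L] <- (m / n) * sum(p[1:n] * w[n:1])
    }
  }
  p
}

#' P0 estimator of the expected mutations per culture
#'
#' `m_hat = -ln(fraction of cultures with zero mutants)`, the inversion of
#' the zero term `p0 = exp(-m)` of the Lea-Coulson distribution.
#'
#' @param mutant_counts non-negative integer counts, one per culture.
#' @return `m_hat`, or an error if no culture has zero mutants (callers
#'   should fall back to the maximum-likelihood estimator).
#' @export
estimate_m_p0 <- function(mutant_counts) {
  check_counts(mutant_counts)
  n_zero <- sum(mutant_counts == 0)
  if (n_zero == 0L) {
    stop("P0 method undefined: no culture with zero mutants; use the MLE")
  }
  -log(n_zero / length(mutant_counts))
}

check_counts <- function(mutant_counts) {
  if (length(mutant_counts) < 2L) stop("need at least 2 parallel cultures")
  if (any(!is.finite(mutant_counts)) || any(mutant_counts < 0)) {
    stop("mutant counts must be finite and non-negative")
  }
  invisible(mutant_counts)
}

# log-likelihood of counts under the MSS pmf with counts > n_max lumped
# into the truncated tail mass
mss_loglik <- function(m, count_tab, n_max) {
  p <- mss_pmf(m, n_max)
  counts <- as.numeric(names(count_tab))
  freq <- as.numeric(count_tab)
  tail_mass <- max(1 - sum(p), 1e-300)
  lp <- ifelse(counts > n_max, log(tail_mass),
               log(pmax(p[counts + 1L], 1e-300)))
  sum(freq * lp)
}

#' Ma-Sandri-Sarkar maximum-likelihood estimate of m
#'
#' Maximises the Lea-Coulson log-likelihood of the observed mutant counts
#' over the expected number of mutations per culture, with counts above
#' `n_max` contributing through the lumped jackpot-tail mass. The 95%
#' confidence interval is from the profile likelihood (log-likelihood drop
#' of 1.92). The search is bracketed scalar optimisation on log(m), seeded
#' at the P0 estimate when zeros are present.
#'
#' @param mutant_counts non-negative integer counts, one per culture.
#' @param n_max pmf truncation point (counts above are lumped).
#' @param m_range search interval for m.
#' @return list with `m_hat`, `ci_low`, `ci_high`, `loglik`, `status`
#'   ("ok" or "all-zero"). For all-zero counts `m_hat = 0` and `ci_high`
#'   is the 95% upper bound `-log(0.05)/n` from `p0^n`.
#' @export
estimate_m_mle <- function(mutant_counts, n_max = 1500,
                           m_range = c(1e-3, 1e2)) {
  check_counts(mutant_counts)
  n <- length(mutant_counts)
  if (all(mutant_counts == 0)) {
    return(list(m_hat = 0, ci_low = 0, ci_high = -log(0.05) / n,
                loglik = 0, status = "all-zero"))
  }
  n_max <- min(as.integer(n_max), max(1L, ceiling(max(mutant_counts))))
  tab <- table(mutant_counts)

  opt <- stats::optimize(function(lm) mss_loglik(exp(lm), tab, n_max),
                         interval = log(m_range), maximum = TRUE,
                         tol = 1e-7)
  m_hat <- exp(opt$maximum)
  ll_max <- opt$objective

  # profile-likelihood 95% CI: loglik(m) = ll_max - qchisq(.95, 1)/2
  drop <- stats::qchisq(0.95, 1) / 2
  f <- function(lm) mss_loglik(exp(lm), tab, n_max) - (ll_max - drop)
  lo <- if (f(log(m_range[1])) < 0) {
    exp(stats::uniroot(f, c(log(m_range[1]), log(m_hat)), tol = 1e-6)$root)
  } else m_range[1]
  hi <- if (f(log(m_range[2])) < 0) {
    exp(stats::uniroot(f, c(log(m_hat), log(m_range[2])), tol = 1e-6)$root)
  } else m_range[2]

  list(m_hat = m_hat, ci_low = lo, ci_high = hi, loglik = ll_max,
       status = "ok")
}

#' Final population size from CFU dilution plates
#'
#' Applies the reliability filter — only plates with 10 to 500 colonies are
#' used — and averages `colony_count / dilution` over the retained plates.
#'
#' @param plate_counts data.frame with columns `dilution` and
#'   `colony_count`.
#' @param min_colonies,max_colonies reliability bounds (inclusive).
#' @return estimated cells per culture.
#' @export
#' @examples
#' cfu_from_plates(data.frame(dilution = 1e-7, colony_count = c(100, 120)))
cfu_from_plates <- function(plate_counts, min_colonies = 10,
                            max_colonies = 500) {
  stopifnot(nrow(plate_counts) >= 1,
            all(plate_counts$dilution > 0),
            all(plate_counts$colony_count >= 0))
  keep <- plate_counts$colony_count >= min_colonies &
          plate_counts$colony_count <= max_colonies
  if (!any(keep)) {
    stop("no reliable plate: all colony counts outside [", min_colonies,
         ", ", max_colonies, "]")
  }
  mean(plate_counts$colony_count[keep] / plate_counts$dilution[keep])
}

#' Mutation rate from one fluctuation assay
#'
#' Estimates the expected mutations per culture (MSS-MLE by default, P0 on
#' request), sizes the population from the CFU plates, and converts to a
#' per-bp per-division rate:
#' `mutation_rate = m_hat / (n_final_hat * target_size_bp)`.
#' The 95% CI on m is scaled identically.
#'
#' @param assay `fluctuation_assay` object (or list with `mutant_counts`
#'   and `target_size_bp`).
#' @param plates CFU plate data.frame; if `NULL`, `assay$n_final` is used
#'   as the population size (synthetic truth).
#' @param method "mle" or "p0".
#' @param n_max pmf truncation for the MLE.
#' @return list with `mutation_rate`, `ci_low`, `ci_high`, `m_hat`,
#'   `n_final_hat`, `method`, `status`.
#' @export
mutation_rate_from_assay <- function(assay, plates = NULL,
                                     method = c("mle", "p0"),
                                     n_max = 1500) {
  method <- match.arg(method)
  counts <- assay$mutant_counts
  target <- assay$target_size_bp
  stopifnot(target > 0)
  n_final <- if (is.null(plates)) assay$n_final else cfu_from_plates(plates)

  if (method == "p0" && any(counts == 0) && !all(counts == 0)) {
    m_hat <- estimate_m_p0(counts)
    est <- list(m_hat = m_hat, ci_low = NA_real_, ci_high = NA_real_,
                status = "ok")
  } else {
    est <- estimate_m_mle(counts, n_max = n_max)
  }
  scale <- n_final * target
  list(mutation_rate = est$m_hat / scale,
       ci_low = est$ci_low / scale,
       ci_high = est$ci_high / scale,
       m_hat = est$m_hat, n_final_hat = n_final,
       method = if (method == "p0") "P0" else "MSS-MLE",
       status = est$status)
}

#' Combine replicate rate estimates
#'
#' Replicate assays (typically N = 3-6 per strain and medium) are combined
#' by the arithmetic mean of the per-assay rates, with the standard error
#' over replicates.
#'
#' @param rates numeric vector of per-assay mutation (or growth) rates.
#' @return list with `mean`, `se`, `n`.
#' @export
combine_replicates <- function(rates) {
  stopifnot(length(rates) >= 1, all(is.finite(rates)))
  n <- length(rates)
  se <- if (n > 1L) stats::sd(rates) / sqrt(n) else NA_real_
  list(mean = mean(rates), se = se, n = n)
}
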