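#' Default medium specifications
#'
#' The three growth media form a nutritional gradient: LB (rich), MAA
#' (minimal medium supplemented with 20 amino acids), and M63 (minimal).
#' Each medium carries the parameters of the per-medium log-linear
#' trade-off law
#' \deqn{\log_{10} M = \log_{10} M_\infty + \alpha \mu,}
#' where \eqn{M} is the mutation rate (bp^-1 division^-1), \eqn{\mu} the
#' growth rate (h^-1), \eqn{M_\infty} the maximal mutation rate as the
#' growth rate approaches zero, and \eqn{\alpha < 0} the slope coupling
#' log mutation rate to growth rate. Defaults use the fitted values
#' \eqn{\alpha} = (-9.5, -12.6, -12.8) and \eqn{M_\infty} =
#' (1e-3, 4e-4, 7e-6) for LB, MAA, M63. The ordinal medium code (LB = 1,
#' MAA = 0, M63 = -1) is the encoding consumed by the regression and
#' classification layers.
#'
#' @param media character vector of medium names to return (subset of
#'   `c("LB", "MAA", "M63")`).
#' @return A data.frame with one row per medium and columns `name`, `code`,
#'   `alpha_true`, `m_inf_true`, `mu_min`, `mu_max`.
#' @export
#' @examples
#' medium_specs()
medium_specs <- function(media = c("LB", "MAA", "M63")) {
  all <- data.frame(
    name       = c("LB", "MAA", "M63"),
    code       = c(1, 0, -1),
    alpha_true = c(-9.5, -12.6, -12.8),
    m_inf_true = c(1e-3, 4e-4, 7e-6),
    mu_min     = c(0.40, 0.25, 0.10),
    mu_max     = c(0.80, 0.60, 0.45),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(media, all$name)
  if (length(bad) > 0L) {
    stop("unknown medium name(s): ", paste(bad, collapse = ", "))
  }
  out <- all[match(media, all$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinal medium code
#'
#' Maps medium names to the fixed ordinal encoding LB -> 1, MAA -> 0,
#' M63 -> -1 used as a numeric covariate.
#'
#' @param medium character vector of medium names.
#' @return numeric vector of codes.
#' @export
medium_code <- function(medium) {
  codes <- c(LB = 1, MAA = 0, M63 = -1)
  bad <- setdiff(unique(medium), names(codes))
  if (length(bad) > 0L) {
    stop("unknown medium name(s): ", paste(bad, collapse = ", "))
  }
  unname(codes[medium])
}

#' Deterministic per-stage sub-seed
#'
#' Derives a stage-specific seed from the global seed and a stage label, so
#' that editing one pipeline stage does not reshuffle the randomness of the
#' others.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return integer seed (< 2^31).
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
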