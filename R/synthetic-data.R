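#' Build a synthetic strain panel
#'
#' Emulates the three strain collections studied: MDS (mismatch-repair /
#' proofreading deletion mutators constructed on the genome-reduced MDS42
#' background), KHK (reduced-genome derivatives of wild-type W3110), and MG
#' (MG1655 and its mutator derivatives). Each collection includes its parent
#' strain (no mutation-machinery deletion); the remaining strains carry the
#' collection's characteristic disturbance:
#' \itemize{
#'   \item MDS: all strains genome-reduced; derivatives additionally
#'     MMR-deficient (genome-reduced mutators).
#'   \item KHK: derivatives genome-reduced, none MMR-deficient; the parent
#'     is wild type.
#'   \item MG: none genome-reduced; derivatives MMR-deficient (mutators).
#' }
#' The four-level `genotype_class` is a deterministic function of the two
#' binary flags: 0/0 wild type, 1/0 reduced genome, 0/1 mutator, 1/1
#' genome-reduced mutator.
#'
#' @param sizes named integer vector of panel sizes per collection, e.g.
#'   `c(MDS = 14, KHK = 10, MG = 10)` (the default: 13 constructed mutators
#'   plus parent MDS42, ten KHK strains, MG1655 plus nine mutators).
#' @param seed integer seed (panels are deterministic given `sizes` + seed).
#' @return data.frame with columns `strain_id`, `collection`,
#'   `genome_reduced`, `mmr_deficient`, `genotype_class`.
#' @export
#' @examples
#' panel <- make_strain_panel(c(MDS = 14, KHK = 10, MG = 10), seed = 1)
#' table(panel$genotype_class)
make_strain_panel <- function(sizes = c(MDS = 14, KHK = 10, MG = 10),
                              seed = 1L) {
  if (length(sizes) == 0L || is.null(names(sizes)) || any(names(sizes) == "")) {
    stop("'sizes' must be a named vector of collection sizes")
  }
  bad <- setdiff(names(sizes), c("MDS", "KHK", "MG"))
  if (length(bad) > 0L) {
    stop("unknown collection name(s): ", paste(bad, collapse = ", "))
  }
  if (any(sizes < 1L)) stop("each requested collection needs size >= 1")

  rows <- lapply(names(sizes), function(coll) {
    n <- as.integer(sizes[[coll]])
    parent_id <- switch(coll, MDS = "MDS42", KHK = "W3110", MG = "MG1655")
    id <- c(parent_id,
            if (n > 1L) sprintf("%s_d%02d", coll, seq_len(n - 1L)))
    gr <- switch(coll,
      MDS = rep(1L, n),                       # all on the reduced genome
      KHK = c(0L, rep(1L, n - 1L)),           # parent wild type, rest reduced
      MG  = rep(0L, n))
    md <- switch(coll,
      MDS = c(0L, rep(1L, n - 1L)),           # derivatives are mutators
      KHK = rep(0L, n),
      MG  = c(0L, rep(1L, n - 1L)))
    data.frame(strain_id = id, collection = coll,
               genome_reduced = gr, mmr_deficient = md,
               is_parent = id == parent_id,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  panel$genotype_class <- genotype_class(panel$genome_reduced,
                                         panel$mmr_deficient)
  stopifnot(!anyDuplicated(panel$strain_id))
  rownames(panel) <- NULL
  panel
}

#' Genotype class from the two disturbance flags
#'
#' @param genome_reduced,mmr_deficient binary flags (0/1).
#' @return character vector in {"wild type", "reduced genome", "mutator",
#'   "genome-reduced mutator"}.
#' @export
genotype_class <- function(genome_reduced, mmr_deficient) {
  stopifnot(all(genome_reduced %in% 0:1), all(mmr_deficient %in% 0:1))
  cls <- c("wild type", "reduced genome", "mutator", "genome-reduced mutator")
  cls[1L + genome_reduced + 2L * mmr_deficient]
}

#' Sample true growth and mutation rates for a panel
#'
#' Draws, for every strain x medium combination, a true growth rate from the
#' medium's growth-rate range and a true mutation rate from the per-medium
#' log-linear law
#' `log10(m_true) = log10(m_inf_true) + alpha_true * mu_true + N(0, sigma_log10)`.
#'
#' Each strain carries a latent growth quantile shared across media, shifted
#' downward for genetically disturbed strains (mutators and reduced genomes
#' grow slower), so per-strain growth rates are positively correlated between
#' media and ordered LB >= MAA >= M63 (the medium ranges are nested in that
#' order and a small per-medium jitter is re-sorted to preserve the
#' ordering). Collection parents (panels carrying an `is_parent` column)
#' draw their quantile from the upper range, reflecting that parents are
#' healthy laboratory strains that out-grow their disturbed derivatives.
#'
#' @param panel strain panel from [make_strain_panel()].
#' @param media data.frame of medium specs ([medium_specs()]).
#' @param sigma_log10 SD of Gaussian noise on log10 mutation rate (>= 0).
#' @param seed integer seed.
#' @param mu_jitter_sd SD (h^-1) of the per-medium jitter on growth rate.
#' @param disturbance_shift fractional downward shift of the growth quantile
#'   per disturbance flag (genome reduction, MMR deficiency).
#' @return data.frame with columns `strain_id`, `collection`,
#'   `genome_reduced`, `mmr_deficient`, `genotype_class`, `medium`,
#'   `mu_true` (h^-1), `m_true` (bp^-1 division^-1).
#' @export
sample_true_rates <- function(panel, media = medium_specs(),
                              sigma_log10 = 0.2, seed = 1L,
                              mu_jitter_sd = 0.02,
                              disturbance_shift = 0.25) {
  if (nrow(panel) == 0L) stop("empty strain panel")
  if (nrow(media) == 0L) stop("empty media list")
  stopifnot(sigma_log10 >= 0, all(media$mu_max > media$mu_min))

  withr::with_seed(seed, {
    n <- nrow(panel)
    # stratified (jittered-grid) quantiles: the real collections were
    # deliberately assembled to span a range of growth abilities (varied
    # genome sizes, varied fidelity deletions), so the panel covers the
    # growth axis evenly rather than clustering by chance
    q <- sample((seq_len(n) - stats::runif(n)) / n)
    if ("is_parent" %in% names(panel)) {
      q[panel$is_parent] <- stats::runif(sum(panel$is_parent), 0.6, 0.95)
    }
    shift <- 1 - disturbance_shift * (panel$genome_reduced +
                                      panel$mmr_deficient)
    q <- q * pmax(shift, 0.05)

    out <- vector("list", n)
    # medium order by code, richest first, so sorting jittered rates
    # descending preserves the LB >= MAA >= M63 contract
    med <- media[order(media$code, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(n)) {
      mu <- med$mu_min + q[i] * (med$mu_max - med$mu_min)
      mu <- mu + stats::rnorm(nrow(med), 0, mu_jitter_sd)
      mu <- pmax(sort(mu, decreasing = TRUE), 0)
      log10_m <- log10(med$m_inf_true) + med$alpha_true * mu +
        stats::rnorm(nrow(med), 0, sigma_log10)
      out[[i]] <- data.frame(
        panel[i, c("strain_id", "collection", "genome_reduced",
                   "mmr_deficient", "genotype_class")],
        medium = med$name, mu_true = mu, m_true = 10^log10_m,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate a fluctuation assay by the Lea-Coulson clone-size process
#'
#' Simulates mutant counts across parallel cultures of a fluctuation test by
#' the brute-force stochastic process, not by inverting the probability mass
#' function: the number of mutation events per culture is Poisson with mean
#' `m = m_true * target_size_bp * n_final`, and each event founds a clone of
#' final size `floor(n_final / x)` with `x` uniform on (1, n_final) —
#' deterministic exponential growth with mutations arising uniformly over
#' cell divisions, which reproduces the classic 1/(k(k+1)) clone-size law
#' and hence the Lea-Coulson mutant-count distribution.
#'
#' @param m_true true mutation rate, bp^-1 division^-1 (0 allowed: no
#'   mutations).
#' @param n_final final number of cells per culture (>= 1e3).
#' @param target_size_bp effective mutational target size in bp.
#' @param n_cultures number of parallel cultures (>= 2).
#' @param seed integer seed.
#' @return object of class `fluctuation_assay`: list with `mutant_counts`,
#'   `n_final`, `target_size_bp`, `m_expected`.
#' @export
simulate_fluctuation_assay <- function(m_true, n_final = 1e9,
                                       target_size_bp = 30,
                                       n_cultures = 30, seed = 1L) {
  stopifnot(n_cultures >= 2, n_final >= 1e3, target_size_bp > 0,
            m_true >= 0)
  m <- m_true * target_size_bp * n_final
  if (!is.finite(m)) stop("expected mutations per culture is not finite")

  counts <- withr::with_seed(seed, {
    n_mut <- stats::rpois(n_cultures, m)
    total <- sum(n_mut)
    if (total == 0L) {
      integer(n_cultures)
    } else {
      x <- stats::runif(total, min = 1, max = n_final)
      clone <- floor(n_final / x)
      culture <- rep.int(seq_len(n_cultures), n_mut)
      cnt <- numeric(n_cultures)
      agg <- tapply(clone, culture, sum)
      cnt[as.integer(names(agg))] <- agg
      cnt
    }
  })
  structure(list(mutant_counts = as.numeric(counts),
                 n_final = n_final,
                 target_size_bp = target_size_bp,
                 m_expected = m),
            class = "fluctuation_assay")
}

#' Simulate CFU dilution plates
#'
#' Per-plate colony counts are Poisson with mean `n_final * dilution`.
#'
#' @param n_final true number of cells per culture.
#' @param dilution_factors positive dilutions, one per plate (recycled over
#'   `n_plates`).
#' @param n_plates number of plates.
#' @param seed integer seed.
#' @return data.frame with columns `plate_index`, `dilution`, `colony_count`.
#' @export
simulate_cfu_plates <- function(n_final, dilution_factors = 1e-7,
                                n_plates = length(dilution_factors),
                                seed = 1L) {
  stopifnot(all(dilution_factors > 0), n_plates >= 1, n_final >= 0)
  dil <- rep_len(dilution_factors, n_plates)
  counts <- withr::with_seed(seed, stats::rpois(n_plates, n_final * dil))
  data.frame(plate_index = seq_len(n_plates), dilution = dil,
             colony_count = counts)
}

#' Simulate plate-reader growth curves
#'
#' Logistic trajectories
#' `OD(t) = K * od0 * exp(mu t) / (K + od0 * (exp(mu t) - 1))`
#' with i.i.d. Gaussian read noise truncated at zero; one curve per well.
#'
#' @param mu_true true growth rate, h^-1.
#' @param od0 inoculum OD (0 < od0 < capacity).
#' @param capacity carrying capacity (saturating OD).
#' @param interval_h read interval in hours.
#' @param duration_h total duration in hours.
#' @param noise_sd SD of Gaussian OD noise.
#' @param n_wells number of replicate wells.
#' @param seed integer seed.
#' @return list of `growth_curve` objects (see [growth_curve()]).
#' @export
simulate_growth_curves <- function(mu_true, od0 = 0.01, capacity = 1.0,
                                   interval_h = 0.5, duration_h = 24,
                                   noise_sd = 0.002, n_wells = 6,
                                   seed = 1L) {
  stopifnot(od0 > 0, od0 < capacity, interval_h > 0, duration_h > 0,
            mu_true >= 0, noise_sd >= 0, n_wells >= 1)
  t <- seq(0, duration_h, by = interval_h)
  od_det <- capacity * od0 * exp(mu_true * t) /
    (capacity + od0 * (exp(mu_true * t) - 1))
  withr::with_seed(seed, {
    lapply(seq_len(n_wells), function(w) {
      od <- pmax(od_det + stats::rnorm(length(t), 0, noise_sd), 0)
      growth_curve(well_id = sprintf("W%02d", w), times = t, od = od)
    })
  })
}

#' Assemble a raw synthetic dataset for the full pipeline
#'
#' For every strain x medium: true rates, replicated fluctuation assays with
#' CFU plates, and replicated growth curves. The final population size of
#' each fluctuation culture is chosen per strain so the expected number of
#' mutations per culture is about `m_target` (clamped to
#' `[1e5, 1e9]` cells), emulating the experimental practice of shrinking
#' culture volume for mutator strains so mutant counts stay countable.
#'
#' @param rates data.frame from [sample_true_rates()].
#' @param n_cultures parallel cultures per assay.
#' @param n_replicates replicate assays (and growth wells / 2) per condition.
#' @param target_size_bp effective mutational target size in bp.
#' @param m_target expected mutations per culture aimed at by the
#'   culture-size choice.
#' @param n_plates CFU plates per assay.
#' @param growth_noise_sd OD read noise SD.
#' @param n_wells replicate growth wells per condition.
#' @param duration_h growth-assay duration in hours.
#' @param interval_h read interval in hours.
#' @param seed integer seed.
#' @return list with elements `rates` (the input truth), `assays` (list of
#'   per-condition lists of `fluctuation_assay` + plate data.frames), and
#'   `curves` (list of per-condition growth-curve lists).
#' @export
simulate_dataset <- function(rates, n_cultures = 30, n_replicates = 3,
                             target_size_bp = 30, m_target = 2,
                             n_plates = 4, growth_noise_sd = 0.002,
                             n_wells = 6, duration_h = 48,
                             interval_h = 0.5, seed = 1L) {
  stopifnot(nrow(rates) > 0)
  assays <- vector("list", nrow(rates))
  curves <- vector("list", nrow(rates))
  names(assays) <- names(curves) <-
    paste(rates$strain_id, rates$medium, sep = ".")
  for (i in seq_len(nrow(rates))) {
    m_true <- rates$m_true[i]
    n_final <- m_target / (m_true * target_size_bp)
    n_final <- round(min(max(n_final, 1e5), 1e9))
    reps <- lapply(seq_len(n_replicates), function(r) {
      s <- stage_seed(seed, paste0("fluct.", names(assays)[i], ".", r))
      assay <- simulate_fluctuation_assay(m_true, n_final = n_final,
                                          target_size_bp = target_size_bp,
                                          n_cultures = n_cultures, seed = s)
      plates <- simulate_cfu_plates(n_final, dilution_factors = 100 / n_final,
                                    n_plates = n_plates,
                                    seed = stage_seed(seed,
                                      paste0("cfu.", names(assays)[i], ".", r)))
      list(assay = assay, plates = plates)
    })
    assays[[i]] <- reps
    curves[[i]] <- simulate_growth_curves(
      rates$mu_true[i], noise_sd = growth_noise_sd, n_wells = n_wells,
      duration_h = duration_h, interval_h = interval_h,
      seed = stage_seed(seed, paste0("growth.", names(curves)[i])))
  }
  list(rates = rates, assays = assays, curves = curves)
}
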