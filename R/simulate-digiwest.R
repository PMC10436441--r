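#' Configuration for a synthetic matched PDM/PTT profiling cohort
#'
#' Defines the study conditions emulated by [simulate_digiwest_cohort()]:
#' a cohort of matched microtumor (PDM) / primary-tumor-tissue (PTT) pairs
#' profiled for a panel of (phospho-)proteins on a 96-fraction
#' molecular-weight grid. Defaults mirror the profiling arm of the study this
#' pipeline was built for: 20 matched pairs, 142 analytes, a median
#' per-protein PDM-PTT correlation of 0.44, and immune-marker attenuation in
#' the microtumors.
#'
#' @param n_pairs number of matched PDM/PTT pairs.
#' @param n_analytes number of analytes (total and phosphorylated proteins).
#' @param pair_correlation target per-protein Pearson correlation between PDM
#'   and PTT members across pairs, in `[0, 1]`.
#' @param subtype_fractions named numeric, fractions of `HR+`, `TNBC` and
#'   `HER2+` pairs (must sum to 1).
#' @param pathway_effects list of effects, each a list with elements
#'   `analytes` (analyte ids or a pathway name), `log2_effect`, and either
#'   `subtype` (e.g. `"TNBC"`) or `tissue` (`"PDM"`/`"PTT"`) naming the
#'   affected samples.
#' @param n_immune number of analytes acting as immune-cell markers; these
#'   are attenuated in PDM samples by `immune_attenuation` log2 units
#'   (microtumors carry few infiltrating immune cells).
#' @param immune_attenuation log2 attenuation of immune markers in PDMs.
#' @param loading_cv coefficient of variation of per-sample total protein.
#' @param peak_sigma_fractions Gaussian peak width (sd) on the fraction grid.
#' @param baseline_level constant fluorescence background added to each lane.
#' @param noise_cv multiplicative (lognormal) noise CV per fraction reading.
#' @param analyte_log2_sd between-analyte sd of mean log2 abundance.
#' @param within_log2_sd between-sample sd of log2 abundance per analyte.
#' @param mean_log2_abundance grand mean log2 abundance (AFI-scale units).
#' @param mw_range_kda range the analytes' expected molecular weights are
#'   drawn from (kept inside the calibrated range so peaks fit on the grid).
#' @param calibration fraction-to-kDa table, see [default_mw_calibration()].
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_pairs = 20, n_analytes = 142,
                          pair_correlation = 0.44,
                          subtype_fractions = c("HR+" = 0.6, "TNBC" = 0.3,
                                                "HER2+" = 0.1),
                          pathway_effects = list(),
                          n_immune = 8, immune_attenuation = 1.5,
                          loading_cv = 0.2, peak_sigma_fractions = 1.5,
                          baseline_level = 20, noise_cv = 0.05,
                          analyte_log2_sd = 1, within_log2_sd = 1,
                          mean_log2_abundance = 10,
                          mw_range_kda = c(20, 200),
                          calibration = default_mw_calibration(),
                          seed = 1L) {
  stopifnot(n_pairs >= 1, n_analytes >= 1)
  check_fraction(pair_correlation, "pair_correlation")
  check_positive(c(loading_cv, baseline_level, noise_cv, n_immune), "rates",
                 strict = FALSE)
  check_positive(peak_sigma_fractions, "peak_sigma_fractions")
  if (abs(sum(subtype_fractions) - 1) > 1e-8) {
    stop_named("subtype_fractions must sum to 1")
  }
  validate_calibration(calibration)
  if (min(mw_range_kda) < min(calibration$kda) ||
      max(mw_range_kda) > max(calibration$kda)) {
    stop_named("mw_range_kda [%.1f, %.1f] outside calibrated MW range [%.1f, %.1f]",
               min(mw_range_kda), max(mw_range_kda),
               min(calibration$kda), max(calibration$kda))
  }
  structure(
    list(n_pairs = as.integer(n_pairs), n_analytes = as.integer(n_analytes),
         pair_correlation = pair_correlation,
         subtype_fractions = subtype_fractions,
         pathway_effects = pathway_effects,
         n_immune = as.integer(min(n_immune, n_analytes)),
         immune_attenuation = immune_attenuation,
         loading_cv = loading_cv,
         peak_sigma_fractions = peak_sigma_fractions,
         baseline_level = baseline_level, noise_cv = noise_cv,
         analyte_log2_sd = analyte_log2_sd, within_log2_sd = within_log2_sd,
         mean_log2_abundance = mean_log2_abundance,
         mw_range_kda = mw_range_kda, calibration = calibration,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

pathway_names <- function() {
  c("cell cycle", "Jak/STAT", "MAPK", "RTK", "PI3K/Akt",
    "EMT/cytoskeleton", "Wnt")
}

#' Simulate a matched PDM/PTT bead-array profiling cohort
#'
#' Generates raw per-fraction fluorescence lanes for every (antibody, sample)
#' combination, per-sample total protein amounts, sample metadata and the
#' latent ground truth. Each lane carries one Gaussian peak centred at the
#' analyte's expected molecular weight with area equal to the latent
#' abundance times the sample's loading factor, on top of a constant baseline
#' and multiplicative noise. PDM and PTT members of a pair share a latent
#' component so that the per-protein correlation across pairs approaches
#' `pair_correlation`; immune-marker analytes are attenuated in PDMs and
#' `pathway_effects` shift the designated analytes in the designated
#' subtype/tissue.
#'
#' @param config a [cohort_config()].
#' @return list with elements `profiles` (long data.frame
#'   `sample_id, antibody_id, fraction_index, mfi`), `totals`
#'   (`sample_id, total_protein`), `specs` (peak specifications for
#'   [build_afi_matrix()]), `calibration`, `metadata` (per-sample clinical
#'   annotations incl. `pair_id`, `tissue`, `subtype`, `histotype`),
#'   `analytes` (incl. `pathway` and `immune` flag) and `truth`
#'   (`true_abundance` matrix on the linear AFI scale, `loading_factor`).
#' @export
simulate_digiwest_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    np <- config$n_pairs
    na <- config$n_analytes
    analyte_ids <- sprintf("A%03d", seq_len(na))
    pair_ids <- sprintf("P%02d", seq_len(np))
    sample_ids <- c(paste0(pair_ids, "_PDM"), paste0(pair_ids, "_PTT"))
    tissue <- rep(c("PDM", "PTT"), each = np)

    # clinical annotations assigned per pair, shared by both members
    subtype <- sample(names(config$subtype_fractions), np, replace = TRUE,
                      prob = config$subtype_fractions)
    histotype <- sample(c("NST", "ILC"), np, replace = TRUE,
                        prob = c(0.8, 0.2))
    metadata <- data.frame(
      sample_id = sample_ids,
      pair_id = rep(pair_ids, 2),
      tissue = tissue,
      subtype = rep(subtype, 2),
      histotype = rep(histotype, 2),
      stringsAsFactors = FALSE
    )

    # analyte panel: expected MW log-uniform, pathways round-robin,
    # the first n_immune analytes act as immune-cell markers
    expected_mw <- exp(runif(na, log(config$mw_range_kda[1]),
                             log(config$mw_range_kda[2])))
    immune <- seq_len(na) <= config$n_immune
    pathway <- rep(pathway_names(), length.out = na)
    pathway[immune] <- "immune"
    analytes <- data.frame(
      analyte_id = analyte_ids,
      antibody_id = sprintf("Ab%03d", seq_len(na)),
      expected_mw = expected_mw,
      pathway = pathway,
      immune = immune,
      stringsAsFactors = FALSE
    )

    # latent log2 abundance: shared-component model inducing the target
    # per-protein PDM-PTT correlation across pairs
    rho <- config$pair_correlation
    sw <- config$within_log2_sd
    mu_a <- rnorm(na, config$mean_log2_abundance, config$analyte_log2_sd)
    z <- matrix(rnorm(na * np, 0, sw * sqrt(rho)), na, np)
    e1 <- matrix(rnorm(na * np, 0, sw * sqrt(1 - rho)), na, np)
    e2 <- matrix(rnorm(na * np, 0, sw * sqrt(1 - rho)), na, np)
    l2 <- cbind(mu_a + z + e1, mu_a + z + e2)  # PDM cols then PTT cols
    dimnames(l2) <- list(analyte_ids, sample_ids)

    # immune markers attenuated in microtumors
    l2[immune, tissue == "PDM"] <-
      l2[immune, tissue == "PDM"] - config$immune_attenuation

    # configured subtype/tissue effects on named analytes or whole pathways
    for (eff in config$pathway_effects) {
      rows <- if (all(eff$analytes %in% analyte_ids)) {
        match(eff$analytes, analyte_ids)
      } else {
        which(pathway %in% eff$analytes)
      }
      cols <- rep(TRUE, 2 * np)
      if (!is.null(eff$subtype)) cols <- cols & metadata$subtype == eff$subtype
      if (!is.null(eff$tissue)) cols <- cols & metadata$tissue == eff$tissue
      l2[rows, cols] <- l2[rows, cols] + eff$log2_effect
    }

    true_abundance <- 2^l2

    # per-sample loading; loading factor relative to the cohort median so
    # that total-protein normalization recovers the latent abundance
    total_protein <- 10 * rlnorm_cv(2 * np, config$loading_cv)
    loading_factor <- total_protein / median(total_protein)
    totals <- data.frame(sample_id = sample_ids,
                         total_protein = total_protein,
                         stringsAsFactors = FALSE)

    # lane synthesis: one Gaussian peak per analyte at its expected MW
    calib <- config$calibration[order(config$calibration$fraction_index), ]
    grid <- 0:95
    # fractional peak centre via interpolation of index against log(kDa)
    centre <- approx(log(calib$kda), calib$fraction_index,
                     xout = log(expected_mw))$y
    sigma <- config$peak_sigma_fractions

    n_samp <- 2 * np
    profiles <- vector("list", na)
    for (ai in seq_len(na)) {
      shape <- dnorm(grid, centre[ai], sigma)             # 96
      area <- true_abundance[ai, ] * loading_factor       # n_samp
      signal <- outer(shape, area) + config$baseline_level
      if (config$noise_cv > 0) {
        signal <- signal * matrix(rlnorm_cv(96 * n_samp, config$noise_cv),
                                  96, n_samp)
      }
      profiles[[ai]] <- data.frame(
        sample_id = rep(sample_ids, each = 96),
        antibody_id = analytes$antibody_id[ai],
        fraction_index = rep(grid, n_samp),
        mfi = as.vector(signal),
        stringsAsFactors = FALSE
      )
    }
    profiles <- do.call(rbind, profiles)

    # emitted integration windows cover +/- 4.5 peak sd on the fraction grid
    # (converted to kDa via the log-spaced calibration step)
    dlog <- abs(diff(log(range(calib$kda)))) / 95
    specs <- analytes[, c("analyte_id", "antibody_id", "expected_mw")]
    specs$window_kda <- expected_mw * (exp(4.5 * sigma * dlog) - 1)

    list(
      profiles = profiles,
      totals = totals,
      specs = specs,
      calibration = calib,
      metadata = metadata,
      analytes = analytes,
      truth = list(true_abundance = true_abundance,
                   loading_factor = stats::setNames(loading_factor, sample_ids),
                   log2_abundance = l2)
    )
  })
}
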