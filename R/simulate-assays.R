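#' Simulate a cytotoxicity plate experiment
#'
#' Emulates a CellTox-style membrane-integrity assay: replicate wells of
#' microtumors per sample and drug, measured as RFU at a series of
#' timepoints, with vehicle-control and blank wells. The dye signal is
#' proportional to cell death, so wells of true responders carry a
#' treatment effect that grows over the time series up to `effect_size` at
#' the final timepoint. Outliers (pipetting/readout artifacts) are injected
#' multiplicatively at rate `outlier_rate`.
#'
#' @param n_samples number of microtumor samples.
#' @param drugs character vector of drug names (defaults to the four agents
#'   of the study: tamoxifen, docetaxel, paclitaxel, palbociclib).
#' @param responder_fraction probability that a (sample, drug) combination is
#'   a true responder.
#' @param effect_size fold increase in the death signal of responders at the
#'   final timepoint (>= 1; 1 = null).
#' @param outlier_rate per-measurement probability of an injected outlier.
#' @param outlier_factor multiplicative size of injected outliers.
#' @param noise_cv lognormal noise CV of well readings.
#' @param n_replicates replicate wells per condition (3-5 in the assay).
#' @param timepoints_h measurement timepoints in hours.
#' @param base_rfu vehicle-well signal above background.
#' @param blank_rfu background (medium-only) signal level.
#' @param seed integer seed.
#' @return list with `table` (data.frame
#'   `sample_id, drug, dose, timepoint_h, replicate_id, role, rfu`) and
#'   `truth` (`responder` data.frame per sample x drug;
#'   `outliers` data.frame of injected outlier measurements;
#'   `multiplier` per timepoint for responders).
#' @export
simulate_cytotox_plate <- function(n_samples = 29,
                                   drugs = c("TAM", "DTX", "PTX", "PAB"),
                                   responder_fraction = 0.2,
                                   effect_size = 3,
                                   outlier_rate = 0,
                                   outlier_factor = 5,
                                   noise_cv = 0.1,
                                   n_replicates = 5,
                                   timepoints_h = c(24, 48, 72),
                                   base_rfu = 1000,
                                   blank_rfu = 100,
                                   seed = 1L) {
  check_fraction(responder_fraction, "responder_fraction")
  check_fraction(outlier_rate, "outlier_rate")
  if (effect_size < 1) stop_named("effect_size must be >= 1")
  check_positive(noise_cv, "noise_cv", strict = FALSE)
  stopifnot(n_replicates >= 2, length(timepoints_h) >= 2)

  doses <- c(TAM = "100 nM", DTX = "5.5 uM", PTX = "4 uM", PAB = "150 nM")
  with_seed(seed, {
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    responder <- expand.grid(sample_id = sample_ids, drug = drugs,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    responder$responder <- runif(nrow(responder)) < responder_fraction

    tmax <- max(timepoints_h)
    mult <- 1 + (effect_size - 1) * timepoints_h / tmax

    grid <- expand.grid(
      replicate_id = sprintf("W%d", seq_len(n_replicates)),
      role = c("treatment", "vehicle"),
      timepoint_h = timepoints_h,
      drug = drugs,
      sample_id = sample_ids,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    key <- paste(grid$sample_id, grid$drug)
    is_resp <- responder$responder[match(key, paste(responder$sample_id,
                                                    responder$drug))]
    m <- ifelse(grid$role == "treatment" & is_resp,
                mult[match(grid$timepoint_h, timepoints_h)], 1)
    rfu <- blank_rfu + base_rfu * m * rlnorm_cv(nrow(grid), noise_cv)

    out_flag <- runif(nrow(grid)) < outlier_rate
    rfu[out_flag] <- rfu[out_flag] * outlier_factor

    blanks <- expand.grid(
      replicate_id = c("B1", "B2"),
      role = "blank",
      timepoint_h = timepoints_h,
      drug = drugs,
      sample_id = sample_ids,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    blanks$rfu <- blank_rfu * rlnorm_cv(nrow(blanks), noise_cv / 2)
    grid$rfu <- rfu

    tab <- rbind(grid, blanks)
    tab$dose <- unname(doses[tab$drug])
    tab <- tab[, c("sample_id", "drug", "dose", "timepoint_h",
                   "replicate_id", "role", "rfu")]
    tab <- tab[order(tab$sample_id, tab$drug, tab$timepoint_h,
                     tab$role, tab$replicate_id), ]
    rownames(tab) <- NULL

    outliers <- grid[out_flag, c("sample_id", "drug", "timepoint_h",
                                 "replicate_id", "role")]
    rownames(outliers) <- NULL
    list(table = tab,
         truth = list(responder = responder, outliers = outliers,
                      multiplier = stats::setNames(mult, timepoints_h)))
  })
}

#' Simulate a stained brightfield image by the Beer-Lambert forward model
#'
#' Synthesizes an RGB image in which each stain occupies a spatially disjoint
#' block of pixels at the requested area fraction; pixel intensities follow
#' `I_c = I0_c * 10^(-A[s, c] * conc_s)` with optional additive Gaussian
#' noise in gray levels. The ground truth records the binary per-stain masks
#' and the realised area fractions.
#'
#' @param stains a stain matrix (see [stain_matrix()]) or a preset name
#'   accepted by [stain_preset()].
#' @param true_fractions numeric vector of per-stain area proportions (sum
#'   <= 1; remaining pixels are unstained background).
#' @param concentrations per-stain concentration in each stained pixel.
#' @param size image height and width in pixels.
#' @param background_intensity per-channel I0 (default 255 for all channels).
#' @param noise_sd additive Gaussian noise sd in gray levels (0-255 scale).
#' @param seed integer seed.
#' @return list with `image` (height x width x 3 double array on the 0-255
#'   scale) and `truth` (`masks`: list of logical matrices; `area_fraction`:
#'   realised per-stain fractions in percent; `concentrations`).
#' @export
simulate_stain_image <- function(stains = "dab_h",
                                 true_fractions = c(0.25),
                                 concentrations = rep(1, length(true_fractions)),
                                 size = c(64, 64),
                                 background_intensity = c(255, 255, 255),
                                 noise_sd = 0, seed = 1L) {
  if (is.character(stains)) stains <- stain_preset(stains)
  stains <- validate_stain_matrix(stains)
  ns <- length(true_fractions)
  if (ns > nrow(stains)) {
    stop_named("more fractions (%d) than stain vectors (%d)", ns, nrow(stains))
  }
  check_positive(true_fractions, "true_fractions", strict = FALSE)
  if (sum(true_fractions) > 1 + 1e-12) {
    stop_named("stain fractions must sum to <= 1")
  }
  stopifnot(length(concentrations) == ns, length(size) == 2)
  h <- size[1]; w <- size[2]; npx <- h * w
  i0 <- rep(background_intensity, length.out = 3)

  with_seed(seed, {
    counts <- round(true_fractions * npx)
    bounds <- cumsum(c(0, counts))
    assign_s <- integer(npx)  # 0 = background
    for (s in seq_len(ns)) {
      if (counts[s] > 0) assign_s[(bounds[s] + 1):bounds[s + 1]] <- s
    }
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      od <- numeric(npx)
      for (s in seq_len(ns)) {
        od[assign_s == s] <- stains[s, ch] * concentrations[s]
      }
      plane <- i0[ch] * 10^(-od)
      if (noise_sd > 0) plane <- plane + rnorm(npx, 0, noise_sd)
      img[, , ch] <- matrix(pmin(pmax(plane, 0), 255), h, w)
    }
    masks <- lapply(seq_len(ns), function(s) matrix(assign_s == s, h, w))
    names(masks) <- rownames(stains)[seq_len(ns)]
    list(image = img,
         truth = list(masks = masks,
                      area_fraction = 100 * counts / npx,
                      concentrations = concentrations))
  })
}

#' Simulate live/dead viability measurements for a cohort of 3D models
#'
#' Per model, generates live- and dead-channel fluorescence intensity sums
#' together with the measured model volume, such that the expected
#' live-to-dead ratio of the volume-normalized intensities equals
#' `live_dead_ratio`.
#'
#' @param n_models number of microtumor models (the study quantified 27).
#' @param live_dead_ratio expected ratio of volume-normalized live to dead
#'   signal (> 0; 1 = null, no viability difference).
#' @param volume_range model volume range in cubic micrometres.
#' @param mean_live_norm expected live intensity per cubic micrometre.
#' @param noise_cv lognormal noise CV of the normalized intensities.
#' @param seed integer seed.
#' @return list with `records` (data.frame `model_id, live_intensity_sum,
#'   dead_intensity_sum, total_volume_um3`) and `truth` (target normalized
#'   intensities).
#' @export
simulate_viability <- function(n_models = 27, live_dead_ratio = 10,
                               volume_range = c(1e4, 8e5),
                               mean_live_norm = 50, noise_cv = 0.2,
                               seed = 1L) {
  check_positive(live_dead_ratio, "live_dead_ratio")
  check_positive(volume_range, "volume_range")
  with_seed(seed, {
    vol <- runif(n_models, volume_range[1], volume_range[2])
    live_norm <- mean_live_norm * rlnorm_cv(n_models, noise_cv)
    dead_norm <- (mean_live_norm / live_dead_ratio) *
      rlnorm_cv(n_models, noise_cv)
    records <- data.frame(
      model_id = sprintf("M%02d", seq_len(n_models)),
      live_intensity_sum = live_norm * vol,
      dead_intensity_sum = dead_norm * vol,
      total_volume_um3 = vol,
      stringsAsFactors = FALSE
    )
    list(records = records,
         truth = list(live_norm = live_norm, dead_norm = dead_norm))
  })
}
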