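#' Default molecular-weight calibration for a 96-fraction lane
#'
#' Bead-array western blotting cuts each protein lane into 96 strips; each
#' strip (bead colour) corresponds to an apparent molecular weight. Gel
#' migration is close to linear in log(MW), so the default calibration maps
#' fraction indices 0..95 onto a log-spaced grid running from high to low
#' molecular weight, mirroring the top-to-bottom orientation of a gel.
#'
#' @param kda_range length-2 numeric, apparent MW at fraction 0 and at
#'   fraction 95 (kDa). Default `c(260, 10)`.
#' @return data.frame with columns `fraction_index` (0..95) and `kda`.
#' @export
default_mw_calibration <- function(kda_range = c(260, 10)) {
  check_positive(kda_range, "kda_range")
  if (kda_range[1] == kda_range[2]) stop_named("calibration must be monotone")
  data.frame(
    fraction_index = 0:95,
    kda = exp(seq(log(kda_range[1]), log(kda_range[2]), length.out = 96))
  )
}

validate_calibration <- function(calibration) {
  need <- c("fraction_index", "kda")
  if (!all(need %in% names(calibration))) {
    stop_named("calibration needs columns %s", paste(need, collapse = ", "))
  }
  if (!setequal(calibration$fraction_index, 0:95)) {
    stop_named("calibration must cover fraction indices 0..95 exactly")
  }
  check_positive(calibration$kda, "calibration kda")
  kda <- calibration$kda[order(calibration$fraction_index)]
  d <- diff(kda)
  if (!(all(d > 0) || all(d < 0))) {
    stop_named("calibration must be strictly monotone in fraction index")
  }
  invisible(calibration)
}

#' Reconstruct a virtual blot lane from per-fraction fluorescence
#'
#' Re-indexes the 96 median-fluorescence readings of one antibody on one
#' sample from fraction index to apparent molecular weight, producing the
#' "virtual western blot lane" in which protein bands appear as peaks. This is
#' a pure re-indexing: intensities are unchanged and the result is sorted by
#' ascending kDa, so the orientation of the calibration does not matter.
#'
#' @param profile data.frame with columns `fraction_index` (0..95, unique,
#'   complete) and `mfi` (median fluorescence, >= 0). Columns `sample_id` and
#'   `antibody_id` are carried along if present.
#' @param calibration data.frame mapping `fraction_index` to `kda`, strictly
#'   monotone (see [default_mw_calibration()]).
#' @return data.frame with columns `kda`, `intensity`, `fraction_index`,
#'   sorted by ascending `kda`.
#' @export
reconstruct_lane <- function(profile, calibration) {
  validate_calibration(calibration)
  if (!all(c("fraction_index", "mfi") %in% names(profile))) {
    stop_named("profile needs columns 'fraction_index' and 'mfi'")
  }
  idx <- profile$fraction_index
  if (anyDuplicated(idx)) {
    stop_named("duplicate fraction index %d in profile",
               idx[duplicated(idx)][1])
  }
  missing <- setdiff(0:95, idx)
  if (length(missing)) {
    stop_named("profile is missing fraction index %d (expected 96 fractions)",
               missing[1])
  }
  if (any(!is.finite(profile$mfi)) || any(profile$mfi < 0)) {
    stop_named("fluorescence must be finite and non-negative")
  }
  kda <- calibration$kda[match(idx, calibration$fraction_index)]
  lane <- data.frame(kda = kda, intensity = profile$mfi,
                     fraction_index = idx)
  lane[order(lane$kda), , drop = FALSE]
}

default_window_kda <- function(expected_mw, calibration) {
  # proportional window (15% of the expected MW) tracks the log-spaced axis;
  # widen if it would cover fewer than 2 fractions on either side of centre
  w <- 0.15 * expected_mw
  kda <- sort(calibration$kda)
  ctr <- which.min(abs(kda - expected_mw))
  lo <- kda[max(1L, ctr - 2L)]
  hi <- kda[min(length(kda), ctr + 2L)]
  max(w, expected_mw - lo, hi - expected_mw)
}

#' Integrate one analyte peak with local background subtraction
#'
#' Locates the peak of an expected molecular weight inside a reconstructed
#' lane, subtracts a local linear background and integrates the remaining
#' area. The background is a straight line anchored at the mean intensity of
#' the two fractions flanking each edge of the integration window, which makes
#' the integral exactly invariant to any constant baseline and to linear
#' drifts. The integral (trapezoidal, in fluorescence x fraction units) is the
#' AFI — the study's protein-abundance unit. Negative background-corrected
#' contributions are clamped at zero, and the final AFI is floored at zero.
#'
#' @param lane output of [reconstruct_lane()].
#' @param spec list or one-row data.frame with `analyte_id`, `expected_mw`
#'   (kDa) and optionally `window_kda` (half-width; default 15% of
#'   `expected_mw`, widened to cover at least 2 fractions each side).
#' @param sample_id sample identifier recorded in the result.
#' @return one-row data.frame (an AFI record): `analyte_id`, `sample_id`,
#'   `afi`, `below_limit`, `peak_center_kda`, `window_lo_kda`, `window_hi_kda`,
#'   `background_level`.
#' @export
integrate_peak <- function(lane, spec, sample_id = NA_character_) {
  expected_mw <- as.numeric(spec$expected_mw)
  check_positive(expected_mw, "expected_mw")
  rng <- range(lane$kda)
  if (expected_mw < rng[1] || expected_mw > rng[2]) {
    stop_named("expected MW %.1f kDa outside calibrated range [%.1f, %.1f]",
               expected_mw, rng[1], rng[2])
  }
  w <- spec$window_kda
  if (is.null(w) || length(w) == 0L || is.na(w)) {
    w <- default_window_kda(expected_mw,
                            data.frame(kda = lane$kda))
  }
  check_positive(w, "window_kda")
  in_win <- which(lane$kda >= expected_mw - w & lane$kda <= expected_mw + w)
  if (length(in_win) == 0L) stop_named("integration window contains no fractions")
  in_win <- seq(min(in_win), max(in_win))  # contiguous by construction
  if (length(in_win) < 2L) {
    in_win <- sort(unique(pmin(pmax(c(in_win - 1L, in_win, in_win + 1L), 1L),
                               nrow(lane))))
  }

  # peak centre: maximum inside the window, ties towards the expected MW
  y <- lane$intensity[in_win]
  peaked <- in_win[y == max(y)]
  peak_i <- peaked[which.min(abs(lane$kda[peaked] - expected_mw))]

  # local linear background through the mean of the two flanking fractions
  # at each window edge (the edge fraction itself when at the lane boundary)
  n <- nrow(lane)
  lo_flank <- unique(pmax(min(in_win) - c(1L, 2L), 1L))
  hi_flank <- unique(pmin(max(in_win) + c(1L, 2L), n))
  lo_flank <- setdiff(lo_flank, in_win)
  hi_flank <- setdiff(hi_flank, in_win)
  if (length(lo_flank) == 0L) lo_flank <- min(in_win)
  if (length(hi_flank) == 0L) hi_flank <- max(in_win)
  b_lo <- mean(lane$intensity[lo_flank])
  b_hi <- mean(lane$intensity[hi_flank])
  x_lo <- mean(lo_flank)
  x_hi <- mean(hi_flank)
  slope <- if (x_hi == x_lo) 0 else (b_hi - b_lo) / (x_hi - x_lo)
  background <- b_lo + slope * (in_win - x_lo)

  corrected <- pmax(lane$intensity[in_win] - background, 0)
  # trapezoidal integral on the fraction grid (unit spacing)
  afi <- sum((corrected[-1] + corrected[-length(corrected)]) / 2)
  afi <- max(afi, 0)

  data.frame(
    analyte_id = as.character(spec$analyte_id %||% NA_character_),
    sample_id = sample_id,
    afi = afi,
    below_limit = FALSE,
    peak_center_kda = lane$kda[peak_i],
    window_lo_kda = expected_mw - w,
    window_hi_kda = expected_mw + w,
    background_level = mean(background),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the raw AFI expression matrix from lane profiles
#'
#' Runs [reconstruct_lane()] and [integrate_peak()] over every requested
#' (analyte, sample) combination and assembles the analyte-by-sample AFI
#' matrix. Missing lanes are recorded as below-limit candidates (`NA` cells,
#' later imputed by [impute_weak_signals()]) with a warning, never silently
#' dropped. A per-lane QC table (peak centre, window, background level) is
#' attached as attribute `"qc"`.
#'
#' @param profiles long data.frame with columns
#'   `sample_id, antibody_id, fraction_index, mfi` (96 rows per lane).
#' @param specs data.frame with columns `analyte_id, antibody_id, expected_mw`
#'   and optional `window_kda`.
#' @param calibration fraction-to-kDa calibration (see
#'   [default_mw_calibration()]).
#' @param samples optional sample metadata data.frame (`sample_id`, ...).
#' @param analytes optional analyte metadata (`analyte_id`, e.g. `pathway`).
#' @return an [expression_matrix()] with `scale_tag = "raw_afi"`; missing
#'   lanes are `NA` and flagged in `$below_limit`.
#' @export
build_afi_matrix <- function(profiles, specs, calibration, samples = NULL,
                             analytes = NULL) {
  validate_calibration(calibration)
  need <- c("sample_id", "antibody_id", "fraction_index", "mfi")
  if (!all(need %in% names(profiles))) {
    stop_named("profiles need columns %s", paste(need, collapse = ", "))
  }
  if (!all(c("analyte_id", "antibody_id", "expected_mw") %in% names(specs))) {
    stop_named("specs need columns analyte_id, antibody_id, expected_mw")
  }
  key <- paste(profiles$sample_id, profiles$antibody_id, sep = "\r")
  lane_split <- split(profiles, key)
  lane_counts <- vapply(lane_split, nrow, integer(1))
  if (any(lane_counts != 96L)) {
    bad <- names(lane_counts)[lane_counts != 96L][1]
    stop_named("lane %s has %d fractions (expected 96)",
               gsub("\r", "/", bad), lane_counts[lane_counts != 96L][1])
  }

  sample_ids <- sort(unique(profiles$sample_id))
  analyte_ids <- as.character(specs$analyte_id)
  if (anyDuplicated(analyte_ids)) stop_named("duplicate analyte ids in specs")

  values <- matrix(NA_real_, length(analyte_ids), length(sample_ids),
                   dimnames = list(analyte_ids, sample_ids))
  below <- matrix(FALSE, length(analyte_ids), length(sample_ids),
                  dimnames = dimnames(values))
  qc <- vector("list", length(analyte_ids) * length(sample_ids))
  k <- 0L
  for (ai in seq_along(analyte_ids)) {
    spec <- specs[ai, , drop = FALSE]
    for (si in seq_along(sample_ids)) {
      lane_key <- paste(sample_ids[si], spec$antibody_id, sep = "\r")
      prof <- lane_split[[lane_key]]
      if (is.null(prof)) {
        warning(sprintf("missing lane for sample %s, antibody %s; flagged below limit",
                        sample_ids[si], spec$antibody_id), call. = FALSE)
        below[ai, si] <- TRUE
        next
      }
      lane <- reconstruct_lane(prof, calibration)
      rec <- integrate_peak(lane, spec, sample_id = sample_ids[si])
      values[ai, si] <- rec$afi
      k <- k + 1L
      qc[[k]] <- rec
    }
  }
  em <- expression_matrix(values, "raw_afi", samples = samples,
                          analytes = analytes, below_limit = below)
  attr(em, "qc") <- do.call(rbind, qc[seq_len(k)])
  em
}

#' Normalize AFI columns to total protein loaded
#'
#' Each sample column is rescaled by (median of all totals) / (sample total),
#' correcting for unequal protein amounts loaded onto the beads while keeping
#' values on the raw AFI scale (the cohort-median rescaling makes the
#' operation a no-op when all totals are equal).
#'
#' @param em [expression_matrix()] with `scale_tag = "raw_afi"`.
#' @param totals data.frame with columns `sample_id`, `total_protein` (> 0),
#'   covering every sample in `em`.
#' @return an `expression_matrix` with `scale_tag = "total_normalized"`.
#' @export
normalize_total_protein <- function(em, totals) {
  check_scale(em, "raw_afi", "normalize_total_protein")
  if (!all(c("sample_id", "total_protein") %in% names(totals))) {
    stop_named("totals need columns sample_id, total_protein")
  }
  m <- match(colnames(em$values), totals$sample_id)
  if (anyNA(m)) {
    stop_named("no total protein amount for sample %s",
               colnames(em$values)[which(is.na(m))[1]])
  }
  tp <- totals$total_protein[m]
  bad <- which(!is.finite(tp) | tp <= 0)
  if (length(bad)) {
    stop_named("non-positive total protein for sample %s",
               colnames(em$values)[bad[1]])
  }
  scaled <- sweep(em$values, 2, median(tp) / tp, `*`)
  out <- expression_matrix(scaled, "total_normalized", samples = em$samples,
                           analytes = em$analytes, below_limit = em$below_limit)
  attr(out, "qc") <- attr(em, "qc")
  out
}

#' Impute weak protein signals as "lower detection limit minus one"
#'
#' For each analyte the lower detection limit is the smallest strictly
#' positive value observed across samples; cells that are zero, missing or
#' flagged below limit are set to (limit - 1), floored at 1 so that the
#' subsequent log2 transform is defined. All cells are >= 1 afterwards.
#'
#' @param em [expression_matrix()] on scale `raw_afi` or `total_normalized`.
#' @return an `expression_matrix` on the same scale with no missing values
#'   and all cells >= 1; imputed cells flagged in `$below_limit`.
#' @export
impute_weak_signals <- function(em) {
  check_scale(em, c("raw_afi", "total_normalized"), "impute_weak_signals")
  v <- em$values
  below <- em$below_limit
  if (is.null(below)) below <- matrix(FALSE, nrow(v), ncol(v),
                                      dimnames = dimnames(v))
  for (a in seq_len(nrow(v))) {
    row <- v[a, ]
    pos <- row[is.finite(row) & row > 0]
    if (length(pos) == 0L) {
      warning(sprintf("analyte %s has no positive signal; imputed to 1",
                      rownames(v)[a]), call. = FALSE)
      limit <- 2  # (limit - 1) = 1
    } else {
      limit <- min(pos)
    }
    weak <- is.na(row) | row <= 0 | below[a, ]
    v[a, weak] <- max(limit - 1, 1)
    below[a, ] <- weak
  }
  v[v < 1] <- 1  # log2-safety floor on the whole matrix
  out <- expression_matrix(v, em$scale_tag, samples = em$samples,
                           analytes = em$analytes, below_limit = below)
  attr(out, "qc") <- attr(em, "qc")
  out
}

#' Log2-transform an imputed AFI matrix
#'
#' Plain log2 transform (no centering), the scale on which between-sample
#' means are compared and correlated. Requires an imputed matrix (all values
#' >= 1) so the transform is defined and non-negative.
#'
#' @param em imputed [expression_matrix()] on scale `raw_afi` or
#'   `total_normalized`.
#' @return an `expression_matrix` with `scale_tag = "log2"`.
#' @export
log2_transform <- function(em) {
  check_scale(em, c("raw_afi", "total_normalized"), "log2_transform")
  if (anyNA(em$values) || any(em$values < 1)) {
    stop_named("matrix must be imputed (all values >= 1) before log2; run impute_weak_signals()")
  }
  out <- expression_matrix(log2(em$values), "log2", samples = em$samples,
                           analytes = em$analytes,
                           below_limit = em$below_limit)
  attr(out, "qc") <- attr(em, "qc")
  out
}

#' Log2-transform and median-centre an AFI matrix
#'
#' Values are log2-transformed, then for every analyte the median over the
#' chosen centering scope (e.g. all samples, or the PDM samples only) is
#' subtracted from all samples. The scope is recorded in the result so that
#' downstream analyses can report which reference the values are relative to.
#'
#' @param em imputed [expression_matrix()] (all values >= 1) on scale
#'   `raw_afi` or `total_normalized`.
#' @param scope `"all"`, `"pdm"` (samples whose `tissue` metadata is
#'   `"PDM"`), or a character vector of sample ids.
#' @return an `expression_matrix` with `scale_tag = "median_centered"`; per
#'   analyte, the median over the scope is 0 (to within 1e-9).
#' @export
median_center_log2 <- function(em, scope = "all") {
  check_scale(em, c("raw_afi", "total_normalized"), "median_center_log2")
  v <- em$values
  if (anyNA(v) || any(v < 1)) {
    stop_named("matrix must be imputed (all values >= 1) before centering; run impute_weak_signals()")
  }
  scope_ids <- resolve_scope(em, scope)
  if (length(scope_ids) == 0L) stop_named("empty centering scope")
  lv <- log2(v)
  med <- apply(lv[, scope_ids, drop = FALSE], 1, median)
  centered <- sweep(lv, 1, med, `-`)
  out <- expression_matrix(centered, "median_centered", samples = em$samples,
                           analytes = em$analytes,
                           centering_scope = scope_ids,
                           below_limit = em$below_limit)
  attr(out, "qc") <- attr(em, "qc")
  out
}

resolve_scope <- function(em, scope) {
  if (identical(scope, "all")) return(colnames(em$values))
  if (identical(scope, "pdm")) {
    if (!"tissue" %in% names(em$samples)) {
      stop_named("scope 'pdm' needs a 'tissue' column in the sample metadata")
    }
    return(em$samples$sample_id[em$samples$tissue == "PDM"])
  }
  missing <- setdiff(scope, colnames(em$values))
  if (length(missing)) {
    stop_named("scope samples not in matrix: %s", paste(missing, collapse = ", "))
  }
  scope
}
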