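#' Stain optical-density matrix
#'
#' Builds the matrix of per-stain optical-density vectors used for color
#' deconvolution of brightfield images. Rows are stains, columns the R, G, B
#' channels; each row is normalized to unit Euclidean norm. With only two
#' stains the third row is completed as the normalized cross product
#' (orthogonal complement), following the standard construction.
#'
#' @param vectors numeric matrix with 2 or 3 rows and 3 columns, or a list of
#'   length-3 numeric vectors.
#' @param names optional stain names (rownames).
#' @return a 2- or 3-row unit-norm matrix of class `stain_matrix`.
#' @export
stain_matrix <- function(vectors, names = NULL) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3 || !nrow(vectors) %in% 2:3) {
    stop_named("stain matrix must have 2 or 3 rows of 3 OD components")
  }
  if (!is.null(names)) rownames(vectors) <- names
  if (is.null(rownames(vectors))) {
    rownames(vectors) <- paste0("stain", seq_len(nrow(vectors)))
  }
  validate_stain_matrix(vectors)
}

validate_stain_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop_named("zero-length stain vector")
  m <- m / norms
  full <- complete_stain_matrix(m)
  if (kappa(full, exact = TRUE) >= 1e6) {
    stop_named("stain vectors are collinear or near-collinear (condition number >= 1e6)")
  }
  class(m) <- c("stain_matrix", "matrix")
  m
}

complete_stain_matrix <- function(m) {
  if (nrow(m) == 3) return(unclass(m))
  v <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
         m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
         m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_named("stain vectors are collinear")
  rbind(unclass(m), residual = v / n)
}

#' Published stain vector presets
#'
#' Returns the standard published optical-density vectors for common
#' brightfield stain combinations (hematoxylin, eosin, DAB). The Movat
#' collagen stain has no published vector; estimate one from pure-stain
#' pixels with [fit_stain_vector()].
#'
#' @param name `"dab_h"` (hematoxylin + DAB), `"h_e"` (hematoxylin + eosin)
#'   or `"h_e_dab"`.
#' @return a [stain_matrix()].
#' @export
stain_preset <- function(name = c("dab_h", "h_e", "h_e_dab")) {
  name <- match.arg(name)
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  dab <- c(0.268, 0.570, 0.776)
  switch(name,
    dab_h = stain_matrix(rbind(h, dab), names = c("hematoxylin", "dab")),
    h_e = stain_matrix(rbind(h, e), names = c("hematoxylin", "eosin")),
    h_e_dab = stain_matrix(rbind(h, e, dab),
                           names = c("hematoxylin", "eosin", "dab"))
  )
}

#' Estimate a stain vector from user-marked pure-stain pixels
#'
#' Computes the mean unit optical-density vector over a region of pixels that
#' contain a single stain — the explicit counterpart of the study's manual
#' deconvolution of the Movat collagen stain.
#'
#' @param image RGB array (height x width x 3).
#' @param mask logical matrix selecting the pure-stain pixels.
#' @param background_intensity per-channel I0 (default 255).
#' @return a length-3 unit-norm OD vector.
#' @export
fit_stain_vector <- function(image, mask,
                             background_intensity = c(255, 255, 255)) {
  image <- as_rgb255(image)
  stopifnot(is.logical(mask), all(dim(mask) == dim(image)[1:2]))
  if (!any(mask)) stop_named("empty pure-stain selection")
  i0 <- rep(background_intensity, length.out = 3)
  od <- vapply(1:3, function(ch) {
    plane <- image[, , ch]
    mean(-log10(pmax(plane[mask], 1) / i0[ch]))
  }, numeric(1))
  n <- sqrt(sum(od^2))
  if (n < 1e-12) stop_named("selection has no optical density (background pixels?)")
  od / n
}

as_rgb255 <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3) stop_named("expected an RGB array (h x w x 3)")
  if (d[3] > 3) image <- image[, , 1:3, drop = FALSE]  # drop alpha
  if (max(image) <= 1) image <- image * 255             # readPNG/readTIFF scale
  image
}

#' Color deconvolution of a brightfield image (Ruifrok-Johnston)
#'
#' Unmixes an RGB image into per-stain concentration maps by inverting the
#' Beer-Lambert model: per pixel, `OD_c = -log10(max(I_c, 1) / I0_c)` and
#' `concentrations = inverse(stain matrix) %*% OD`. With two stain vectors
#' the third row is completed orthogonally, so its map collects residual
#' density. Negative concentrations are clamped at 0 in the returned maps;
#' the raw (unclamped) maps are attached as attribute `"raw"`.
#'
#' @param image RGB array (height x width x 3), on the 0-255 or 0-1 scale
#'   (e.g. from [png::readPNG()] or [tiff::readTIFF()]).
#' @param stains a [stain_matrix()] or preset name for [stain_preset()].
#' @param background_intensity per-channel I0; must be > 0.
#' @return named list of concentration matrices, one per stain row (plus
#'   `residual` for 2-stain input), each height x width.
#' @export
color_deconvolve <- function(image, stains = "dab_h",
                             background_intensity = c(255, 255, 255)) {
  if (is.character(stains)) stains <- stain_preset(stains)
  stains <- validate_stain_matrix(stains)
  i0 <- rep(background_intensity, length.out = 3)
  if (any(i0 <= 0)) stop_named("background intensity must be positive")
  image <- as_rgb255(image)
  h <- dim(image)[1]; w <- dim(image)[2]

  od <- vapply(1:3, function(ch) {
    -log10(pmax(as.vector(image[, , ch]), 1) / i0[ch])
  }, numeric(h * w))                       # (h*w) x 3
  # per pixel (row vector): OD = conc %*% stain matrix, so conc = OD %*% inv
  full <- complete_stain_matrix(stains)
  conc <- od %*% solve(full)               # (h*w) x 3 stain concentrations

  nm <- rownames(full)
  raw <- lapply(seq_len(nrow(full)), function(s) matrix(conc[, s], h, w))
  names(raw) <- nm
  maps <- lapply(raw, function(m) pmax(m, 0))
  attr(maps, "raw") <- raw
  maps
}

#' Otsu's threshold on an arbitrary-range map
#'
#' Maximizes the between-class variance of the value histogram, the standard
#' automatic threshold for bimodal stain-concentration maps. The search is
#' over bin edges of an `n_bins` histogram spanning the observed range;
#' returned is the threshold value (pixels strictly above it are "positive").
#'
#' @param x numeric vector or matrix of finite values.
#' @param n_bins number of histogram bins.
#' @return a single threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop_named("no finite values to threshold")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          n_bins), n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b[-n_bins])
  edges[k + 1]
}

#' Percent-area fraction of a stain concentration map
#'
#' The semi-quantitative score used for DAB/Movat staining: the percentage of
#' pixels in the image (or in a selection) whose concentration exceeds a
#' threshold. The threshold actually applied is recorded in the result for
#' reproducibility.
#'
#' @param map numeric matrix (one stain's concentration map).
#' @param threshold `"otsu"` (default) or a fixed numeric value.
#' @param mask optional logical selection matrix of the same shape.
#' @param image_id,stain identifiers carried into the result.
#' @return one-row data.frame: `image_id, stain, threshold, percent_area,
#'   n_above, n_total`.
#' @export
area_fraction <- function(map, threshold = "otsu", mask = NULL,
                          image_id = NA_character_, stain = NA_character_) {
  stopifnot(is.numeric(map))
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(map))) stop_named("mask shape differs from map")
    sel <- map[mask]
  } else {
    sel <- as.vector(map)
  }
  if (length(sel) == 0) stop_named("empty selection")
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(sel)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1,
              is.finite(threshold))
    as.numeric(threshold)
  }
  n_above <- sum(sel > thr)
  data.frame(image_id = image_id, stain = stain, threshold = thr,
             percent_area = 100 * n_above / length(sel),
             n_above = n_above, n_total = length(sel),
             stringsAsFactors = FALSE)
}

#' Volume-normalized live/dead viability record
#'
#' Normalizes live- and dead-channel fluorescence intensity sums to the
#' measured model volume (intensity per cubic micrometre), the quantity used
#' to compare viable and dead cell content across 3D models. Instead of a
#' scalar volume, a voxel mask plus voxel volume may be given.
#'
#' @param live_sum,dead_sum channel intensity sums (>= 0).
#' @param volume total model volume in cubic micrometres (> 0); ignored when
#'   `voxel_mask` is given.
#' @param voxel_mask optional logical array of model voxels.
#' @param voxel_volume_um3 volume of one voxel, required with `voxel_mask`.
#' @param model_id identifier carried into the record.
#' @return one-row data.frame: `model_id, live_intensity_sum,
#'   dead_intensity_sum, total_volume_um3, live_norm, dead_norm`.
#' @export
viability_normalize <- function(live_sum, dead_sum, volume = NULL,
                                voxel_mask = NULL, voxel_volume_um3 = NULL,
                                model_id = NA_character_) {
  check_positive(live_sum, "live_sum", strict = FALSE)
  check_positive(dead_sum, "dead_sum", strict = FALSE)
  if (!is.null(voxel_mask)) {
    if (is.null(voxel_volume_um3)) {
      stop_named("voxel_volume_um3 required with a voxel mask")
    }
    volume <- sum(voxel_mask) * voxel_volume_um3
  }
  if (is.null(volume) || !is.finite(volume) || volume <= 0) {
    stop_named("model volume must be positive")
  }
  data.frame(model_id = model_id,
             live_intensity_sum = live_sum, dead_intensity_sum = dead_sum,
             total_volume_um3 = volume,
             live_norm = live_sum / volume, dead_norm = dead_sum / volume,
             stringsAsFactors = FALSE)
}
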