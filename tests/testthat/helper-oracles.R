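# Independent oracles used across the suite. Each is implemented directly
# from the defining formula or by enumeration, never by calling the package
# code path it checks.

# exact two-sided Mann-Whitney p by enumerating all group assignments
enum_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  m <- n1 * length(y)
  # two-sided: distance of U from its mean under H0
  dev_obs <- abs(u_obs - m / 2)
  assigns <- utils::combn(n, n1)
  us <- apply(assigns, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - m / 2) >= dev_obs - 1e-12)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  dev_obs <- abs(v_obs - ev)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mean(abs(vs - ev) >= dev_obs - 1e-12)
}

# brute-force two-stage adaptive FDR rejection set (independent of bky_fdr)
brute_bky_reject <- function(p, q) {
  bh <- function(p, a) {
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= (1:m) / m * a)
    rej <- rep(FALSE, m)
    if (length(k)) rej[o[1:max(k)]] <- TRUE
    rej
  }
  m <- length(p)
  qp <- q / (1 + q)
  r1 <- sum(bh(p, qp))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, qp * m / (m - r1))
}

# closed-form Holm-Sidak adjustment (written from the formula)
brute_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  a <- pmin(1 - (1 - p[o])^(m - seq_len(m) + 1), 1)
  for (i in seq_len(m)[-1]) a[i] <- max(a[i], a[i - 1])
  out <- numeric(m)
  out[o] <- a
  out
}

# build a 96-fraction profile carrying a Gaussian peak (forward model only)
gaussian_profile <- function(amplitude, center_kda, sigma_frac,
                             baseline = 0, calibration = default_mw_calibration(),
                             sample_id = "S1", antibody_id = "Ab1") {
  calib <- calibration[order(calibration$fraction_index), ]
  ctr <- approx(log(calib$kda), calib$fraction_index,
                xout = log(center_kda))$y
  mfi <- amplitude * exp(-((0:95) - ctr)^2 / (2 * sigma_frac^2)) + baseline
  data.frame(sample_id = sample_id, antibody_id = antibody_id,
             fraction_index = 0:95, mfi = mfi, stringsAsFactors = FALSE)
}

# small expression matrix with PDM/PTT pair metadata from explicit values
toy_paired_matrix <- function(values, scale_tag = "log2") {
  n_pairs <- ncol(values) / 2
  ids <- c(sprintf("P%02d_PDM", seq_len(n_pairs)),
           sprintf("P%02d_PTT", seq_len(n_pairs)))
  colnames(values) <- ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("A%03d", seq_len(nrow(values)))
  }
  meta <- data.frame(sample_id = ids,
                     pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2),
                     tissue = rep(c("PDM", "PTT"), each = n_pairs),
                     stringsAsFactors = FALSE)
  expression_matrix(values, scale_tag, samples = meta)
}
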