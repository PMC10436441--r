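#' Pearson correlation of matched PDM/PTT protein profiles
#'
#' Correlates protein signals between matched microtumor (PDM) and primary
#' tumor tissue (PTT) samples at three levels: `overall_means` correlates the
#' per-analyte (mean over PDMs, mean over PTTs) points; `per_protein` gives,
#' for every analyte, the correlation of (PDM, PTT) values across pairs;
#' `per_pair` gives, for every matched pair, the correlation across analytes.
#' Two-sided p-values come from the usual t transform. Coefficients with
#' fewer than 3 points are omitted with a warning.
#'
#' @param em [expression_matrix()] on the `log2` or `median_centered` scale
#'   whose sample metadata carries `pair_id` and `tissue` (PDM/PTT) columns,
#'   or any matrix plus an explicit `pairing`.
#' @param pairing optional data.frame `pair_id, pdm_sample, ptt_sample`
#'   overriding the metadata-derived pairing.
#' @param level `"overall_means"`, `"per_protein"` or `"per_pair"`.
#' @return for `overall_means` a one-row data.frame (`r, p, n`); otherwise a
#'   data.frame with one row per analyte / per pair.
#' @export
pearson_pairs <- function(em, pairing = NULL,
                          level = c("overall_means", "per_protein",
                                    "per_pair")) {
  level <- match.arg(level)
  check_scale(em, c("log2", "median_centered"), "pearson_pairs")
  if (is.null(pairing)) pairing <- derive_pairing(em$samples)
  missing <- setdiff(c(pairing$pdm_sample, pairing$ptt_sample),
                     colnames(em$values))
  if (length(missing)) {
    stop_named("pairing references unknown samples: %s",
               paste(missing, collapse = ", "))
  }
  pdm <- em$values[, pairing$pdm_sample, drop = FALSE]
  ptt <- em$values[, pairing$ptt_sample, drop = FALSE]

  cor_test <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok])
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }

  if (level == "overall_means") {
    res <- cor_test(rowMeans(pdm), rowMeans(ptt))
    return(data.frame(level = level, r = res["r"], p = res["p"],
                      n = as.integer(res["n"]), row.names = NULL))
  }
  if (level == "per_protein") {
    out <- t(vapply(seq_len(nrow(pdm)),
                    function(a) cor_test(pdm[a, ], ptt[a, ]), numeric(3)))
    res <- data.frame(analyte_id = rownames(pdm), r = out[, 1], p = out[, 2],
                      n = as.integer(out[, 3]), stringsAsFactors = FALSE)
  } else {
    out <- t(vapply(seq_len(ncol(pdm)),
                    function(j) cor_test(pdm[, j], ptt[, j]), numeric(3)))
    res <- data.frame(pair_id = pairing$pair_id, r = out[, 1], p = out[, 2],
                      n = as.integer(out[, 3]), stringsAsFactors = FALSE)
  }
  if (anyNA(res$r)) {
    warning(sprintf("%d coefficient(s) omitted (< 3 points or zero variance)",
                    sum(is.na(res$r))), call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

derive_pairing <- function(samples) {
  if (!all(c("pair_id", "tissue") %in% names(samples))) {
    stop_named("sample metadata needs 'pair_id' and 'tissue' columns (or pass 'pairing')")
  }
  pairs <- split(samples, samples$pair_id)
  rows <- lapply(pairs, function(p) {
    pdm <- p$sample_id[p$tissue == "PDM"]
    ptt <- p$sample_id[p$tissue == "PTT"]
    if (length(pdm) != 1 || length(ptt) != 1) {
      stop_named("pair %s does not have exactly one PDM and one PTT sample",
                 p$pair_id[1])
    }
    data.frame(pair_id = p$pair_id[1], pdm_sample = pdm, ptt_sample = ptt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch volcano analysis with two-stage adaptive FDR
#'
#' Per-analyte unpaired t-tests with Welch correction on log2 values between
#' two sample groups, adjusted by the two-stage Benjamini-Krieger-Yekutieli
#' FDR ([bky_fdr()]). An analyte is called significant when its q-value
#' clears the FDR threshold (`-log10(q) > 1.3` at the default 0.05) and its
#' absolute log2 fold change reaches `fc_threshold`.
#'
#' @param em [expression_matrix()] on the `log2` or `median_centered` scale.
#' @param group1,group2 character vectors of sample ids (>= 2 each).
#' @param q_threshold FDR level (default 0.05).
#' @param fc_threshold absolute log2 fold-change cut (default 1).
#' @param paired if TRUE, paired t-tests (groups aligned by position).
#' @return data.frame per analyte: `analyte_id, log2_fc, t, p, q,
#'   significant, flag` (`flag` marks degenerate zero-variance cases).
#' @export
welch_volcano <- function(em, group1, group2, q_threshold = 0.05,
                          fc_threshold = 1, paired = FALSE) {
  check_scale(em, c("log2", "median_centered"), "welch_volcano")
  check_fraction(q_threshold, "q_threshold")
  for (g in list(group1, group2)) {
    missing <- setdiff(g, colnames(em$values))
    if (length(missing)) {
      stop_named("unknown samples: %s", paste(missing, collapse = ", "))
    }
    if (length(g) < 2) stop_named("both groups need >= 2 samples")
  }
  v1 <- em$values[, group1, drop = FALSE]
  v2 <- em$values[, group2, drop = FALSE]

  one <- function(a) {
    x <- v1[a, ]; y <- v2[a, ]
    d <- mean(x) - mean(y)
    if (sd(x) == 0 && sd(y) == 0) {
      if (d == 0) return(c(d, 0, 1, 1))       # identical constants
      return(c(d, Inf, 0, 2))                  # separated constants, flagged
    }
    tt <- tryCatch(t.test(x, y, paired = paired),
                   error = function(e) NULL)
    if (is.null(tt)) return(c(d, NA, NA, 2))
    c(d, unname(tt$statistic), tt$p.value, 0)
  }
  res <- t(vapply(seq_len(nrow(v1)), one, numeric(4)))
  fdr <- bky_fdr(res[, 3], q_level = q_threshold)
  out <- data.frame(
    analyte_id = rownames(em$values),
    log2_fc = res[, 1], t = res[, 2], p = res[, 3], q = fdr$q_values,
    significant = fdr$rejected & abs(res[, 1]) >= fc_threshold,
    flag = c("ok", "constant", "degenerate")[res[, 4] + 1],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR
#'
#' The two-stage adaptive linear step-up procedure: stage 1 applies
#' Benjamini-Hochberg at level `q' = q/(1+q)` and uses the rejection count
#' r1 to estimate the number of true nulls `m0 = m - r1`; stage 2 re-applies
#' BH at level `q' * m / m0` (all rejected if r1 = m, none extra if r1 = 0).
#' The reported q-value of a test is the smallest `q_level` at which it would
#' be rejected, obtained by bisection over the level.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q_level target FDR level for the rejection set.
#' @return list with `rejected` (logical), `q_values`, and `m0_hat`.
#' @export
bky_fdr <- function(p, q_level = 0.05) {
  if (length(p) == 0) {
    return(list(rejected = logical(0), q_values = numeric(0), m0_hat = 0))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_named("p-values must lie in [0, 1]")
  }
  rej <- bky_reject(p, q_level)
  m0 <- attr(rej, "m0_hat")
  attributes(rej) <- NULL
  qv <- vapply(seq_along(p), function(i) {
    lo <- 0; hi <- 1
    if (!bky_reject(p, 1 - 1e-12)[i]) return(1)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (bky_reject(p, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  list(rejected = rej, q_values = qv, m0_hat = m0)
}

# BH step-up rejection set at level alpha
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

bky_reject <- function(p, q_level) {
  m <- length(p)
  q1 <- q_level / (1 + q_level)
  r1 <- sum(bh_reject(p, q1))
  if (r1 == 0) {
    rej <- logical(m)
  } else if (r1 == m) {
    rej <- rep(TRUE, m)
  } else {
    m0 <- m - r1
    rej <- bh_reject(p, q1 * m / m0)
  }
  attr(rej, "m0_hat") <- m - r1
  rej
}

#' Mann-Whitney U test
#'
#' Unpaired, two-tailed rank-sum comparison of two groups, exact for small
#' samples without ties and a tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors (non-empty).
#' @return data.frame `U, p, n1, n2, exact`.
#' @export
mw_u_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  data.frame(U = unname(wt$statistic), p = wt$p.value,
             n1 = length(x), n2 = length(y), exact = exact)
}

#' Wilcoxon paired signed-rank test
#'
#' Two-sided signed-rank test on matched pairs, exact for small samples
#' without ties/zeros. All-zero differences give p = 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return data.frame `V, p, n_nonzero, exact`.
#' @export
signed_rank_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) {
    return(data.frame(V = 0, p = 1, n_nonzero = 0L, exact = TRUE))
  }
  if (nz < 3) {
    warning("fewer than 3 non-zero differences; test is uninformative",
            call. = FALSE)
  }
  dd <- d[d != 0]
  ties <- anyDuplicated(abs(dd)) > 0
  exact <- nz <= 15 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                     correct = !exact))
  data.frame(V = unname(wt$statistic), p = wt$p.value,
             n_nonzero = nz, exact = exact)
}

#' Holm-Sidak step-down adjustment
#'
#' Adjusted p-values `1 - (1 - p_(i))^(m - i + 1)` over the ascending
#' ordering, with the running maximum enforced (step-down monotonicity).
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_named("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' ANOVA with Holm-Sidak multiple comparisons
#'
#' One-way (or two-way) analysis of variance followed by all pairwise t
#' contrasts on the pooled residual variance, adjusted by the Holm-Sidak
#' step-down. For the two-way design the pairwise comparisons are between
#' levels of `factor1` within each level of `factor2`.
#'
#' @param values numeric response vector.
#' @param factor1 grouping factor (>= 3 levels for one-way; >= 2 values per
#'   group).
#' @param factor2 optional second factor; triggers the two-way design.
#' @return list with `anova` (the summary table) and `comparisons`
#'   (data.frame `group1, group2, estimate, t, df, p, p_adj`).
#' @export
anova_holm_sidak <- function(values, factor1, factor2 = NULL) {
  f1 <- factor(factor1)
  cnt <- table(f1)
  if (any(cnt < 2)) {
    stop_named("degenerate group '%s' (< 2 values)", names(cnt)[cnt < 2][1])
  }
  if (is.null(factor2)) {
    d <- data.frame(y = values, g = f1)
    fit <- aov(y ~ g, data = d)
    mse <- sum(residuals(fit)^2) / fit$df.residual
    df <- fit$df.residual
    levs <- levels(f1)
    cmp <- do.call(rbind, lapply(utils::combn(levs, 2, simplify = FALSE),
      function(pr) {
        n1 <- sum(f1 == pr[1]); n2 <- sum(f1 == pr[2])
        est <- mean(values[f1 == pr[1]]) - mean(values[f1 == pr[2]])
        se <- sqrt(mse * (1 / n1 + 1 / n2))
        tstat <- if (se == 0) 0 else est / se
        data.frame(group1 = pr[1], group2 = pr[2], estimate = est, t = tstat,
                   df = df, p = 2 * pt(-abs(tstat), df),
                   stringsAsFactors = FALSE)
      }))
  } else {
    f2 <- factor(factor2)
    d <- data.frame(y = values, g = f1, h = f2)
    fit <- aov(y ~ g * h, data = d)
    mse <- sum(residuals(fit)^2) / fit$df.residual
    df <- fit$df.residual
    cmp <- do.call(rbind, lapply(levels(f2), function(hl) {
      sub <- f1[f2 == hl]
      yv <- values[f2 == hl]
      prs <- utils::combn(levels(droplevels(sub)), 2, simplify = FALSE)
      do.call(rbind, lapply(prs, function(pr) {
        n1 <- sum(sub == pr[1]); n2 <- sum(sub == pr[2])
        if (n1 == 0 || n2 == 0) return(NULL)
        est <- mean(yv[sub == pr[1]]) - mean(yv[sub == pr[2]])
        se <- sqrt(mse * (1 / n1 + 1 / n2))
        tstat <- if (se == 0) 0 else est / se
        data.frame(group1 = paste(pr[1], hl, sep = ":"),
                   group2 = paste(pr[2], hl, sep = ":"),
                   estimate = est, t = tstat, df = df,
                   p = 2 * pt(-abs(tstat), df), stringsAsFactors = FALSE)
      }))
    }))
  }
  cmp$p_adj <- holm_sidak_adjust(cmp$p)
  rownames(cmp) <- NULL
  list(anova = summary(fit), comparisons = cmp)
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering of samples and/or analytes of a median-centered
#' log2 matrix with complete or average linkage, on euclidean or
#' (1 - Pearson) correlation distance. `hclust`'s deterministic
#' agglomeration (ties broken by smallest original index) is used, so equal
#' input yields equal trees.
#'
#' @param em [expression_matrix()] on the `median_centered` (or `log2`)
#'   scale, without missing values.
#' @param axis `"samples"`, `"analytes"` or `"both"`.
#' @param linkage `"complete"` or `"average"`.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param k optional number of flat clusters to cut each tree into.
#' @return list with (per requested axis) the `hclust` tree, the leaf
#'   `order` (labels), and optionally `clusters` from [stats::cutree()].
#' @export
hcl_cluster <- function(em, axis = c("samples", "analytes", "both"),
                        linkage = c("complete", "average"),
                        distance = c("euclidean", "correlation"), k = NULL) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  check_scale(em, c("log2", "median_centered"), "hcl_cluster")
  v <- em$values
  if (anyNA(v)) stop_named("matrix contains missing values")

  cluster_one <- function(m) {
    if (nrow(m) == 1) {
      return(list(tree = NULL, order = rownames(m), clusters = NULL))
    }
    dmat <- if (distance == "euclidean") dist(m) else {
      as.dist(1 - cor(t(m)))
    }
    tree <- hclust(dmat, method = linkage)
    out <- list(tree = tree, order = rownames(m)[tree$order])
    if (!is.null(k)) out$clusters <- cutree(tree, k = min(k, nrow(m)))
    out
  }
  res <- list(linkage = linkage, distance = distance)
  if (axis %in% c("samples", "both")) res$samples <- cluster_one(t(v))
  if (axis %in% c("analytes", "both")) res$analytes <- cluster_one(v)
  res
}

#' Simple logistic regression of treatment response on one protein
#'
#' Maximum-likelihood fit of `responder ~ intercept + beta1 * value`, where
#' `value` is the sample's median-centered log2 signal of one analyte (one
#' unit = a 2-fold protein change). Reports the odds ratio `exp(beta1)` with
#' Wald 95% CI and p, and a likelihood-ratio p against the intercept-only
#' model. Complete or quasi-separation (diverging coefficient or
#' non-convergence) is flagged and no finite CI is reported.
#'
#' @param values numeric per-sample signal for one analyte.
#' @param labels responder labels: logical, 0/1, or
#'   `"responder"`/`"non-responder"` strings.
#' @param per `"log2"` (default: per unit of log2 signal) or `"sd"`
#'   (values standardized first, OR per standard deviation).
#' @return object of class `logistic_fit`: data.frame row with
#'   `beta1, or_, ci_low, ci_high, p_wald, p_lrt, n, separation`.
#' @export
logistic_response_model <- function(values, labels, per = c("log2", "sd")) {
  per <- match.arg(per)
  y <- normalize_labels(labels)
  ok <- is.finite(values) & !is.na(y)
  values <- values[ok]; y <- y[ok]
  if (length(y) < 6) stop_named("need n >= 6 samples")
  if (length(unique(y)) < 2) stop_named("both response classes must be present")
  if (per == "sd") values <- values / sd(values)

  fit <- suppressWarnings(glm(y ~ values, family = binomial()))
  null_fit <- glm(y ~ 1, family = binomial())
  beta1 <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  separation <- !fit$converged || abs(beta1) > 15 || se > 10
  lrt_p <- 1 - pchisq(null_fit$deviance - fit$deviance, df = 1)
  wald_p <- 2 * pnorm(-abs(beta1 / se))
  out <- data.frame(
    beta1 = beta1,
    or_ = exp(beta1),
    ci_low = if (separation) NA_real_ else exp(beta1 - 1.96 * se),
    ci_high = if (separation) NA_real_ else exp(beta1 + 1.96 * se),
    p_wald = wald_p, p_lrt = lrt_p,
    n = length(y), separation = separation
  )
  class(out) <- c("logistic_fit", class(out))
  out
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% 0:1))
    return(as.integer(labels))
  }
  lab <- tolower(as.character(labels))
  y <- ifelse(lab %in% c("responder", "r", "1", "true"), 1L,
              ifelse(lab %in% c("non-responder", "nonresponder", "non-r",
                                "0", "false"), 0L, NA_integer_))
  if (anyNA(y)) stop_named("unrecognized response label '%s'",
                           labels[which(is.na(y))[1]])
  y
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: OR = %.3f [%.3f, %.3f], Wald p = %.3g, LRT p = %.3g%s\n",
              x$or_, x$ci_low, x$ci_high, x$p_wald, x$p_lrt,
              if (x$separation) " (separation: CI unstable)" else ""))
  invisible(x)
}

#' Compare a marker-panel's signals between responders and non-responders
#'
#' Pools every (panel analyte, sample) median-centered log2 value into its
#' sample's response group and compares the groups with an unpaired
#' Mann-Whitney U test; per-analyte tests are reported alongside. The
#' expected direction (a resistance panel is higher in non-responders, a
#' sensitivity panel higher in responders) is checked against the observed
#' median difference.
#'
#' @param em [expression_matrix()] on the `median_centered` scale.
#' @param panel list or data.frame with `drug`, `direction`
#'   (`"resistance"`/`"sensitivity"`) and `analyte_id` (the panel members).
#' @param calls data.frame of response calls with `sample_id, drug, label`
#'   (see [call_drug_response()]).
#' @return list with `pooled` (one-row data.frame `drug, direction, U, p,
#'   n_responder, n_nonresponder, median_diff, direction_consistent`),
#'   `per_analyte` (Mann-Whitney per panel member) and `missing_analytes`.
#' @export
panel_compare <- function(em, panel, calls) {
  check_scale(em, "median_centered", "panel_compare")
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "direction", "analyte_id") %in% names(panel)))
  drug <- unique(panel$drug)
  direction <- unique(panel$direction)
  stopifnot(length(drug) == 1, length(direction) == 1)
  direction <- match.arg(direction, c("resistance", "sensitivity"))

  missing <- setdiff(panel$analyte_id, rownames(em$values))
  if (length(missing)) {
    warning(sprintf("panel analytes missing from matrix: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  analytes <- intersect(panel$analyte_id, rownames(em$values))
  if (length(analytes) == 0) stop_named("no panel analytes in the matrix")

  dc <- calls[calls$drug == drug, , drop = FALSE]
  dc <- dc[dc$sample_id %in% colnames(em$values), , drop = FALSE]
  resp <- dc$sample_id[dc$label == "responder"]
  nonr <- dc$sample_id[dc$label == "non-responder"]
  if (length(resp) == 0 || length(nonr) == 0) {
    stop_named("both response classes must be non-empty for drug %s", drug)
  }
  vr <- as.vector(em$values[analytes, resp, drop = FALSE])
  vn <- as.vector(em$values[analytes, nonr, drop = FALSE])
  pooled_test <- mw_u_test(vr, vn)
  md <- median(vr) - median(vn)
  consistent <- if (direction == "sensitivity") md > 0 else md < 0

  per <- do.call(rbind, lapply(analytes, function(a) {
    t <- mw_u_test(em$values[a, resp], em$values[a, nonr])
    data.frame(analyte_id = a, U = t$U, p = t$p,
               median_diff = median(em$values[a, resp]) -
                 median(em$values[a, nonr]),
               stringsAsFactors = FALSE)
  }))
  list(
    pooled = data.frame(drug = drug, direction = direction,
                        U = pooled_test$U, p = pooled_test$p,
                        n_responder = length(resp),
                        n_nonresponder = length(nonr),
                        median_diff = md,
                        direction_consistent = consistent,
                        stringsAsFactors = FALSE),
    per_analyte = per,
    missing_analytes = missing
  )
}
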