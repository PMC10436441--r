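#' Background-corrected fold changes for a cytotoxicity table
#'
#' Converts well-level RFU readings into per-well fold changes relative to
#' the vehicle-control mean at the same timepoint. When blank (medium-only)
#' wells are present, their mean at the matching (sample, drug, timepoint) —
#' or, failing that, at the timepoint — is subtracted from all wells first.
#' Vehicle wells receive their own fold change relative to the vehicle mean,
#' so vehicle fold changes average 1 per timepoint by construction.
#' Background-corrected readings are clamped at a small positive epsilon
#' (1e-6 of the vehicle mean) before division.
#'
#' @param table data.frame with columns
#'   `sample_id, drug, timepoint_h, replicate_id, role, rfu`
#'   (`role` in treatment/vehicle/blank; `dose` optional, carried along).
#' @return data.frame of treatment and vehicle wells with added columns
#'   `well_id` (replicate well identity across timepoints),
#'   `corrected_rfu` and `fold_change`.
#' @export
fold_changes <- function(table) {
  need <- c("sample_id", "drug", "timepoint_h", "replicate_id", "role", "rfu")
  if (!all(need %in% names(table))) {
    stop_named("cytotoxicity table needs columns %s",
               paste(setdiff(need, names(table)), collapse = ", "))
  }
  if (any(!is.finite(table$rfu)) || any(table$rfu < 0)) {
    stop_named("RFU values must be finite and non-negative")
  }
  bad_role <- setdiff(unique(table$role), c("treatment", "vehicle", "blank"))
  if (length(bad_role)) stop_named("unknown role '%s'", bad_role[1])

  blanks <- table[table$role == "blank", , drop = FALSE]
  wells <- table[table$role != "blank", , drop = FALSE]

  blank_for <- function(sid, drg, tp) {
    if (nrow(blanks) == 0) return(0)
    local <- blanks$rfu[blanks$sample_id == sid & blanks$drug == drg &
                          blanks$timepoint_h == tp]
    if (length(local)) return(mean(local))
    global <- blanks$rfu[blanks$timepoint_h == tp]
    if (length(global)) mean(global) else mean(blanks$rfu)
  }

  key <- paste(wells$sample_id, wells$drug, wells$timepoint_h, sep = "\r")
  out <- lapply(split(wells, key), function(g) {
    b <- blank_for(g$sample_id[1], g$drug[1], g$timepoint_h[1])
    corr <- g$rfu - b
    veh <- corr[g$role == "vehicle"]
    if (length(veh) == 0) {
      stop_named("no vehicle wells for sample %s, drug %s at %s h",
                 g$sample_id[1], g$drug[1], format(g$timepoint_h[1]))
    }
    vm <- mean(veh)
    if (vm <= 0) {
      stop_named("vehicle mean non-positive after background correction (sample %s, drug %s, %s h)",
                 g$sample_id[1], g$drug[1], format(g$timepoint_h[1]))
    }
    g$corrected_rfu <- pmax(corr, 1e-6 * vm)
    g$fold_change <- g$corrected_rfu / vm
    g
  })
  out <- do.call(rbind, out)
  out$well_id <- paste(out$sample_id, out$drug, out$role, out$replicate_id,
                       sep = "_")
  out <- out[order(out$sample_id, out$drug, out$timepoint_h, out$role,
                   out$replicate_id), ]
  rownames(out) <- NULL
  out
}

#' Robust outlier detection by the modified Z-score
#'
#' Iglewicz and Hoaglin's robust test for multiple outliers:
#' `M_i = 0.6745 * (x_i - median) / MAD`, flagging `|M_i| >= 3.5`. When the
#' MAD is zero the mean absolute deviation fallback
#' `M_i = (x_i - median) / (1.253314 * MeanAD)` is used; when both scales are
#' zero no value can be an outlier. With fewer than 3 values no test is
#' performed (warning) and nothing is flagged.
#'
#' @param values numeric vector of well measurements from one exchangeable
#'   group (same sample, drug, condition and timepoint).
#' @param z_cut exclusion threshold on `|M_i|` (default 3.5, the recommended
#'   cut-off).
#' @return data.frame with columns `value, m, excluded` and attributes
#'   `location`, `scale`, `scale_method`.
#' @export
modified_z_outliers <- function(values, z_cut = 3.5) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 3) {
    warning("fewer than 3 values; outlier test not performed", call. = FALSE)
    res <- data.frame(value = values, m = rep(NA_real_, n),
                      excluded = rep(FALSE, n))
    attr(res, "location") <- if (n) median(values) else NA_real_
    attr(res, "scale") <- NA_real_
    attr(res, "scale_method") <- "none"
    return(res)
  }
  med <- median(values)
  mad_raw <- median(abs(values - med))  # unscaled MAD, per the M_i formula
  if (mad_raw > 0) {
    m <- 0.6745 * (values - med) / mad_raw
    scale <- mad_raw
    method <- "mad"
  } else {
    meanad <- mean(abs(values - med))
    if (meanad > 0) {
      m <- (values - med) / (1.253314 * meanad)
      scale <- meanad
      method <- "meanad"
    } else {
      m <- rep(0, n)
      scale <- 0
      method <- "degenerate"
    }
  }
  res <- data.frame(value = values, m = m, excluded = abs(m) >= z_cut)
  attr(res, "location") <- med
  attr(res, "scale") <- scale
  attr(res, "scale_method") <- method
  res
}

# flag outlier wells within each (sample, drug, role, timepoint) cell
apply_outlier_filter <- function(fc, z_cut = 3.5) {
  key <- paste(fc$sample_id, fc$drug, fc$role, fc$timepoint_h, sep = "\r")
  excluded <- logical(nrow(fc))
  m <- rep(NA_real_, nrow(fc))
  for (g in split(seq_len(nrow(fc)), key)) {
    if (length(g) < 3) next
    rep_ <- modified_z_outliers(fc$fold_change[g], z_cut = z_cut)
    excluded[g] <- rep_$excluded
    m[g] <- rep_$m
  }
  fc$modified_z <- m
  fc$excluded <- excluded
  fc
}

#' Fit the REML mixed-effects treatment model for one sample and drug
#'
#' Models per-well fold changes as
#' `fold_change ~ condition * timepoint + (1 | well)` — condition
#' (treatment vs vehicle) and timepoint as categorical fixed effects, with a
#' random intercept per replicate well (the repeated-measure unit across the
#' time series) — fitted by REML. Per-timepoint treatment-vs-vehicle
#' contrasts are tested with model-based standard errors and residual degrees
#' of freedom, without multiplicity adjustment (Fisher's uncorrected LSD).
#' When the random-intercept variance estimates to zero the fit degenerates
#' to ordinary least squares and is flagged; on non-convergence the fallback
#' is per-timepoint Welch t-tests, also flagged.
#'
#' @param fc fold-change rows for one sample x drug (output of
#'   [fold_changes()], optionally filtered by the outlier rule); must contain
#'   treatment and vehicle wells at >= 2 timepoints.
#' @param against `"vehicle"` (default: mixed model contrast against the
#'   vehicle wells) or `"unity"` (per-timepoint one-sample t-test of the
#'   treatment fold changes against 1).
#' @return object of class `treatment_fit`: data.frame `contrasts` with one
#'   row per timepoint (`timepoint_h, estimate, se, df, t, p`), plus fields
#'   `singular`, `converged`, `method`, `varcomp`.
#' @export
fit_treatment_model <- function(fc, against = c("vehicle", "unity")) {
  against <- match.arg(against)
  stopifnot(all(c("fold_change", "role", "timepoint_h", "well_id") %in%
                  names(fc)))
  tps <- sort(unique(fc$timepoint_h))
  if (length(tps) < 2) stop_named("need >= 2 timepoints")

  if (against == "unity") {
    contrasts <- do.call(rbind, lapply(tps, function(tp) {
      x <- fc$fold_change[fc$role == "treatment" & fc$timepoint_h == tp]
      tt <- t.test(x, mu = 1)
      data.frame(timepoint_h = tp, estimate = mean(x) - 1,
                 se = unname(tt$stderr), df = unname(tt$parameter),
                 t = unname(tt$statistic), p = tt$p.value)
    }))
    return(structure(list(contrasts = contrasts, singular = NA,
                          converged = TRUE, method = "one-sample t vs unity",
                          varcomp = NULL),
                     class = "treatment_fit"))
  }

  cnt <- table(fc$role, fc$timepoint_h)
  if (!all(c("treatment", "vehicle") %in% rownames(cnt)) || any(cnt < 2)) {
    stop_named("need >= 2 treatment and >= 2 vehicle wells at every timepoint")
  }
  d <- data.frame(
    fc = fc$fold_change,
    condition = factor(fc$role, levels = c("vehicle", "treatment")),
    timepoint = factor(fc$timepoint_h, levels = tps),
    well = factor(fc$well_id)
  )
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fc ~ condition * timepoint + (1 | well), data = d,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    # documented fallback: per-timepoint Welch t-tests
    contrasts <- do.call(rbind, lapply(tps, function(tp) {
      x <- d$fc[d$condition == "treatment" & d$timepoint == tp]
      y <- d$fc[d$condition == "vehicle" & d$timepoint == tp]
      tt <- t.test(x, y)
      data.frame(timepoint_h = tp, estimate = mean(x) - mean(y),
                 se = unname(tt$stderr), df = unname(tt$parameter),
                 t = unname(tt$statistic), p = tt$p.value)
    }))
    return(structure(list(contrasts = contrasts, singular = NA,
                          converged = FALSE, method = "welch fallback",
                          varcomp = NULL),
                     class = "treatment_fit"))
  }

  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  df_resid <- nobs(fit) - length(beta)
  contrasts <- do.call(rbind, lapply(seq_along(tps), function(i) {
    L <- numeric(length(beta))
    names(L) <- names(beta)
    L["conditiontreatment"] <- 1
    if (i > 1) {
      L[paste0("conditiontreatment:timepoint", tps[i])] <- 1
    }
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tstat <- est / se
    data.frame(timepoint_h = tps[i], estimate = est, se = se, df = df_resid,
               t = tstat, p = 2 * pt(-abs(tstat), df_resid))
  }))
  vc <- as.data.frame(lme4::VarCorr(fit))
  singular <- lme4::isSingular(fit)
  structure(list(contrasts = contrasts, singular = singular, converged = TRUE,
                 method = if (singular) "reml (degenerate to ols)" else "reml",
                 varcomp = vc),
            class = "treatment_fit")
}

#' @export
print.treatment_fit <- function(x, ...) {
  cat(sprintf("treatment_fit [%s]%s\n", x$method,
              if (isTRUE(x$singular)) " (zero well variance)" else ""))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Classify a treatment fit into responder / non-responder
#'
#' A sample is a responder to a drug when at least one timepoint shows a
#' significant (`p < alpha`) treatment effect in the direction of increased
#' cell death (positive effect); otherwise it is a non-responder. A
#' significant effect in the opposite direction does not count as response.
#'
#' @param fit a [fit_treatment_model()] result.
#' @param alpha significance level per timepoint (uncorrected looks).
#' @param require_positive whether the effect must be positive (default TRUE;
#'   the assay signal is proportional to cell death).
#' @return list of class `response_call` with `label`
#'   (`"responder"`/`"non-responder"`) and the per-timepoint evidence.
#' @export
classify_response <- function(fit, alpha = 0.05, require_positive = TRUE) {
  stopifnot(inherits(fit, "treatment_fit"))
  check_fraction(alpha, "alpha")
  ct <- fit$contrasts
  hit <- ct$p < alpha & (!require_positive | ct$estimate > 0)
  structure(list(label = if (any(hit)) "responder" else "non-responder",
                 contrasts = ct, alpha = alpha, method = fit$method,
                 singular = fit$singular, converged = fit$converged),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("response_call: %s (alpha = %g, %s)\n", x$label, x$alpha,
              x$method))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Call drug response for every sample and drug in a cytotoxicity table
#'
#' The full responder-calling chain: background-corrected fold changes,
#' modified Z-score outlier exclusion within each
#' (sample, drug, condition, timepoint) cell, the REML mixed-effects model
#' with per-timepoint uncorrected LSD contrasts, and the responder rule.
#'
#' @param table cytotoxicity table (see [fold_changes()]).
#' @param alpha per-timepoint significance level.
#' @param z_cut modified Z-score exclusion threshold.
#' @param against `"vehicle"` or `"unity"` (see [fit_treatment_model()]).
#' @return data.frame with one row per (sample, drug):
#'   `sample_id, drug, label`, per-timepoint `p<t>` and `effect<t>` columns,
#'   `n_outliers_removed, method`. The fitted objects are attached as
#'   attribute `"fits"`, the filtered fold changes as `"fold_changes"`.
#' @export
call_drug_response <- function(table, alpha = 0.05, z_cut = 3.5,
                               against = "vehicle") {
  fc <- fold_changes(table)
  fc <- apply_outlier_filter(fc, z_cut = z_cut)
  kept <- fc[!fc$excluded, , drop = FALSE]

  combos <- unique(kept[, c("sample_id", "drug")])
  combos <- combos[order(combos$sample_id, combos$drug), , drop = FALSE]
  tps <- sort(unique(kept$timepoint_h))
  fits <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- kept[kept$sample_id == combos$sample_id[i] &
                  kept$drug == combos$drug[i], , drop = FALSE]
    fit <- fit_treatment_model(sub, against = against)
    call <- classify_response(fit, alpha = alpha)
    fits[[i]] <- call
    row <- data.frame(sample_id = combos$sample_id[i],
                      drug = combos$drug[i], label = call$label,
                      stringsAsFactors = FALSE)
    for (tp in tps) {
      j <- match(tp, fit$contrasts$timepoint_h)
      row[[paste0("p", tp)]] <- fit$contrasts$p[j]
      row[[paste0("effect", tp)]] <- fit$contrasts$estimate[j]
    }
    row$n_outliers_removed <- sum(fc$excluded[fc$sample_id == row$sample_id &
                                                fc$drug == row$drug])
    row$method <- fit$method
    rows[[i]] <- row
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  attr(calls, "fits") <- fits
  attr(calls, "fold_changes") <- fc
  calls
}
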