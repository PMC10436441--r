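test_that("matched-pair Pearson correlation at all three levels", {
  # identical PDM and PTT halves: r = 1 everywhere
  set.seed(1)
  half <- matrix(rnorm(40), 8, 5)
  em <- toy_paired_matrix(cbind(half, half))
  expect_equal(pearson_pairs(em, level = "overall_means")$r, 1)
  expect_equal(pearson_pairs(em, level = "per_protein")$r, rep(1, 8),
               tolerance = 1e-12)
  expect_equal(pearson_pairs(em, level = "per_pair")$r, rep(1, 5),
               tolerance = 1e-12)

  # hand-computed coefficient via the product-moment formula
  pdm_vals <- c(1, 2, 3, 5)
  ptt_vals <- c(2, 1, 4, 4)
  v <- matrix(0, 2, 8)
  v[1, ] <- c(pdm_vals, ptt_vals)
  v[2, ] <- rnorm(8)
  em2 <- toy_paired_matrix(v)
  r_hand <- sum((pdm_vals - mean(pdm_vals)) * (ptt_vals - mean(ptt_vals))) /
    sqrt(sum((pdm_vals - mean(pdm_vals))^2) * sum((ptt_vals - mean(ptt_vals))^2))
  pp <- pearson_pairs(em2, level = "per_protein")
  expect_equal(pp$r[1], r_hand, tolerance = 1e-12)

  # p-value agrees with the t transform
  ct <- cor.test(pdm_vals, ptt_vals)
  expect_equal(pp$p[1], ct$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exact enumeration on small inputs", {
  res <- mw_u_test(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)

  # identical multisets -> p = 1
  expect_equal(mw_u_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # randomized comparison against full enumeration, all n1+n2 <= 10 shapes
  set.seed(20)
  for (n1 in 2:5) {
    for (n2 in n1:(10 - n1)) {
      x <- sample(seq_len(50), n1)
      y <- sample(setdiff(seq_len(50), x), n2)
      expect_equal(mw_u_test(x, y)$p, enum_mw_p(x, y), tolerance = 1e-10,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("Wilcoxon signed-rank matches sign enumeration", {
  # 5 all-positive differences: two-sided p = 2/32
  x <- c(2, 3, 4, 5, 6); y <- c(1, 2, 3, 4, 5) - c(0, 0.1, 0.25, 0.4, 0.7)
  res <- signed_rank_test(x, y)
  expect_equal(res$p, 2 / 32, tolerance = 1e-12)

  expect_equal(signed_rank_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(30)
  for (n in c(5, 7, 9)) {
    a <- rnorm(n); b <- a + rnorm(n)
    expect_equal(signed_rank_test(a, b)$p, enum_signed_rank_p(a - b),
                 tolerance = 1e-10)
  }
})

test_that("two-stage FDR matches the brute-force definition", {
  # no rejections when every p = 1
  out <- bky_fdr(rep(1, 6))
  expect_false(any(out$rejected))
  expect_true(all(out$q_values == 1))

  # worked example from the two-stage definition
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_identical(unname(bky_fdr(p, 0.05)$rejected),
                   brute_bky_reject(p, 0.05))

  # randomized rejection-set agreement across q levels
  set.seed(40)
  for (i in 1:50) {
    m <- sample(5:40, 1)
    p <- c(runif(m %/% 2, 0, 0.05), runif(m - m %/% 2))[sample(m)]
    for (q in c(0.01, 0.05, 0.1, 0.25)) {
      expect_identical(unname(bky_fdr(p, q)$rejected), brute_bky_reject(p, q),
                       info = sprintf("i=%d q=%g", i, q))
    }
  }

  # q-values are the smallest level at which a test is rejected, and are
  # monotone in the p-value ordering
  set.seed(41)
  p <- runif(15, 0, 0.3)
  q <- bky_fdr(p)$q_values
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  for (i in seq_along(p)) {
    expect_true(brute_bky_reject(p, min(q[i] + 1e-6, 1))[i])
    if (q[i] > 1e-6) expect_false(brute_bky_reject(p, q[i] - 1e-6)[i])
  }
})

test_that("Holm-Sidak adjustment matches the closed formula", {
  set.seed(50)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- holm_sidak_adjust(p)
    expect_equal(adj, brute_holm_sidak(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))  # adjustment never helps
    expect_true(all(adj <= 1))
  }
})

test_that("ANOVA with Holm-Sidak comparisons behaves on null and signal", {
  # identical groups: F ~ 0, nothing significant
  y <- rep(c(5, 6, 7), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_holm_sidak(y, g)
  f_stat <- res$anova[[1]]$`F value`[1]
  expect_lt(f_stat, 1e-10)
  expect_true(all(res$comparisons$p_adj > 0.9))

  # adjusted p from the closed formula on the raw pairwise p's
  set.seed(60)
  y2 <- c(rnorm(5, 0), rnorm(5, 2), rnorm(5, 0.5))
  g2 <- rep(c("a", "b", "c"), each = 5)
  res2 <- anova_holm_sidak(y2, g2)
  expect_equal(res2$comparisons$p_adj, brute_holm_sidak(res2$comparisons$p))

  # two-way design produces within-level comparisons
  y3 <- rnorm(24)
  res3 <- anova_holm_sidak(y3, rep(c("a", "b"), 12),
                           rep(c("x", "y"), each = 12))
  expect_equal(nrow(res3$comparisons), 2)

  expect_error(anova_holm_sidak(1:3, c("a", "a", "b")), "degenerate")
})

test_that("hierarchical clustering merges match the hand-computed tree", {
  v <- matrix(c(0, 1, 10, 11), 1, 4,
              dimnames = list("A1", paste0("S", 1:4)))
  em <- expression_matrix(v, "median_centered")
  cl <- hcl_cluster(em, axis = "samples", linkage = "complete")
  expect_equal(sort(cl$samples$tree$height), c(1, 1, 11))
  expect_equal(unname(cutree(cl$samples$tree, 2)),
               c(1, 1, 2, 2))

  # duplicated sample merges first at height 0
  v2 <- matrix(rnorm(12), 3, 4,
               dimnames = list(paste0("A", 1:3), paste0("S", 1:4)))
  v2[, 4] <- v2[, 1]
  em2 <- expression_matrix(v2, "median_centered")
  cl2 <- hcl_cluster(em2, axis = "samples", linkage = "average")
  expect_equal(min(cl2$samples$tree$height), 0)
  expect_identical(sort(cl2$samples$tree$merge[1, ]), c(-4L, -1L))

  # deterministic: permuting input rows leaves the merge heights unchanged
  cl3 <- hcl_cluster(expression_matrix(v2[c(2, 3, 1), ], "median_centered"),
                     axis = "samples", linkage = "average")
  expect_equal(cl3$samples$tree$height, cl2$samples$tree$height)
})

test_that("logistic response model matches the 2x2 odds-ratio oracle", {
  # binary predictor: OR = ad/bc
  a <- 8; b <- 4; c_ <- 3; d <- 9
  x <- c(rep(1, a), rep(1, b), rep(0, c_), rep(0, d))
  y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  fit <- logistic_response_model(x, y)
  expect_equal(fit$or_, (a * d) / (b * c_), tolerance = 1e-6)
  expect_false(fit$separation)
  expect_true(fit$ci_low < fit$or_ && fit$or_ < fit$ci_high)

  # LRT p agrees with the nested-deviance test
  g0 <- glm(y ~ 1, family = binomial())
  g1 <- glm(y ~ x, family = binomial())
  expect_equal(fit$p_lrt, 1 - pchisq(g0$deviance - g1$deviance, 1),
               tolerance = 1e-12)

  # complete separation is flagged with no finite CI
  xs <- c(1:6, 11:16)
  ys <- rep(c(0, 1), each = 6)
  sep <- logistic_response_model(xs, ys)
  expect_true(sep$separation)
  expect_true(is.na(sep$ci_low))

  expect_error(logistic_response_model(rnorm(10), rep(1, 10)), "both")
  expect_error(logistic_response_model(rnorm(4), c(0, 1, 0, 1)), "n >= 6")
})

test_that("null logistic fits centre the odds ratio at one", {
  set.seed(70)
  betas <- replicate(60, {
    x <- rnorm(200)
    y <- rbinom(200, 1, 0.4)
    logistic_response_model(x, y)$beta1
  })
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("Welch volcano flags shifted analytes and controls the null", {
  set.seed(80)
  n <- 20
  v <- matrix(rnorm(50 * 2 * n, 0, 0.5), 50, 2 * n)
  v[7, 1:n] <- v[7, 1:n] + 2  # one analyte shifted by 2 log2 units
  em <- toy_paired_matrix(v)
  ids <- colnames(em$values)
  g1 <- ids[1:n]; g2 <- ids[(n + 1):(2 * n)]
  res <- welch_volcano(em, g1, g2)
  expect_true(res$significant[7])
  expect_equal(res$log2_fc[7], 2, tolerance = 0.5)
  # q never below p's procedure floor; flags clean
  expect_true(all(res$flag == "ok"))
  expect_lte(sum(res$significant), 3)

  # degenerate cases: identical constants p = 1; separated constants flagged
  vc <- matrix(1, 2, 8)
  vc[2, 5:8] <- 2
  emc <- toy_paired_matrix(vc)
  idc <- colnames(emc$values)
  resc <- welch_volcano(emc, idc[1:4], idc[5:8])
  expect_equal(resc$p[1], 1)
  expect_identical(resc$flag[1], "constant")
  expect_equal(resc$p[2], 0)
  expect_identical(resc$flag[2], "degenerate")
})

test_that("panel comparison pools analyte-sample values across groups", {
  set.seed(90)
  n_samp <- 20
  v <- matrix(rnorm(10 * n_samp), 10, n_samp,
              dimnames = list(sprintf("A%03d", 1:10),
                              sprintf("S%03d", 1:n_samp)))
  em <- expression_matrix(v, "median_centered")
  calls <- data.frame(sample_id = colnames(v), drug = "TAM",
                      label = rep(c("responder", "non-responder"),
                                  each = n_samp / 2))
  panel <- data.frame(drug = "TAM", direction = "sensitivity",
                      analyte_id = sprintf("A%03d", 1:5))

  # compositional identity with the pooled Mann-Whitney test
  res <- panel_compare(em, panel, calls)
  resp <- calls$sample_id[calls$label == "responder"]
  nonr <- calls$sample_id[calls$label == "non-responder"]
  direct <- mw_u_test(as.vector(v[1:5, resp]), as.vector(v[1:5, nonr]))
  expect_equal(res$pooled$U, direct$U)
  expect_equal(res$pooled$p, direct$p)

  # shifted panel is detected with the right direction
  v2 <- v
  v2[1:5, resp] <- v2[1:5, resp] + 1
  res2 <- panel_compare(expression_matrix(v2, "median_centered"), panel, calls)
  expect_lt(res2$pooled$p, 0.001)
  expect_true(res2$pooled$direction_consistent)

  # missing analytes are reported, run continues
  panel3 <- rbind(panel, data.frame(drug = "TAM", direction = "sensitivity",
                                    analyte_id = "A999"))
  expect_warning(res3 <- panel_compare(em, panel3, calls), "A999")
  expect_identical(res3$missing_analytes, "A999")
})
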