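two_group_design <- function(n_per = 4) {
  condition_design(rep(c("a", "b"), each = n_per))
}

test_that("two-group contrast reproduces the pooled-variance t closed form", {
  expr <- rbind(g1 = c(4, 4, 4, 2, 2, 2), g2 = c(5, 6, 7, 5, 6, 7),
                g3 = c(5.1, 6.3, 4.8, 3.2, 3.9, 3.1))
  design <- condition_design(rep(c("a", "b"), each = 3))
  fit <- fit_linear_contrast(expr, design, c(a = 1, b = -1))
  expect_equal(fit$log2fc, c(2, 0, mean(expr[3, 1:3]) - mean(expr[3, 4:6])))
  tt <- t.test(expr[3, 1:3], expr[3, 4:6], var.equal = TRUE)
  expect_equal(fit$t[3], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fit$p_value[3], tt$p.value, tolerance = 1e-10)
  expect_equal(fit$df[1], 4)
})

test_that("an all-zero contrast returns zero log2FC for every gene", {
  set.seed(1)
  expr <- matrix(rnorm(50 * 8), 50, dimnames = list(sprintf("g%d", 1:50), NULL))
  fit <- fit_linear_contrast(expr, two_group_design(), c(0, 0))
  expect_equal(fit$log2fc, rep(0, 50))
})

test_that("linear contrast estimates equal a normal-equations solve to 1e-10", {
  set.seed(42)
  cond <- sample(c("a", "b", "c"), 12, replace = TRUE)
  design <- condition_design(cond)
  expr <- matrix(rnorm(100 * 12), 100,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  contrast <- c(a = 1, b = -0.5, c = -0.5)
  fit <- fit_linear_contrast(expr, design, contrast)
  oracle <- ols_contrast_oracle(expr, design, contrast[colnames(design)])
  expect_equal(fit$log2fc, unname(oracle[, "log2fc"]), tolerance = 1e-10)
  expect_equal(fit$s2, unname(oracle[, "s2"]), tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  design <- cbind(two_group_design(3), dup = two_group_design(3)[, 1])
  expr <- matrix(rnorm(5 * 6), 5)
  expect_error(fit_linear_contrast(expr, design, c(1, -1, 0)),
               "rank deficient.*dup")
})

test_that("named contrasts are aligned to design columns by name", {
  cc <- simulate_coculture(coculture_config(seed = 8))
  design <- condition_design(cc$conditions$condition)
  canonical <- coculture_contrast()              # canonical condition order
  aligned <- coculture_contrast(colnames(design))  # design column order
  f1 <- fit_linear_contrast(cc$expr, design, canonical)
  f2 <- fit_linear_contrast(cc$expr, design, aligned)
  expect_equal(f1$log2fc, f2$log2fc)
  expect_error(fit_linear_contrast(cc$expr, design,
                                   c(bogus = 1, coculture_contrast()[-1])),
               "names")
})

test_that("moderation matches limma's empirical Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  design <- two_group_design(4)
  expr <- matrix(rnorm(300 * 8, sd = rep(sqrt(rchisq(300, 5) / 5), 8)), 300,
                 dimnames = list(sprintf("g%03d", 1:300), NULL))
  fit <- moderate(fit_linear_contrast(expr, design, c(a = 1, b = -1)))
  lfit <- limma::lmFit(expr, design)
  lfit <- limma::contrasts.fit(lfit, c(1, -1))
  lfit <- limma::eBayes(lfit)
  expect_equal(attr(fit, "d0"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s02"), lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$t, unname(lfit$t[, 1]), tolerance = 1e-6)
  expect_equal(fit$p_value, unname(lfit$p.value[, 1]), tolerance = 1e-6)
})

test_that("identical sample variances trigger the degenerate full-shrinkage prior", {
  # residual variance identical across genes by construction: shared residuals
  base <- rnorm(8)
  expr <- outer(rnorm(20), rep(1, 8)) + matrix(rep(base, each = 20), 20)
  rownames(expr) <- sprintf("g%d", 1:20)
  fit <- fit_linear_contrast(expr, two_group_design(4), c(a = 1, b = -1))
  expect_lt(diff(range(fit$s2)), 1e-12)
  mod <- moderate(fit)
  expect_true(is.infinite(attr(mod, "d0")))
  expect_equal(unique(round(mod$s2_post, 12)),
               round(attr(mod, "s02"), 12))
})

test_that("moderated t is monotone in |log2FC| at fixed variance", {
  set.seed(3)
  design <- two_group_design(4)
  expr <- matrix(rnorm(200 * 8), 200, dimnames = list(sprintf("g%d", 1:200), NULL))
  mod <- moderate(fit_linear_contrast(expr, design, c(a = 1, b = -1)))
  # same posterior variance => |t| ordering must follow |log2fc| ordering
  ord <- order(abs(mod$log2fc) / sqrt(mod$s2_post))
  expect_equal(order(abs(mod$t)), ord)
})

test_that("BH adjustment reproduces hand-derived examples and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjamini_hochberg(p), bh_bruteforce(p), tolerance = 1e-14)
  }
})

test_that("one biopsy per patient collapses the mixed model to OLS exactly", {
  set.seed(2)
  n_pat <- 12
  outcome <- setNames(rep(c("BCR", "NED"), each = n_pat / 2),
                      sprintf("P%02d", 1:n_pat))
  expr <- matrix(rnorm(20 * n_pat), 20,
                 dimnames = list(sprintf("g%d", 1:20), names(outcome)))
  res <- fit_mixed_model(expr, outcome, names(outcome))
  expect_true(all(res$method == "ols"))
  grp <- as.numeric(outcome == "BCR")
  ols <- t(apply(expr, 1, function(y) {
    s <- summary(lm(y ~ grp))$coefficients["grp", ]
    c(s[["Estimate"]], s[["Pr(>|t|)"]])
  }))
  expect_equal(res$beta, unname(ols[, 1]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(ols[, 2]), tolerance = 1e-8)
})

test_that("balanced repeated biopsies recover the patient-mean group estimate", {
  co <- simulate_cohort(cohort_config(n_patients = 16, biopsy_range = c(2, 2),
                                      bcr_fraction = 0.5, n_genes = 30,
                                      signature_effect = 0.8, seed = 21))
  ann <- co$annotation
  outcome <- co$truth$outcomes
  res <- fit_mixed_model(co$expr, outcome, ann$patient_id)
  # balanced random-intercept GLS equals the difference of patient-mean means
  pm <- t(apply(co$expr, 1, function(y) tapply(y, ann$patient_id, mean)))
  is_bcr <- outcome[colnames(pm)] == "BCR"
  closed <- rowMeans(pm[, is_bcr]) - rowMeans(pm[, !is_bcr])
  reml <- res$method == "reml"
  expect_gt(sum(reml), 0)
  expect_equal(res$beta[reml], unname(closed)[reml], tolerance = 1e-6)
})

test_that("mixed model rejects a patient split across outcome groups", {
  set.seed(5)
  expr <- matrix(rnorm(3 * 6), 3, dimnames = list(letters[1:3], NULL))
  pid <- c("P1", "P1", "P2", "P2", "P3", "P3")
  # sample-level outcome that contradicts patient-level blocking
  expect_error(
    fit_mixed_model(expr, c("BCR", "NED", "NED", "NED", "BCR", "BCR"), pid),
    "both outcome groups"
  )
})

test_that("REML solution is at least as good as the no-random-effect fit", {
  co <- simulate_cohort(cohort_config(n_patients = 10, biopsy_range = c(3, 3),
                                      bcr_fraction = 0.5, n_genes = 5,
                                      n_signature = 2, patient_sd = 0.7,
                                      seed = 31))
  grp <- as.numeric(co$annotation$outcome == "BCR")
  patient <- factor(co$annotation$patient_id)
  res <- fit_mixed_model(co$expr, co$truth$outcomes, co$annotation$patient_id)
  for (g in 1:5) {
    d <- data.frame(y = co$expr[g, ], grp = grp, patient = patient)
    devfun <- lme4::lmer(y ~ grp + (1 | patient), data = d, REML = TRUE,
                         devFunOnly = TRUE)
    theta_hat <- sqrt(res$sigma_u2[g] / res$sigma_e2[g])
    expect_lte(devfun(theta_hat), devfun(0) + 1e-6)
  }
})

test_that("mixed-model p-values are uniform under the null", {
  co <- simulate_cohort(cohort_config(n_patients = 20, biopsy_range = c(2, 2),
                                      bcr_fraction = 0.5, n_genes = 300,
                                      signature_effect = 0, patient_sd = 0.5,
                                      residual_sd = 0.5, seed = 17))
  res <- fit_mixed_model(co$expr, co$truth$outcomes, co$annotation$patient_id)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("filter_de applies the p and fold-change thresholds as stated", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    log2fc = c(1.2, 0.9, -1.5, 2.0, 0.2),
    p_value = c(0.04, 0.04, 0.01, 0.2, 0.001),
    p_adj = c(0.08, 0.08, 0.05, 0.3, 0.01)
  )
  expect_equal(filter_de(tab, 0.05, 1, use_adjusted = FALSE), c("a", "c"))
  # brute-force scan over rows agrees
  manual <- tab$gene[tab$p_value < 0.05 & abs(tab$log2fc) >= 1]
  expect_equal(filter_de(tab, 0.05, 1), manual)
  expect_equal(filter_de(tab, 0.1, 0.5, use_adjusted = TRUE), c("a", "b", "c"))
})
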