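#' Build a group-means design matrix from condition labels
#'
#' One indicator column per condition (no intercept), suitable for contrasts
#' such as [coculture_contrast()].
#'
#' @param condition Character or factor vector, one entry per sample.
#' @return Samples x conditions 0/1 matrix with condition names as columns.
#' @export
condition_design <- function(condition) {
  f <- factor(condition)
  x <- stats::model.matrix(~ 0 + f)
  colnames(x) <- levels(f)
  x
}

#' Gene-wise linear-model contrast (unmoderated)
#'
#' Fits the shared least-squares design to every gene and reports the
#' contrast combination `c' beta_hat` as log2 fold-change, with the ordinary
#' t-statistic from the per-gene residual variance.
#'
#' @param expr Genes x samples numeric matrix.
#' @param design Samples x coefficients design matrix (full column rank).
#' @param contrast Numeric contrast vector, one weight per coefficient.
#' @return A `de_result` data.frame (gene, log2fc, s2, df, t, p_value, p_adj)
#'   with attributes `se_factor` = sqrt(c'(X'X)^-1 c), `moderated = FALSE`.
#' @export
fit_linear_contrast <- function(expr, design, contrast) {
  expr <- as.matrix(expr)
  design <- as.matrix(design)
  if (nrow(design) != ncol(expr)) {
    stop("design has ", nrow(design), " rows but expression has ",
         ncol(expr), " samples")
  }
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    bad <- colnames(design)[qr_x$pivot[seq(qr_x$rank + 1, ncol(design))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(contrast) != ncol(design)) {
    stop("contrast length must match the number of design coefficients")
  }
  if (!is.null(names(contrast)) && !is.null(colnames(design))) {
    if (!setequal(names(contrast), colnames(design))) {
      stop("contrast names do not match design coefficient names")
    }
    contrast <- contrast[colnames(design)]
  }
  df_resid <- nrow(design) - ncol(design)
  if (df_resid < 1) stop("residual degrees of freedom must be >= 1")

  xtx_inv <- chol2inv(chol(crossprod(design)))
  beta <- expr %*% design %*% xtx_inv            # genes x coefficients
  resid <- expr - beta %*% t(design)
  s2 <- rowSums(resid^2) / df_resid
  se_factor <- sqrt(drop(t(contrast) %*% xtx_inv %*% contrast))
  log2fc <- drop(beta %*% contrast)

  if (se_factor == 0) {
    tstat <- rep(NA_real_, nrow(expr))
    p <- rep(NA_real_, nrow(expr))
  } else {
    tstat <- log2fc / (sqrt(s2) * se_factor)
    p <- 2 * stats::pt(-abs(tstat), df = df_resid)
  }
  out <- data.frame(
    gene = rownames(expr) %||% sprintf("gene%d", seq_len(nrow(expr))),
    log2fc = log2fc, s2 = s2, df = df_resid, t = tstat, p_value = p,
    p_adj = if (all(is.na(p))) p else benjamini_hochberg(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("de_result", "data.frame"),
            se_factor = se_factor, moderated = FALSE,
            d0 = NA_real_, s02 = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inverse of trigamma by Newton iteration on 1/x scale (Smyth's algorithm).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Moment-matching fit of the scaled inverse-chi-square variance prior
# (d0, s02) from log sample variances; d0 = Inf when the observed spread of
# log s2 is no larger than expected from chi-square sampling alone.
fit_variance_prior <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[keep])
  dg <- if (length(df) == 1) rep(df, sum(keep)) else df[keep]
  e <- z - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  n <- length(e)
  v <- mean((e - ebar)^2 * n / (n - 1) - trigamma(dg / 2))
  if (v <= 0) {
    list(d0 = Inf, s02 = exp(ebar))
  } else {
    d0 <- 2 * trigamma_inverse(v)
    list(d0 = d0, s02 = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderation of a gene-wise linear fit
#'
#' Estimates the variance prior (d0, s0^2) by moment matching on the log
#' sample variances (digamma/trigamma equations), shrinks each gene's
#' variance to the posterior `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and
#' recomputes t against d0 + d_g degrees of freedom. When all sample
#' variances are essentially identical the prior is degenerate (d0 = Inf)
#' and every posterior variance equals s0^2.
#'
#' @param fit A `de_result` from [fit_linear_contrast()].
#' @return A moderated `de_result` with updated t, p_value, p_adj, a
#'   `s2_post` column, and attributes `d0`, `s02`, `moderated = TRUE`.
#' @export
moderate <- function(fit) {
  stopifnot(inherits(fit, "de_result"))
  if (isTRUE(attr(fit, "moderated"))) stop("fit is already moderated")
  if (sum(fit$df > 0) < 2) stop("need at least 2 genes with positive residual df")
  prior <- fit_variance_prior(fit$s2, fit$df)
  d0 <- prior$d0
  s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) {
    rep(s02, nrow(fit))
  } else {
    (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
  }
  se_factor <- attr(fit, "se_factor")
  tstat <- fit$log2fc / (sqrt(s2_post) * se_factor)
  df_total <- d0 + fit$df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- fit
  out$s2_post <- s2_post
  out$t <- tstat
  out$df_total <- df_total
  out$p_value <- p
  out$p_adj <- benjamini_hochberg(p)
  attr(out, "moderated") <- TRUE
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-wise random-intercept mixed model for repeated biopsies
#'
#' Fits, per gene, `y = b0 + b1 * outcome + u_patient + e` by REML with the
#' patient as a random intercept, returning the Wald t-test of the outcome
#' effect with Satterthwaite degrees of freedom. A singular fit (estimated
#' sigma_u^2 at the zero boundary), or a design with a single biopsy per
#' patient, falls back to the ordinary two-group least-squares fit, whose
#' Wald test it then equals exactly.
#'
#' @param expr Genes x samples matrix; columns must match `patient_ids`.
#' @param outcome Patient-level labels: named vector (names = patient IDs)
#'   with two levels, e.g. "BCR"/"NED"; the second level sorted is the
#'   reference unless `positive` says otherwise.
#' @param patient_ids Patient ID per sample (length = ncol(expr)).
#' @param positive Label treated as the exposed group (default "BCR" when
#'   present, else the alphabetically last level).
#' @return An `lmm_result` data.frame: gene, beta (log2 units), sigma_u2,
#'   sigma_e2, statistic, df, p_value, p_adj, method ("reml" or "ols").
#' @export
fit_mixed_model <- function(expr, outcome, patient_ids, positive = NULL) {
  expr <- as.matrix(expr)
  if (length(patient_ids) != ncol(expr)) {
    stop("`patient_ids` must have one entry per expression column")
  }
  if (is.null(names(outcome))) {
    if (length(outcome) != ncol(expr)) {
      stop("`outcome` must be named by patient ID, or given per sample")
    }
    out_sample <- as.character(outcome)
  } else {
    if (!all(patient_ids %in% names(outcome))) {
      stop("every sample must map to a patient with an outcome")
    }
    out_sample <- as.character(outcome[patient_ids])
  }
  # outcome is patient-level by definition; a patient in two groups is an error
  split_chk <- tapply(out_sample, patient_ids, function(x) length(unique(x)))
  if (any(split_chk > 1)) {
    stop("patient(s) with samples in both outcome groups: ",
         paste(names(split_chk)[split_chk > 1], collapse = ", "))
  }
  lv <- sort(unique(as.character(out_sample)))
  if (length(lv) != 2) stop("outcome must have exactly two levels")
  if (is.null(positive)) positive <- if ("BCR" %in% lv) "BCR" else lv[2]
  grp <- as.numeric(out_sample == positive)
  if (min(table(tapply(grp, patient_ids, unique))) < 2) {
    stop("need at least 2 patients per outcome group")
  }
  patient <- factor(patient_ids)
  repeated <- any(table(patient) > 1)

  fit_one <- function(y) {
    if (repeated) {
      d <- data.frame(y = y, grp = grp, patient = patient)
      m <- suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ grp + (1 | patient), data = d, REML = TRUE)
      ))
      if (!lme4::isSingular(m, tol = 1e-5)) {
        co <- stats::coef(summary(m))["grp", ]
        vc <- lme4::VarCorr(m)
        return(c(beta = co[["Estimate"]], sigma_u2 = as.numeric(vc$patient),
                 sigma_e2 = attr(vc, "sc")^2, statistic = co[["t value"]],
                 df = co[["df"]], p_value = co[["Pr(>|t|)"]], ols = 0))
      }
    }
    m0 <- stats::lm(y ~ grp)
    co <- stats::coef(summary(m0))["grp", ]
    c(beta = co[["Estimate"]], sigma_u2 = 0,
      sigma_e2 = summary(m0)$sigma^2, statistic = co[["t value"]],
      df = m0$df.residual, p_value = co[["Pr(>|t|)"]], ols = 1)
  }

  res <- t(apply(expr, 1, fit_one))
  out <- data.frame(
    gene = rownames(expr) %||% sprintf("gene%d", seq_len(nrow(expr))),
    beta = res[, "beta"], sigma_u2 = res[, "sigma_u2"],
    sigma_e2 = res[, "sigma_e2"], statistic = res[, "statistic"],
    df = res[, "df"], p_value = res[, "p_value"],
    p_adj = benjamini_hochberg(res[, "p_value"]),
    method = ifelse(res[, "ols"] == 1, "ols", "reml"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("lmm_result", "data.frame"), positive = positive)
}

#' Filter a differential-expression table by p-value and fold-change
#'
#' @param result A `de_result` or `lmm_result` (needs `gene`, `p_value` or
#'   `p_adj`, and an effect column `log2fc`/`beta`).
#' @param p_threshold Retain genes with p below this value.
#' @param fc_threshold_log2 Retain genes with |log2 fold-change| at least
#'   this value (1 corresponds to the 2-fold rule).
#' @param use_adjusted Use BH-adjusted p-values instead of raw.
#' @return Character vector of retained gene IDs.
#' @export
filter_de <- function(result, p_threshold = 0.05, fc_threshold_log2 = 1,
                      use_adjusted = FALSE) {
  stopifnot(p_threshold > 0, fc_threshold_log2 >= 0)
  p <- if (use_adjusted) result$p_adj else result$p_value
  fc <- result$log2fc %||% result$beta
  result$gene[!is.na(p) & p < p_threshold & abs(fc) >= fc_threshold_log2]
}
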