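#' ROC curve and AUC via the Mann-Whitney rank identity
#'
#' AUC is the probability that a random positive outscores a random negative
#' with ties counted one half — identical to the trapezoid area under the
#' ROC curve traversed over all score thresholds.
#'
#' @param scores Numeric score per sample (higher = more positive).
#' @param labels Binary labels: logical, or values compared to `positive`.
#' @param positive Positive-class label used when `labels` is not logical,
#'   default "BCR".
#' @return A `roc_result` list: `auc`, `curve` (data.frame fpr, tpr ordered
#'   from (0,0) to (1,1)), `positive`.
#' @export
roc_auc <- function(scores, labels, positive = "BCR") {
  y <- if (is.logical(labels)) labels else labels == positive
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / n_neg, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  structure(list(auc = auc, curve = curve,
                 positive = if (is.logical(labels)) TRUE else positive),
            class = "roc_result")
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value by enumeration of the U null distribution when
#' the combined sample size is at most 12 and there are no ties; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @return List: `u` (number of (a, b) pairs with a > b, ties counted half),
#'   `p_value` (two-sided), `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must contain at least one value")
  }
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- n <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(u = unname(wt$statistic), p_value = min(1, wt$p.value), exact = exact)
}

#' Spearman correlation of a score against lesion volumes
#'
#' Volumes receive a pseudocount and a log10 transform before ranking (the
#' transform is monotone, so rho is unchanged; it only matters for
#' plotting). The p-value uses the t-approximation.
#'
#' @param x Numeric vector (e.g. signature scores).
#' @param volumes Non-negative lesion volumes (cm^3).
#' @param pseudocount Added to volumes before log10; default 0.1 cm^3.
#' @return List: `rho`, `p_value`, `log10_volumes` (the transformed values).
#' @export
spearman_volume <- function(x, volumes, pseudocount = 0.1) {
  if (length(x) != length(volumes)) stop("`x` and `volumes` differ in length")
  if (any(volumes < 0)) stop("volumes must be non-negative")
  lv <- log10(volumes + pseudocount)
  ct <- suppressWarnings(
    stats::cor.test(x, lv, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, log10_volumes = lv)
}

#' Call biochemical recurrence from a PSA series (Phoenix rule)
#'
#' The nadir is the running minimum of all PSA values up to each time; BCR
#' is called at the first time the PSA rises to the running nadir plus
#' 2 ng/mL or more (inclusive). Later declines cannot retract a call.
#'
#' @param time_months Strictly increasing measurement times.
#' @param psa_ng_ml PSA values (ng/mL), same length.
#' @return A `bcr_call` list: `outcome` ("BCR"/"NED"), `time_bcr` (months,
#'   NA if NED), `nadir` (ng/mL; running nadir at the call, or the overall
#'   nadir for NED).
#' @export
call_bcr <- function(time_months, psa_ng_ml) {
  if (length(time_months) != length(psa_ng_ml) || length(time_months) < 1) {
    stop("need matching, non-empty time and PSA vectors")
  }
  if (any(diff(time_months) <= 0)) stop("time stamps must be strictly increasing")
  nadir <- cummin(psa_ng_ml)
  hit <- which(psa_ng_ml >= nadir + 2.0)
  if (length(hit) > 0) {
    i <- hit[1]
    structure(list(outcome = "BCR", time_bcr = time_months[i],
                   nadir = nadir[i]), class = "bcr_call")
  } else {
    structure(list(outcome = "NED", time_bcr = NA_real_,
                   nadir = min(psa_ng_ml)), class = "bcr_call")
  }
}

#' Apply the Phoenix caller to a cohort PSA table
#'
#' @param series Data.frame with patient_id, time_months, psa_ng_ml (see
#'   [simulate_psa_series()]).
#' @return Data.frame: patient_id, outcome, time_bcr, nadir.
#' @export
call_bcr_cohort <- function(series) {
  stopifnot(all(c("patient_id", "time_months", "psa_ng_ml") %in% names(series)))
  pts <- unique(series$patient_id)
  rows <- lapply(pts, function(p) {
    s <- series[series$patient_id == p, ]
    s <- s[order(s$time_months), ]
    cl <- call_bcr(s$time_months, s$psa_ng_ml)
    data.frame(patient_id = p, outcome = cl$outcome, time_bcr = cl$time_bcr,
               nadir = cl$nadir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
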