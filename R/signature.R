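#' Contrast for the TGF-beta co-culture derivation
#'
#' Weight +1 on the TGF-beta-stimulated co-culture and -1/5 on each of the
#' five negative conditions, aligned to the columns of a group-means design.
#'
#' @param conditions Condition names available in the design (default the
#'   canonical six of [coculture_conditions()]).
#' @return Named numeric contrast vector over `conditions`.
#' @export
coculture_contrast <- function(conditions = coculture_conditions()) {
  need <- coculture_conditions()
  missing <- setdiff(need, conditions)
  if (length(missing) > 0) {
    stop("design is missing condition(s): ", paste(missing, collapse = ", "))
  }
  w <- stats::setNames(rep(0, length(conditions)), conditions)
  w["cocult_tgfb"] <- 1
  w[setdiff(need, "cocult_tgfb")] <- -1 / 5
  w
}

#' Rank signature candidates by fold-change under an FDR filter
#'
#' Keeps genes with BH-adjusted p below `fdr_threshold` and orders them by
#' descending log2 fold-change (ties broken by gene ID for determinism).
#'
#' @param de A `de_result` with `p_adj` (see [moderate()]).
#' @param fdr_threshold Adjusted-p cutoff, default 0.1.
#' @return A `ranked_candidates` data.frame (gene, log2fc, p_adj), possibly
#'   empty.
#' @export
rank_candidates <- function(de, fdr_threshold = 0.1) {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "p_adj") %in% names(de)))
  keep <- !is.na(de$p_adj) & de$p_adj < fdr_threshold
  out <- de[keep, c("gene", "log2fc", "p_adj")]
  out <- out[order(-out$log2fc, out$gene), ]
  rownames(out) <- NULL
  structure(out, class = c("ranked_candidates", "data.frame"),
            fdr_threshold = fdr_threshold)
}

#' Parameters of the ssGSEA running-sum score
#'
#' @param tau Rank-weighting exponent; 0.25 is the value used throughout the
#'   pipeline.
#' @param normalize Rescale the cohort's scores by (max - min) across
#'   samples; single-sample use should set FALSE (scores then comparable
#'   only within a run).
#' @param allow_missing If TRUE, signature genes absent from the expression
#'   matrix are dropped with a warning instead of an error.
#' @return An `ssgsea_params` list.
#' @export
ssgsea_params <- function(tau = 0.25, normalize = TRUE, allow_missing = FALSE) {
  if (tau < 0) stop("`tau` must be >= 0")
  structure(list(tau = tau, normalize = normalize,
                 allow_missing = allow_missing),
            class = "ssgsea_params")
}

#' Single-sample gene-set enrichment (ssGSEA running sum)
#'
#' Per sample, genes are ranked by expression (average ranks on ties; the
#' most expressed gene has rank N) and walked in descending rank order (rank
#' ties broken by gene ID). The score is the sum over walk positions of the
#' difference between the tau-weighted in-set ECDF,
#' `P_G(i) = sum_(g in G, pos <= i) r_g^tau / sum_(g in G) r_g^tau`, and the
#' out-of-set ECDF `P_NG(i) = #\{g not in G, pos <= i\} / (N - |G|)`.
#'
#' @param expr Genes x samples numeric matrix.
#' @param genes Character vector: the gene set G (or a `gene_signature`).
#' @param params An [ssgsea_params()].
#' @return Named numeric vector of enrichment scores, one per sample;
#'   attribute `raw` carries unnormalized scores when `normalize` is TRUE.
#' @export
ssgsea <- function(expr, genes, params = ssgsea_params()) {
  stopifnot(inherits(params, "ssgsea_params"))
  if (inherits(genes, "gene_signature")) genes <- genes$genes
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix must have gene rownames")
  genes <- unique(genes)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    if (!params$allow_missing) {
      stop("signature gene(s) absent from expression matrix: ",
           paste(absent, collapse = ", "))
    }
    warning("dropping ", length(absent), " signature gene(s) absent from matrix")
    genes <- setdiff(genes, absent)
  }
  if (length(genes) == 0) stop("no signature genes present in the matrix")
  if (length(genes) >= nrow(expr)) {
    stop("gene set must be a strict subset of the matrix genes")
  }
  in_set <- rownames(expr) %in% genes
  n <- nrow(expr)
  n_out <- n - sum(in_set)
  ids <- rownames(expr)

  score_one <- function(x) {
    r <- rank(x, ties.method = "average")
    ord <- order(-r, ids)
    ins <- in_set[ord]
    rw <- r[ord]^params$tau * ins
    p_g <- cumsum(rw) / sum(rw)
    p_ng <- cumsum(!ins) / n_out
    sum(p_g - p_ng)
  }
  es <- apply(expr, 2, score_one)
  if (params$normalize) {
    rng <- max(es) - min(es)
    if (rng == 0) {
      warning("degenerate score range; returning unnormalized scores")
      return(es)
    }
    out <- es / rng
    attr(out, "raw") <- es
    return(out)
  }
  es
}

#' Construct a gene signature object
#'
#' @param genes Ordered gene identifiers.
#' @param tau Weighting exponent used for scoring.
#' @param locked Locked signatures are immutable: any field assignment fails.
#' @param provenance Free-form list (thresholds, contrast name, AUC trace).
#' @return A `gene_signature`.
#' @export
gene_signature <- function(genes, tau = 0.25, locked = FALSE,
                           provenance = list()) {
  stopifnot(is.character(genes), length(genes) >= 1, !anyDuplicated(genes))
  structure(list(genes = genes, n = length(genes), tau = tau,
                 locked = locked, provenance = provenance),
            class = "gene_signature")
}

#' @export
`$<-.gene_signature` <- function(x, name, value) {
  if (isTRUE(x[["locked"]])) stop("signature is locked and cannot be modified")
  NextMethod()
}

#' @export
`[[<-.gene_signature` <- function(x, i, value) {
  if (isTRUE(x[["locked"]])) stop("signature is locked and cannot be modified")
  NextMethod()
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature (", x$n, " genes, tau = ", x$tau,
      if (x$locked) ", locked" else "", ")\n", sep = "")
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Select signature size by local-maximum AUC
#'
#' Scores the top-N candidate genes (N from `n_start` upward) by ssGSEA in
#' the discovery cohort, computes the ROC AUC against the outcome labels,
#' and returns the smallest N that is a local maximum of the AUC trace
#' (AUC(N) >= AUC(N-1) where defined and AUC(N) >= AUC(N+1)). If the trace
#' strictly increases through `n_max`, `n_max` is returned with a warning.
#' The returned signature is locked; the full AUC trace is kept in its
#' provenance.
#'
#' @param candidates A `ranked_candidates` table (see [rank_candidates()]).
#' @param expr Discovery genes x samples matrix.
#' @param labels Binary outcome per sample (logical, or values matching
#'   `positive`).
#' @param n_start Smallest signature size tried, default 3.
#' @param n_max Largest size tried; default `min(30, nrow(candidates))`.
#' @param params An [ssgsea_params()].
#' @param positive Label of the positive class, default "BCR".
#' @return A locked `gene_signature` with the selected top-N genes.
#' @export
select_signature <- function(candidates, expr, labels, n_start = 3,
                             n_max = NULL, params = ssgsea_params(),
                             positive = "BCR") {
  stopifnot(inherits(candidates, "ranked_candidates"))
  if (is.null(n_max)) n_max <- min(30, nrow(candidates))
  if (nrow(candidates) < n_start) {
    stop("need at least ", n_start, " candidates; have ", nrow(candidates))
  }
  n_max <- min(n_max, nrow(candidates))
  y <- if (is.logical(labels)) labels else labels == positive
  if (length(unique(y)) < 2) stop("both outcome classes must be present")

  sizes <- n_start:n_max
  aucs <- vapply(sizes, function(n) {
    sc <- ssgsea(expr, candidates$gene[seq_len(n)], params)
    roc_auc(sc, y)$auc
  }, numeric(1))

  pick <- NA_integer_
  for (k in seq_along(sizes)) {
    left_ok <- k == 1 || aucs[k] >= aucs[k - 1]
    right_ok <- k == length(sizes) || aucs[k] >= aucs[k + 1]
    if (left_ok && right_ok) { pick <- k; break }
  }
  if (is.na(pick)) pick <- length(sizes)  # unreachable, defensive
  if (pick == length(sizes) && length(sizes) > 1 && all(diff(aucs) > 0)) {
    warning("AUC still increasing at n_max = ", n_max,
            "; returning n_max — consider raising it")
  }
  n_sel <- sizes[pick]
  gene_signature(
    candidates$gene[seq_len(n_sel)], tau = params$tau, locked = TRUE,
    provenance = list(
      fdr_threshold = attr(candidates, "fdr_threshold"),
      n_start = n_start, n_max = n_max,
      auc_trace = stats::setNames(aucs, sizes),
      discovery_auc = aucs[pick]
    )
  )
}
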