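#' Derive and lock the TGF-beta signature end to end
#'
#' Runs the full derivation: moderated linear contrast of the stimulated
#' co-culture against the five negative conditions, FDR-filtered
#' fold-change ranking, then top-N local-maximum-AUC selection of the
#' signature size in the discovery cohort, scored by ssGSEA.
#'
#' @param coculture Output of [simulate_coculture()] (or a list with `expr`
#'   and `conditions` of the same shape).
#' @param cohort_expr Discovery cohort genes x samples matrix.
#' @param cohort_labels Outcome per cohort sample ("BCR"/"NED" or logical).
#' @param config A [run_config()].
#' @return List: `signature` (locked), `candidates`, `de` (moderated
#'   `de_result`), `scores` (ssGSEA of the selected signature on the
#'   cohort), `roc` (discovery `roc_result`).
#' @export
derive_signature <- function(coculture, cohort_expr, cohort_labels,
                             config = run_config()) {
  design <- condition_design(coculture$conditions$condition)
  contrast <- coculture_contrast(colnames(design))
  de <- moderate(fit_linear_contrast(coculture$expr, design, contrast))
  candidates <- rank_candidates(de, fdr_threshold = config$fdr_threshold)
  params <- ssgsea_params(tau = config$tau,
                          normalize = config$normalize_scores,
                          allow_missing = config$allow_missing_genes)
  sig <- select_signature(candidates, cohort_expr, cohort_labels,
                          n_start = config$n_start, params = params)
  scores <- ssgsea(cohort_expr, sig, params)
  roc <- roc_auc(scores, cohort_labels)
  list(signature = sig, candidates = candidates, de = de,
       scores = scores, roc = roc)
}
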