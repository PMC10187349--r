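toy_expr <- function(values, genes = LETTERS[seq_along(values)]) {
  matrix(values, ncol = 1, dimnames = list(genes, "s1"))
}

test_that("co-culture contrast weights the positive arm against five negatives", {
  w <- coculture_contrast()
  expect_equal(sum(w), 0)
  expect_equal(unname(w["cocult_tgfb"]), 1)
  expect_equal(unname(w[names(w) != "cocult_tgfb"]), rep(-0.2, 5))
  expect_error(coculture_contrast(c("cocult_tgfb", "stroma_tgfb")),
               "cocult_vehicle")
  # a gene flat across all conditions gets log2FC 0
  cond <- rep(coculture_conditions(), each = 2)
  design <- condition_design(cond)
  flat <- matrix(5, 1, length(cond), dimnames = list("g1", NULL))
  fit <- fit_linear_contrast(flat, design, coculture_contrast(colnames(design)))
  expect_equal(fit$log2fc, 0)
})

test_that("candidate ranking filters on FDR then orders by fold-change", {
  de <- data.frame(gene = c("A", "B", "C"), log2fc = c(3, 5, 2),
                   p_adj = c(0.01, 0.2, 0.05))
  rc <- rank_candidates(de, fdr_threshold = 0.1)
  expect_equal(rc$gene, c("A", "C"))
  all_fail <- data.frame(gene = "A", log2fc = 1, p_adj = 0.5)
  expect_equal(nrow(rank_candidates(all_fail)), 0)
  ties <- data.frame(gene = c("B", "A"), log2fc = c(1, 1), p_adj = c(0.01, 0.01))
  expect_equal(rank_candidates(ties)$gene, c("A", "B"))
})

test_that("ssGSEA reproduces the hand-derived three-gene running sums", {
  p <- ssgsea_params(normalize = FALSE)
  top <- ssgsea(toy_expr(c(3, 2, 1)), "A", p)
  expect_equal(unname(top), 1.5)
  bottom <- ssgsea(toy_expr(c(3, 2, 1)), "C", p)
  expect_equal(unname(bottom), -1.5)
  # tau does not matter for a singleton set
  expect_equal(unname(ssgsea(toy_expr(c(3, 2, 1)), "A",
                             ssgsea_params(tau = 2, normalize = FALSE))), 1.5)
})

test_that("ssGSEA matches the naive double-loop oracle", {
  set.seed(12)
  for (i in 1:10) {
    expr <- matrix(rnorm(30 * 6), 30, 6,
                   dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
    genes <- sample(rownames(expr), 5)
    for (tau in c(0, 0.25, 1)) {
      es <- ssgsea(expr, genes, ssgsea_params(tau = tau, normalize = FALSE))
      expect_equal(unname(es), ssgsea_oracle(expr, genes, tau),
                   tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA is rank-based: invariant to monotone transforms", {
  set.seed(13)
  expr <- matrix(rnorm(40 * 5), 40, 5,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:5)))
  genes <- sprintf("g%02d", 1:6)
  p <- ssgsea_params(normalize = FALSE)
  expect_equal(ssgsea(expr, genes, p), ssgsea(exp(expr), genes, p))
  expect_equal(ssgsea(expr, genes, p), ssgsea(expr^3, genes, p))
})

test_that("at tau = 0 swapping the set and its complement negates the score", {
  set.seed(14)
  expr <- matrix(rnorm(20 * 4), 20, 4,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:4)))
  genes <- sprintf("g%02d", 1:7)
  comp <- setdiff(rownames(expr), genes)
  p0 <- ssgsea_params(tau = 0, normalize = FALSE)
  expect_equal(unname(ssgsea(expr, genes, p0)),
               -unname(ssgsea(expr, comp, p0)), tolerance = 1e-12)
})

test_that("scores are bounded by N - 1 and normalization rescales by the range", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    expr <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:3)))
    genes <- sample(rownames(expr), sample(1:(n - 1), 1))
    es <- ssgsea(expr, genes, ssgsea_params(normalize = FALSE))
    expect_true(all(abs(es) <= n - 1 + 1e-12))
  }
  expr <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  raw <- ssgsea(expr, sprintf("g%02d", 1:5), ssgsea_params(normalize = FALSE))
  norm <- ssgsea(expr, sprintf("g%02d", 1:5), ssgsea_params(normalize = TRUE))
  expect_equal(as.numeric(norm), unname(raw / (max(raw) - min(raw))))
})

test_that("ssGSEA rejects degenerate gene sets and missing genes by default", {
  expr <- matrix(rnorm(10 * 2), 10, 2,
                 dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  expect_error(ssgsea(expr, rownames(expr)), "strict subset")
  expect_error(ssgsea(expr, c("g01", "nope")), "absent")
  expect_warning(
    es <- ssgsea(expr, c("g01", "nope"),
                 ssgsea_params(normalize = FALSE, allow_missing = TRUE)),
    "dropping"
  )
  expect_equal(es, ssgsea(expr, "g01", ssgsea_params(normalize = FALSE)))
})

test_that("locked signatures are immutable", {
  sig <- gene_signature(c("A", "B", "C"), locked = TRUE)
  expect_error(sig$genes <- c("X"), "locked")
  expect_error(sig[["n"]] <- 5, "locked")
  open <- gene_signature(c("A", "B", "C"), locked = FALSE)
  expect_silent(open$tau <- 0.5)
})

test_that("signature size lands on the smallest local maximum of the AUC trace", {
  cc <- simulate_coculture(coculture_config(seed = 19))
  co <- simulate_cohort(cohort_config(seed = 19,
                                      signature_genes = cc$truth$planted_genes))
  res <- suppressWarnings(derive_signature(cc, co$expr, co$annotation$outcome))
  sig <- res$signature
  trace <- sig$provenance$auc_trace
  sizes <- as.integer(names(trace))
  k <- match(sig$n, sizes)
  expect_gte(sig$n, 3)
  expect_true(sig$locked)
  # local-maximum definition, recomputed from the returned trace
  if (k > 1) expect_gte(trace[k], trace[k - 1])
  if (k < length(trace)) expect_gte(trace[k], trace[k + 1])
  for (j in seq_len(k - 1)) {
    left_ok <- j == 1 || trace[j] >= trace[j - 1]
    right_ok <- trace[j] >= trace[j + 1]
    expect_false(left_ok && right_ok)  # no earlier local max was skipped
  }
  expect_equal(unname(sig$provenance$discovery_auc), unname(res$roc$auc))
})

test_that("a strictly increasing AUC trace returns n_max with a warning", {
  cc <- simulate_coculture(coculture_config(seed = 23, n_planted = 8,
                                            planted_log2fc = 2))
  co <- simulate_cohort(cohort_config(seed = 23,
                                      signature_genes = cc$truth$planted_genes))
  design <- condition_design(cc$conditions$condition)
  de <- moderate(fit_linear_contrast(cc$expr, design,
                                     coculture_contrast(colnames(design))))
  cand <- rank_candidates(de)
  skip_if(nrow(cand) < 4)
  # force a short search so the trace cannot turn over before n_max
  got_warning <- FALSE
  sig <- withCallingHandlers(
    select_signature(cand, co$expr, co$annotation$outcome,
                     n_start = 3, n_max = 4),
    warning = function(w) {
      got_warning <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  trace <- sig$provenance$auc_trace
  if (all(diff(trace) > 0)) {
    expect_true(got_warning)
    expect_equal(sig$n, 4)
  } else {
    succeed()
  }
})

test_that("selection errors on too few candidates or one-class labels", {
  cand <- structure(data.frame(gene = c("A", "B"), log2fc = c(2, 1),
                               p_adj = c(0.01, 0.01)),
                    class = c("ranked_candidates", "data.frame"))
  expr <- matrix(rnorm(10 * 4), 10, 4,
                 dimnames = list(c("A", "B", sprintf("g%d", 1:8)),
                                 sprintf("s%d", 1:4)))
  expect_error(select_signature(cand, expr, c(TRUE, TRUE, FALSE, FALSE)),
               "at least 3")
  cand3 <- structure(data.frame(gene = c("A", "B", "g1"), log2fc = 3:1,
                                p_adj = rep(0.01, 3)),
                     class = c("ranked_candidates", "data.frame"))
  expect_error(select_signature(cand3, expr, rep(TRUE, 4)), "both outcome")
})

test_that("in-sample selection on null cohorts shows only modest optimism", {
  aucs <- vapply(1:9, function(s) {
    cc <- simulate_coculture(coculture_config(seed = 100 + s))
    co <- simulate_cohort(cohort_config(seed = 100 + s, signature_effect = 0,
                                        signature_genes = cc$truth$planted_genes))
    res <- suppressWarnings(derive_signature(cc, co$expr, co$annotation$outcome))
    res$signature$provenance$discovery_auc
  }, numeric(1))
  expect_gte(median(aucs), 0.45)
  expect_lte(median(aucs), 0.65)
})
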