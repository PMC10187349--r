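# Independent oracles used to cross-check the package implementations.
# Each is a direct transcription of the defining formula, kept deliberately
# naive (loops, enumeration) and separate from the package code paths.

# ssGSEA by a naive double loop over walk positions.
ssgsea_oracle <- function(expr, genes, tau) {
  ids <- rownames(expr)
  n_out <- length(ids) - length(genes)
  vapply(seq_len(ncol(expr)), function(s) {
    x <- expr[, s]
    r <- rank(x, ties.method = "average")
    ord <- ids[order(-r, ids)]
    denom <- sum(r[genes]^tau)
    es <- 0
    for (i in seq_along(ord)) {
      walked <- ord[seq_len(i)]
      in_walked <- walked[walked %in% genes]
      p_g <- if (length(in_walked) > 0) sum(r[in_walked]^tau) / denom else 0
      p_ng <- sum(!walked %in% genes) / n_out
      es <- es + (p_g - p_ng)
    }
    es
  }, numeric(1))
}

# Benjamini-Hochberg by the literal step-up definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Mann-Whitney U and exact two-sided p by full enumeration of assignments.
mw_enumeration <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  us <- apply(utils::combn(length(pooled), na), 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  list(u = u_obs,
       p_value = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

# AUC as the normalized count of concordant positive/negative pairs.
auc_pairs <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Least-squares contrast by explicit normal equations, one gene at a time.
ols_contrast_oracle <- function(expr, design, contrast) {
  t(vapply(seq_len(nrow(expr)), function(g) {
    y <- expr[g, ]
    beta <- solve(t(design) %*% design, t(design) %*% y)
    res <- y - design %*% beta
    df <- length(y) - ncol(design)
    c(log2fc = sum(contrast * beta), s2 = sum(res^2) / df)
  }, numeric(2)))
}
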