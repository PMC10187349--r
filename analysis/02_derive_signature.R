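#!/usr/bin/env Rscript

# Step 2: derive the TGF-beta signature from the co-culture contrast.
#
# Moderated linear contrast of the TGF-beta-stimulated co-culture against
# the five negative conditions, FDR < 0.1 candidates ranked by log2
# fold-change, then local-maximum-AUC size selection in the discovery
# cohort. Writes the DE table, the ranked candidates, the AUC trace and
# the locked signature (GMT).

suppressPackageStartupMessages(library(tgfbsig))

cfg <- run_config(seed = 1L)
dat <- "results/data"
out <- "results"

expr <- read_expression(file.path(dat, "coculture_expression.gct"))
conditions <- read_table_tsv(file.path(dat, "coculture_conditions.tsv"))
cohort <- read_expression(file.path(dat, "cohort_expression.tsv"))
ann <- read_table_tsv(file.path(dat, "cohort_annotation.tsv"))

design <- condition_design(conditions$condition)
contrast <- coculture_contrast(colnames(design))
de <- moderate(fit_linear_contrast(expr, design, contrast))
write_table_tsv(as.data.frame(de), file.path(out, "coculture_de.tsv"))
message(sprintf("co-culture DE: %d genes, prior d0 = %.1f, s0^2 = %.3f",
                nrow(de), attr(de, "d0"), attr(de, "s02")))

cand <- rank_candidates(de, fdr_threshold = cfg$fdr_threshold)
write_table_tsv(as.data.frame(cand), file.path(out, "signature_candidates.tsv"))
message(sprintf("%d candidate genes at FDR < %.2f, ranked by log2FC",
                nrow(cand), cfg$fdr_threshold))

params <- ssgsea_params(tau = cfg$tau, normalize = cfg$normalize_scores)
sig <- select_signature(cand, cohort, ann$outcome, n_start = cfg$n_start,
                        params = params)
write_gmt(sig, file.path(out, "tgfb_signature.gmt"))
trace <- sig$provenance$auc_trace
write_table_tsv(data.frame(n_genes = as.integer(names(trace)), auc = trace),
                file.path(out, "signature_auc_trace.tsv"))
message(sprintf("locked %d-gene signature (tau = %.2f), discovery AUC %.3f",
                sig$n, sig$tau, sig$provenance$discovery_auc))
message("genes: ", paste(sig$genes, collapse = ", "))
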