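#!/usr/bin/env Rscript

# Step 1: generate the synthetic study inputs.
#
# Produces, under results/data/: the six-condition co-culture expression
# matrix (GCT), the repeated-biopsy cohort expression matrix and annotation,
# PTEN/TP53 allele-call tables (MAF-like mutations + gene-level copy
# losses are emulated directly as a joined table), post-treatment PSA
# series, and a JSON record of all planted truths.

suppressPackageStartupMessages(library(tgfbsig))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cc <- simulate_coculture(coculture_config(
  n_genes = 200, n_planted = 6, planted_log2fc = 2, n_replicates = 3,
  seed = seed))
write_expression(cc$expr, file.path(out, "coculture_expression.gct"),
                 format = "gct")
write_table_tsv(cc$conditions, file.path(out, "coculture_conditions.tsv"))

co <- simulate_cohort(cohort_config(
  n_patients = 29, bcr_fraction = 0.17, signature_effect = 1,
  patient_sd = 0.5, residual_sd = 0.5,
  signature_genes = cc$truth$planted_genes, seed = seed))
write_expression(co$expr, file.path(out, "cohort_expression.tsv"))
write_table_tsv(co$annotation, file.path(out, "cohort_annotation.tsv"))

calls <- simulate_allele_calls(allele_config(seed = seed), co$annotation)
write_table_tsv(calls, file.path(out, "allele_calls.tsv"))

psa <- simulate_psa_series(co$annotation, psa_config(seed = seed))
write_table_tsv(psa, file.path(out, "psa_series.tsv"))

truth <- list(
  planted_coculture_genes = cc$truth$planted_genes,
  planted_log2fc = cc$truth$planted_log2fc,
  cohort_outcomes = as.list(co$truth$outcomes),
  intended_alleles = attr(calls, "truth"),
  psa_truth = attr(psa, "truth")
)
jsonlite::write_json(truth, file.path(out, "planted_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf(
  "simulated: co-culture %d genes x %d arrays; cohort %d patients, %d biopsies (%d BCR); %d allele rows; %d PSA points",
  nrow(cc$expr), ncol(cc$expr), length(unique(co$annotation$patient_id)),
  ncol(co$expr), sum(co$truth$outcomes == "BCR"), nrow(calls), nrow(psa)))
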