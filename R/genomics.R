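tumor_suppressors <- c("PTEN", "TP53")

validate_allele_rows <- function(calls) {
  need <- c("gene", "copies_lost", "oncogenic_mutation_count")
  if (!all(need %in% names(calls))) {
    stop("allele calls need columns: ", paste(need, collapse = ", "))
  }
  if (any(calls$copies_lost < 0 | calls$copies_lost > 2)) {
    stop("`copies_lost` must be in 0..2")
  }
  if (any(calls$oncogenic_mutation_count < 0)) {
    stop("`oncogenic_mutation_count` must be non-negative")
  }
  invisible(calls)
}

#' Count altered PTEN/TP53 alleles for one sample
#'
#' The allele-dosage count is `A = sum over genes of
#' min(2, copies_lost + oncogenic_mutation_count)`: each tumor suppressor
#' contributes at most its two alleles, so a mutation on an already-deleted
#' allele cannot push a gene past 2. A sample is classified high-risk
#' (positive) when `A >= threshold` (default 3, the 3-allele cutpoint).
#'
#' @param calls Data.frame of this sample's rows: gene ("PTEN"/"TP53"),
#'   copies_lost in 0..2, oncogenic_mutation_count >= 0. A gene without a
#'   row is treated as unaltered, with a warning.
#' @param threshold Positivity cutpoint on A, default 3.
#' @return List: `a_count` (0..4), `positive`, `per_gene` contributions,
#'   `threshold`.
#' @export
count_altered_alleles <- function(calls, threshold = 3) {
  validate_allele_rows(calls)
  calls <- calls[calls$gene %in% tumor_suppressors, , drop = FALSE]
  if (anyDuplicated(calls$gene)) stop("one row per gene expected")
  missing <- setdiff(tumor_suppressors, calls$gene)
  if (length(missing) > 0) {
    warning("no allele call for ", paste(missing, collapse = ", "),
            "; treated as unaltered")
  }
  per_gene <- stats::setNames(rep(0L, 2), tumor_suppressors)
  hit <- pmin(2, calls$copies_lost + calls$oncogenic_mutation_count)
  per_gene[calls$gene] <- as.integer(hit)
  a <- sum(per_gene)
  list(a_count = a, positive = a >= threshold, per_gene = per_gene,
       threshold = threshold)
}

#' Allele-dosage counts for every sample in a call table
#'
#' @param table Allele-call table (sample_id, gene, copies_lost,
#'   oncogenic_mutation_count), one row per (sample, gene).
#' @param threshold Positivity cutpoint, default 3.
#' @return Data.frame: sample_id, a_count, positive.
#' @export
allele_dose <- function(table, threshold = 3) {
  validate_allele_rows(table)
  if (anyDuplicated(table[, c("sample_id", "gene")])) {
    stop("duplicate (sample, gene) rows in allele-call table")
  }
  samples <- unique(table$sample_id)
  res <- lapply(samples, function(s) {
    suppressWarnings(count_altered_alleles(table[table$sample_id == s, ],
                                           threshold = threshold))
  })
  data.frame(sample_id = samples,
             a_count = vapply(res, `[[`, integer(1), "a_count"),
             positive = vapply(res, `[[`, logical(1), "positive"),
             stringsAsFactors = FALSE)
}

#' Select the representative biopsy core of a tumor
#'
#' The core with the highest Gleason grade group wins; ties go to the core
#' with the greatest percentage of tumor at the highest-grade pattern; a
#' residual tie goes to the lexicographically smallest biopsy ID.
#'
#' @param biopsies Data.frame with biopsy_id, grade_group (1-5),
#'   pct_highest_grade (0-100).
#' @return The selected biopsy ID.
#' @export
select_representative_biopsy <- function(biopsies) {
  if (is.null(biopsies) || nrow(biopsies) == 0) stop("no biopsies to select from")
  need <- c("biopsy_id", "grade_group", "pct_highest_grade")
  if (!all(need %in% names(biopsies))) {
    stop("biopsy records need columns: ", paste(need, collapse = ", "))
  }
  if (any(!biopsies$grade_group %in% 1:5)) stop("grade_group must be in 1..5")
  ord <- order(-biopsies$grade_group, -biopsies$pct_highest_grade,
               biopsies$biopsy_id)
  biopsies$biopsy_id[ord[1]]
}

#' Patient-level allele-dosage classification and its operating
#' characteristics
#'
#' Designates one representative biopsy per patient (highest grade group,
#' ties by percent highest-grade pattern), applies the `A >= threshold` rule
#' to that sample, and tallies the patient-level confusion matrix against
#' the BCR/NED outcome. Specificity is TN / (TN + FP) among NED patients.
#'
#' @param table Allele-call table with sample_id, patient_id, gene,
#'   copies_lost, oncogenic_mutation_count.
#' @param annotation Sample annotation with sample_id, patient_id, outcome,
#'   grade_group, pct_highest_grade.
#' @param threshold Positivity cutpoint, default 3.
#' @return List: `per_patient` data.frame (patient_id, sample_id, a_count,
#'   positive, outcome), `confusion` (TP, FP, TN, FN), `sensitivity`,
#'   `specificity`, `threshold`.
#' @export
classify_cohort <- function(table, annotation, threshold = 3) {
  need <- c("sample_id", "patient_id", "outcome", "grade_group",
            "pct_highest_grade")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  doses <- allele_dose(table, threshold = threshold)
  patients <- unique(annotation$patient_id)
  rows <- lapply(patients, function(p) {
    ann <- annotation[annotation$patient_id == p, ]
    rep_id <- select_representative_biopsy(data.frame(
      biopsy_id = ann$sample_id, grade_group = ann$grade_group,
      pct_highest_grade = ann$pct_highest_grade, stringsAsFactors = FALSE))
    d <- doses[doses$sample_id == rep_id, ]
    if (nrow(d) == 0) {
      stop("no allele calls for designated sample ", rep_id,
           " of patient ", p)
    }
    data.frame(patient_id = p, sample_id = rep_id, a_count = d$a_count,
               positive = d$positive, outcome = ann$outcome[1],
               stringsAsFactors = FALSE)
  })
  per_patient <- do.call(rbind, rows)
  is_bcr <- per_patient$outcome == "BCR"
  pos <- per_patient$positive
  confusion <- c(TP = sum(pos & is_bcr), FP = sum(pos & !is_bcr),
                 TN = sum(!pos & !is_bcr), FN = sum(!pos & is_bcr))
  list(per_patient = per_patient, confusion = confusion,
       sensitivity = unname(confusion["TP"] / sum(is_bcr)),
       specificity = unname(confusion["TN"] / sum(!is_bcr)),
       threshold = threshold)
}
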