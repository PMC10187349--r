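#' Condition labels of the six-arm co-culture experiment
#'
#' The derivation contrast compares TGF-beta-stimulated LNCaP/HPS-19I
#' co-culture against five equally weighted negative conditions: vehicle
#' co-culture, co-culture with the TGF-beta receptor inhibitor SD-208 (with
#' and without stimulation), and stroma alone (with and without stimulation).
#'
#' @return Character vector of the six condition labels; the first element is
#'   the positive (stimulated co-culture) condition.
#' @export
coculture_conditions <- function() {
  c("cocult_tgfb", "cocult_vehicle", "cocult_tgfb_sd208",
    "cocult_sd208", "stroma_tgfb", "stroma_vehicle")
}

# One global seed expands to fixed per-stream seeds so adding a stream never
# perturbs draws of earlier streams.
.stream_offsets <- c(
  genes = 1L, planted = 2L, noise = 3L, patients = 4L, biopsies = 5L,
  intercepts = 6L, residuals = 7L, grades = 8L, volumes = 9L,
  alleles = 10L, psa = 11L
)

stream_seed <- function(seed, stream) {
  offset <- .stream_offsets[[stream]]
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483629)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, stream))
  expr
}

#' Configuration for the synthetic co-culture experiment
#'
#' @param n_genes Number of genes simulated.
#' @param n_replicates Replicates per condition (the source arrays do not
#'   state a replicate count; 3 is the default).
#' @param n_planted Number of genes planted as truly TGF-beta-responsive in
#'   the stimulated co-culture condition only.
#' @param planted_log2fc Planted effect, log2 units, added in `cocult_tgfb`.
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `coculture_config` list.
#' @export
coculture_config <- function(n_genes = 200, n_replicates = 3, n_planted = 6,
                             planted_log2fc = 2, noise_sd = 0.5, seed = 1) {
  if (n_planted > n_genes) {
    stop("`n_planted` (", n_planted, ") exceeds `n_genes` (", n_genes, ")")
  }
  if (n_planted > 0 && planted_log2fc <= 0) stop("`planted_log2fc` must be > 0")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  structure(
    list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
         n_planted = as.integer(n_planted), planted_log2fc = planted_log2fc,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "coculture_config"
  )
}

#' Simulate the six-condition co-culture expression experiment
#'
#' Gene baselines are drawn once from Normal(8, 2) on the log2 scale
#' (RMA-like intensities). Planted genes are elevated by `planted_log2fc`
#' only in the stimulated co-culture condition; every other cell is i.i.d.
#' Gaussian noise around the gene baseline.
#'
#' @param config A [coculture_config()].
#' @return A list with `expr` (genes x samples matrix), `conditions`
#'   (data.frame of sample_id, condition) and `truth` (planted genes,
#'   planted effect, baselines).
#' @export
simulate_coculture <- function(config = coculture_config()) {
  stopifnot(inherits(config, "coculture_config"))
  conds <- coculture_conditions()
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  samples <- paste(rep(conds, each = config$n_replicates),
                   rep(seq_len(config$n_replicates), times = length(conds)),
                   sep = "_r")
  condition <- rep(conds, each = config$n_replicates)

  mu <- with_stream(config$seed, "genes",
                    stats::rnorm(config$n_genes, mean = 8, sd = 2))
  planted <- if (config$n_planted > 0) {
    sort(with_stream(config$seed, "planted",
                     sample(genes, config$n_planted)))
  } else character(0)

  expr <- matrix(mu, nrow = config$n_genes, ncol = length(samples),
                 dimnames = list(genes, samples))
  expr[planted, condition == "cocult_tgfb"] <-
    expr[planted, condition == "cocult_tgfb"] + config$planted_log2fc
  expr <- expr + with_stream(config$seed, "noise",
                             matrix(stats::rnorm(length(expr), sd = config$noise_sd),
                                    nrow = nrow(expr)))

  list(
    expr = expr,
    conditions = data.frame(sample_id = samples, condition = condition,
                            stringsAsFactors = FALSE),
    truth = list(planted_genes = planted, planted_log2fc = config$planted_log2fc,
                 baselines = stats::setNames(mu, genes))
  )
}

#' Configuration for the synthetic patient cohort
#'
#' Emulates the repeated-biopsy radiotherapy cohort: ~29 patients with 1-4
#' MRI-targeted biopsies each, a rare biochemical-recurrence (BCR) outcome
#' assigned at the patient level, patient random intercepts, and a planted
#' expression effect on signature genes in BCR patients.
#'
#' @param n_patients Number of patients.
#' @param biopsy_range Integer range (min, max) of biopsies per patient,
#'   drawn uniformly.
#' @param bcr_fraction Per-patient probability of BCR.
#' @param n_genes Number of genes.
#' @param signature_genes Character vector of genes carrying the planted
#'   outcome effect; `NULL` plants `n_signature` genes chosen at random.
#' @param n_signature Number of genes planted when `signature_genes` is NULL.
#' @param signature_effect Log2 expression shift added to signature genes in
#'   samples of BCR patients.
#' @param patient_sd Random-intercept SD (sigma_u), shared by all biopsies of
#'   a patient, per gene.
#' @param residual_sd Residual SD (sigma_e) per sample, per gene.
#' @param volume_meanlog,volume_sdlog Lognormal parameters (cm^3) of baseline
#'   lesion volume, named per outcome group (`ned`, `bcr`); BCR tumors are
#'   larger at the median.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 29, biopsy_range = c(1, 4),
                          bcr_fraction = 0.17, n_genes = 200,
                          signature_genes = NULL, n_signature = 6,
                          signature_effect = 1, patient_sd = 0.5,
                          residual_sd = 0.5,
                          volume_meanlog = c(ned = 0.7, bcr = 1.8),
                          volume_sdlog = 0.8, seed = 1) {
  if (bcr_fraction <= 0 || bcr_fraction >= 1) stop("`bcr_fraction` must be in (0, 1)")
  if (patient_sd < 0) stop("`patient_sd` must be >= 0")
  if (residual_sd <= 0) stop("`residual_sd` must be > 0")
  stopifnot(length(biopsy_range) == 2, biopsy_range[1] >= 1,
            biopsy_range[2] >= biopsy_range[1])
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(signature_genes) && !all(signature_genes %in% genes)) {
    stop("every signature gene must be among the ", n_genes, " simulated genes")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         biopsy_range = as.integer(biopsy_range),
         bcr_fraction = bcr_fraction, n_genes = as.integer(n_genes),
         signature_genes = signature_genes, n_signature = as.integer(n_signature),
         signature_effect = signature_effect, patient_sd = patient_sd,
         residual_sd = residual_sd, volume_meanlog = volume_meanlog,
         volume_sdlog = volume_sdlog, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate the repeated-biopsy patient cohort
#'
#' Per-sample expression follows the random-intercept model
#' `y_gij = mu_g + beta_g * BCR_i + u_gi + e_gij`, with `u_gi ~ N(0, sigma_u^2)`
#' shared across a patient's biopsies and `e ~ N(0, sigma_e^2)`; `beta_g`
#' equals `signature_effect` for signature genes and 0 otherwise. Outcome is
#' assigned per patient and shared by all of that patient's biopsies. The
#' annotation also carries Gleason grade group, percent highest-grade pattern
#' (for representative-core selection) and lognormal lesion volumes drawn per
#' outcome group.
#'
#' @param config A [cohort_config()].
#' @return A list with `expr` (genes x samples), `annotation` (one row per
#'   biopsy sample) and `truth` (planted effects, random intercepts, outcome
#'   labels).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  patients <- sprintf("P%03d", seq_len(config$n_patients))

  bcr <- with_stream(config$seed, "patients",
                     stats::rbinom(config$n_patients, 1, config$bcr_fraction) == 1)
  if (!any(bcr)) {
    stop("no BCR patient drawn at bcr_fraction = ", config$bcr_fraction,
         "; increase `n_patients` or the fraction")
  }
  if (all(bcr)) stop("all patients drew BCR; decrease `bcr_fraction`")

  rng <- seq(config$biopsy_range[1], config$biopsy_range[2])
  n_biops <- if (length(rng) == 1) {
    rep(rng, config$n_patients)
  } else {
    with_stream(config$seed, "biopsies",
                sample(rng, config$n_patients, replace = TRUE))
  }
  patient_of <- rep(patients, times = n_biops)
  sample_id <- paste0(patient_of, "_B", unlist(lapply(n_biops, seq_len)))
  n_samples <- length(sample_id)

  sig_genes <- config$signature_genes
  if (is.null(sig_genes)) {
    sig_genes <- sort(with_stream(config$seed, "planted",
                                  sample(genes, config$n_signature)))
  }
  beta <- stats::setNames(rep(0, config$n_genes), genes)
  beta[sig_genes] <- config$signature_effect

  mu <- with_stream(config$seed, "genes",
                    stats::rnorm(config$n_genes, mean = 8, sd = 2))
  u <- with_stream(config$seed, "intercepts",
                   matrix(stats::rnorm(config$n_genes * config$n_patients,
                                       sd = config$patient_sd),
                          nrow = config$n_genes,
                          dimnames = list(genes, patients)))
  eps <- with_stream(config$seed, "residuals",
                     matrix(stats::rnorm(config$n_genes * n_samples,
                                         sd = config$residual_sd),
                            nrow = config$n_genes))

  bcr_of_sample <- bcr[match(patient_of, patients)]
  expr <- mu + outer(beta, as.numeric(bcr_of_sample)) +
    u[, patient_of, drop = FALSE] + eps
  dimnames(expr) <- list(genes, sample_id)

  grades <- with_stream(config$seed, "grades", {
    gg <- sample(1:5, n_samples, replace = TRUE,
                 prob = c(0.05, 0.10, 0.10, 0.40, 0.35))
    pct <- round(stats::runif(n_samples, 10, 100))
    list(gg = gg, pct = pct)
  })
  volumes <- with_stream(config$seed, "volumes", {
    ml <- ifelse(bcr, config$volume_meanlog[["bcr"]], config$volume_meanlog[["ned"]])
    base <- stats::rlnorm(config$n_patients, meanlog = ml, sdlog = config$volume_sdlog)
    post <- base * stats::runif(config$n_patients, 0.05, 0.6)
    list(base = base, post = post)
  })

  annotation <- data.frame(
    sample_id = sample_id,
    patient_id = patient_of,
    lesion_id = paste0(patient_of, "_L1"),
    outcome = ifelse(bcr_of_sample, "BCR", "NED"),
    grade_group = grades$gg,
    pct_highest_grade = grades$pct,
    volume_baseline = volumes$base[match(patient_of, patients)],
    volume_post = volumes$post[match(patient_of, patients)],
    stringsAsFactors = FALSE
  )

  list(
    expr = expr,
    annotation = annotation,
    truth = list(signature_genes = sig_genes, planted_effects = beta,
                 random_intercepts = u,
                 outcomes = stats::setNames(ifelse(bcr, "BCR", "NED"), patients),
                 baselines = stats::setNames(mu, genes))
  )
}

#' Configuration for synthetic PTEN/TP53 allele calls
#'
#' `probs_bcr` and `probs_ned` give the outcome-conditional distribution of
#' the total altered-allele count A in 0..4 across PTEN and TP53. The default
#' places no NED mass at A >= 3 (the 3-allele rule is then perfectly specific
#' by construction) while enriching BCR samples at 3-4 alleles; set
#' `probs_bcr = probs_ned` to switch enrichment off.
#'
#' @param probs_bcr,probs_ned Length-5 probability vectors over A = 0..4.
#' @param p_copy_loss Probability that a single allele hit is a copy loss
#'   rather than an oncogenic mutation.
#' @param seed Integer seed.
#' @return An `allele_config` list.
#' @export
allele_config <- function(probs_bcr = c(0.05, 0.10, 0.15, 0.35, 0.35),
                          probs_ned = c(0.50, 0.30, 0.20, 0, 0),
                          p_copy_loss = 0.6, seed = 1) {
  stopifnot(length(probs_bcr) == 5, length(probs_ned) == 5,
            all(probs_bcr >= 0), all(probs_ned >= 0))
  structure(
    list(probs_bcr = probs_bcr / sum(probs_bcr),
         probs_ned = probs_ned / sum(probs_ned),
         p_copy_loss = p_copy_loss, seed = as.integer(seed)),
    class = "allele_config"
  )
}

#' Simulate per-sample PTEN/TP53 allele-call tables
#'
#' Draws each sample's intended altered-allele count A from the
#' outcome-conditional distribution in `config`, then distributes the hits
#' over the four tumor-suppressor alleles (two per gene), splitting each
#' gene's hits into copy losses and oncogenic mutations.
#'
#' @param config An [allele_config()].
#' @param annotation Cohort annotation with `sample_id`, `patient_id`,
#'   `outcome` columns (see [simulate_cohort()]).
#' @return A data.frame with one row per (sample, gene in PTEN/TP53):
#'   `copies_lost` in 0..2 and `oncogenic_mutation_count`; the intended A per
#'   sample is attached as attribute `truth`.
#' @export
simulate_allele_calls <- function(config, annotation) {
  stopifnot(inherits(config, "allele_config"),
            all(c("sample_id", "patient_id", "outcome") %in% names(annotation)))
  n <- nrow(annotation)
  with_stream(config$seed, "alleles", {
    a <- vapply(annotation$outcome, function(o) {
      p <- if (o == "BCR") config$probs_bcr else config$probs_ned
      sample(0:4, 1, prob = p)
    }, integer(1), USE.NAMES = FALSE)
    rows <- lapply(seq_len(n), function(i) {
      slots <- sample(4, a[i])  # 1-2 = PTEN alleles, 3-4 = TP53 alleles
      per_gene <- c(PTEN = sum(slots <= 2), TP53 = sum(slots > 2))
      cl <- stats::rbinom(2, per_gene, config$p_copy_loss)
      data.frame(sample_id = annotation$sample_id[i],
                 patient_id = annotation$patient_id[i],
                 gene = c("PTEN", "TP53"),
                 copies_lost = as.integer(cl),
                 oncogenic_mutation_count = as.integer(per_gene - cl),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(sample_id = annotation$sample_id,
                                     intended_alleles = as.integer(a),
                                     outcome = annotation$outcome,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Configuration for synthetic post-treatment PSA trajectories
#'
#' @param followup_months Length of follow-up.
#' @param interval_months Sampling interval of PSA measurements.
#' @param start_meanlog,start_sdlog Lognormal parameters of the pretreatment
#'   PSA (ng/mL); default median ~13.5 ng/mL.
#' @param decline_months Months from treatment start to the nadir.
#' @param nadir_range Uniform range of the post-treatment nadir (ng/mL).
#' @param crossing_range Range (months) in which a BCR patient's PSA crosses
#'   nadir + 2 ng/mL; the planted crossing lands on a measurement time.
#' @param doubling_months PSA doubling time during biochemical relapse.
#' @param noise_sd Measurement noise SD (ng/mL); clipped at +/- 0.5 so NED
#'   trajectories can never drift across the Phoenix threshold.
#' @param seed Integer seed.
#' @return A `psa_config` list.
#' @export
psa_config <- function(followup_months = 60, interval_months = 3,
                       start_meanlog = log(13.5), start_sdlog = 0.5,
                       decline_months = 12, nadir_range = c(0.05, 0.5),
                       crossing_range = c(24, 48), doubling_months = 6,
                       noise_sd = 0.05, seed = 1) {
  stopifnot(noise_sd >= 0, followup_months > decline_months,
            crossing_range[1] > decline_months,
            crossing_range[2] <= followup_months)
  structure(
    list(followup_months = followup_months, interval_months = interval_months,
         start_meanlog = start_meanlog, start_sdlog = start_sdlog,
         decline_months = decline_months, nadir_range = nadir_range,
         crossing_range = crossing_range, doubling_months = doubling_months,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "psa_config"
  )
}

#' Simulate post-treatment PSA series with planted Phoenix crossings
#'
#' NED patients decline log-linearly to a nadir and stay there with small
#' clipped noise, never reaching nadir + 2 ng/mL. BCR patients decline, then
#' regrow exponentially so that PSA equals exactly nadir + 2 at the planted
#' crossing time (a measurement time); with `noise_sd = 0` the Phoenix caller
#' recovers the planted time exactly.
#'
#' @param annotation Cohort annotation (or any data.frame with `patient_id`
#'   and `outcome`); one trajectory per unique patient.
#' @param config A [psa_config()].
#' @return A data.frame (patient_id, time_months, psa_ng_ml) with attribute
#'   `truth` (per-patient nadir and planted crossing time, NA for NED).
#' @export
simulate_psa_series <- function(annotation, config = psa_config()) {
  stopifnot(inherits(config, "psa_config"),
            all(c("patient_id", "outcome") %in% names(annotation)))
  pts <- unique(annotation[, c("patient_id", "outcome")])
  if (anyDuplicated(pts$patient_id)) stop("conflicting outcomes within a patient")
  times <- seq(0, config$followup_months, by = config$interval_months)
  grid_cross <- times[times >= config$crossing_range[1] &
                        times <= config$crossing_range[2]]

  with_stream(config$seed, "psa", {
    out <- lapply(seq_len(nrow(pts)), function(i) {
      psa0 <- stats::rlnorm(1, config$start_meanlog, config$start_sdlog)
      nadir <- stats::runif(1, config$nadir_range[1], config$nadir_range[2])
      is_bcr <- pts$outcome[i] == "BCR"
      t_cross <- if (!is_bcr) NA_real_ else if (length(grid_cross) == 1) {
        grid_cross
      } else {
        sample(grid_cross, 1)
      }

      decline <- times <= config$decline_months
      v <- numeric(length(times))
      v[decline] <- exp(log(psa0) + (log(nadir) - log(psa0)) *
                          times[decline] / config$decline_months)
      v[!decline] <- nadir
      if (is_bcr) {
        grow <- !decline & times > config$decline_months
        v[grow] <- nadir + 2 * 2^((times[grow] - t_cross) / config$doubling_months)
        # keep pre-relapse values at the nadir until regrowth is appreciable
        v[grow] <- pmax(v[grow], nadir)
      }
      if (config$noise_sd > 0) {
        noise <- pmax(pmin(stats::rnorm(length(times), sd = config$noise_sd), 0.5), -0.5)
        v <- pmax(v + noise, 0.01)
      }
      list(df = data.frame(patient_id = pts$patient_id[i], time_months = times,
                           psa_ng_ml = v, stringsAsFactors = FALSE),
           truth = data.frame(patient_id = pts$patient_id[i],
                              outcome = pts$outcome[i], nadir = nadir,
                              planted_crossing = t_cross,
                              stringsAsFactors = FALSE))
    })
    series <- do.call(rbind, lapply(out, `[[`, "df"))
    rownames(series) <- NULL
    attr(series, "truth") <- do.call(rbind, lapply(out, `[[`, "truth"))
    series
  })
}
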