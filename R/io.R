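#' Read a gene expression matrix from TSV or GCT
#'
#' Plain TSV has the gene identifier in the first column and sample IDs in
#' the header. GCT v1.2 (`#1.2` first line, `rows<TAB>cols` second line,
#' Name/Description columns) is detected automatically and its declared
#' dimensions are checked. Gene identifiers are upper-cased; duplicates and
#' non-finite or non-numeric cells are rejected with coordinates.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#1.2")) {
    lines <- readLines(path)
    dims <- as.integer(strsplit(lines[2], "\t")[[1]])
    df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || ncol(df) - 2 != dims[2]) {
      stop("GCT declares ", dims[1], " x ", dims[2], " but file has ",
           nrow(df), " x ", ncol(df) - 2)
    }
    genes <- toupper(df[[1]])
    vals <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- toupper(df[[1]])
    vals <- df[, -1, drop = FALSE]
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric value at gene ", genes[bad], " (row ", bad,
           "), sample column '", names(vals)[j], "'")
    }
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite value at gene ", genes[idx[1]], ", sample column '",
         colnames(m)[idx[2]], "'")
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV or GCT
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path Output path.
#' @param format "tsv" (default) or "gct" (v1.2).
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    df <- data.frame(Name = rownames(expr), Description = "na", expr,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path: per line, set name, description, then tab-separated
#'   genes (order preserved, upper-cased).
#' @return Named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  names_ <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) {
    g <- toupper(p[-(1:2)])
    g <- g[nzchar(g)]
    if (length(g) == 0) stop("gene set '", p[1], "' has no genes")
    g
  })
  names(sets) <- names_
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
                           character(1)), names_)
  sets
}

#' Write a signature (or named gene-set list) as GMT
#'
#' @param x A `gene_signature` or named list of character vectors.
#' @param path Output path.
#' @param description Description field, recycled over sets.
#' @export
write_gmt <- function(x, path, description = "tgfbsig") {
  sets <- if (inherits(x, "gene_signature")) {
    stats::setNames(list(x$genes), "TGFB_PCA_SIGNATURE")
  } else x
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble an allele-call table from mutation and copy-number files
#'
#' The mutation TSV carries MAF-subset columns (Tumor_Sample_Barcode,
#' Hugo_Symbol, oncogenic); only mutations flagged "Oncogenic" or
#' "Likely Oncogenic" (case-insensitive; logical TRUE also accepted) are
#' counted. The copy TSV carries gene-level copies_lost per sample
#' (sample_id, gene, copies_lost). Rows are joined per (sample, gene);
#' absent rows default to unaltered; genes other than PTEN/TP53 are dropped
#' with a warning.
#'
#' @param mutation_path,copy_path File paths; either may point to a
#'   header-only (empty) table.
#' @param samples Optional sample universe; defaults to samples seen in
#'   either file.
#' @return Allele-call table: sample_id, gene, copies_lost,
#'   oncogenic_mutation_count.
#' @export
read_allele_calls <- function(mutation_path, copy_path, samples = NULL) {
  muts <- utils::read.delim(mutation_path, stringsAsFactors = FALSE)
  cns <- utils::read.delim(copy_path, stringsAsFactors = FALSE)
  if (nrow(muts) > 0) {
    need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "oncogenic")
    if (!all(need %in% names(muts))) {
      stop("mutation table needs columns: ", paste(need, collapse = ", "))
    }
    muts$Hugo_Symbol <- toupper(muts$Hugo_Symbol)
    drop <- !muts$Hugo_Symbol %in% tumor_suppressors
    if (any(drop)) {
      warning("dropping ", sum(drop), " mutation row(s) outside PTEN/TP53")
      muts <- muts[!drop, , drop = FALSE]
    }
    onc <- if (is.logical(muts$oncogenic)) muts$oncogenic else
      tolower(muts$oncogenic) %in% c("oncogenic", "likely oncogenic", "true")
    muts <- muts[onc, , drop = FALSE]
  }
  if (nrow(cns) > 0) {
    need <- c("sample_id", "gene", "copies_lost")
    if (!all(need %in% names(cns))) {
      stop("copy-number table needs columns: ", paste(need, collapse = ", "))
    }
    cns$gene <- toupper(cns$gene)
    drop <- !cns$gene %in% tumor_suppressors
    if (any(drop)) {
      warning("dropping ", sum(drop), " copy-number row(s) outside PTEN/TP53")
      cns <- cns[!drop, , drop = FALSE]
    }
    if (anyDuplicated(cns[, c("sample_id", "gene")])) {
      stop("duplicate (sample, gene) copy-number rows")
    }
  }
  if (is.null(samples)) {
    samples <- sort(unique(c(
      if (nrow(muts) > 0) muts$Tumor_Sample_Barcode else character(0),
      if (nrow(cns) > 0) cns$sample_id else character(0))))
  }
  out <- expand.grid(sample_id = samples, gene = tumor_suppressors,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$gene), ]
  key <- function(s, g) paste(s, g, sep = "\r")
  mut_count <- if (nrow(muts) > 0) {
    table(key(muts$Tumor_Sample_Barcode, muts$Hugo_Symbol))
  } else table(character(0))
  k <- key(out$sample_id, out$gene)
  out$copies_lost <- 0L
  if (nrow(cns) > 0) {
    m <- match(k, key(cns$sample_id, cns$gene))
    out$copies_lost[!is.na(m)] <- as.integer(cns$copies_lost[m[!is.na(m)]])
  }
  out$oncogenic_mutation_count <- as.integer(mut_count[k])
  out$oncogenic_mutation_count[is.na(out$oncogenic_mutation_count)] <- 0L
  rownames(out) <- NULL
  validate_allele_rows(out)
}

#' Pipeline run configuration with the study defaults
#'
#' Thresholds default to the derivation and classification constants used
#' throughout: candidate FDR 0.1, DE p 0.05, 2-fold change (log2 = 1),
#' allele cutpoint 3, ssGSEA tau 0.25, signature search start 3, volume
#' pseudocount 0.1.
#'
#' @param ... Overrides for any default field.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L, fdr_threshold = 0.1, p_threshold = 0.05,
    fc_threshold_log2 = 1, allele_threshold = 3, tau = 0.25, n_start = 3,
    normalize_scores = TRUE, allow_missing_genes = FALSE, pseudocount = 0.1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  # canonical types so a JSON round trip is identical
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("fdr_threshold", "p_threshold", "fc_threshold_log2",
              "allele_threshold", "tau", "n_start", "pseudocount")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
  }
  for (f in c("normalize_scores", "allow_missing_genes")) {
    cfg[[f]] <- as.logical(cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON (identical round trip)
#'
#' @param path JSON path.
#' @return `read_config` returns a `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a sample annotation, allele or PSA table as TSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_table_tsv()]
#'
#' @param path Input path.
#' @return Data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
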