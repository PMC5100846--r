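# Reproducible end-to-end runs. Each run_* function executes one stage
# of the pipeline over files or in-memory objects, writes plain-text
# outputs (TSV) plus a JSON manifest recording the configuration and
# seeds, and returns its results invisibly for interactive use.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

write_manifest <- function(out_dir, stage, config) {
  manifest <- list(
    stage = stage,
    package = "mrnadecay",
    version = as.character(utils::packageVersion("mrnadecay")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Compute sequence features for a FASTA file
#'
#' Reads coding sequences, computes the full feature table, and writes
#' `features.tsv`, `rejects.tsv`, and `manifest.json` into `out_dir`.
#'
#' @param fasta Path to a FASTA file of coding sequences.
#' @param usage_counts Named codon count vector, or path to a 2-column
#'   TSV (codon, count).
#' @param nte_weights Named nTE weight vector, or path to a 2-column TSV.
#' @param out_dir Output directory (created if needed).
#' @param pseudo_count Passed to [relative_adaptiveness()].
#' @return Invisibly, list with `features` and `rejects` data frames.
#' @export
run_features <- function(fasta, usage_counts, nte_weights, out_dir,
                         pseudo_count = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(usage_counts)) usage_counts <- read_codon_table(usage_counts)
  if (is.character(nte_weights)) nte_weights <- read_codon_table(nte_weights)
  parsed <- read_coding_fasta(fasta)
  usage <- relative_adaptiveness(usage_counts, pseudo_count)
  features <- if (length(parsed$records)) {
    sequence_feature_table(parsed$records, usage, nte_weights)
  } else {
    data.frame(gene_id = character(), coding_length = integer(),
               gc1 = numeric(), gc2 = numeric(), gc3 = numeric(),
               cai = numeric(), nte = numeric(), polyproline = logical())
  }
  write_tsv(features, file.path(out_dir, "features.tsv"))
  write_tsv(parsed$rejects, file.path(out_dir, "rejects.tsv"))
  write_manifest(out_dir, "features",
                 list(fasta = fasta, pseudo_count = pseudo_count,
                      n_records = length(parsed$records),
                      n_rejects = nrow(parsed$rejects)))
  if (length(parsed$records) == 0L) {
    warning("no valid coding sequences in ", fasta, call. = FALSE)
  }
  invisible(list(features = features, rejects = parsed$rejects))
}

#' Run the full regression stage on a predictor table
#'
#' Applies the Tukey-fence filter to the response, screens predictors,
#' builds the reduced model with the chosen stepwise procedure, extends
#' it with categorical indicators when annotations are given, flags
#' residual outliers, and writes the variance-decomposition report, the
#' predicted-vs-measured scatter data, and a JSON decision log.
#'
#' @param table A `predictor_table`.
#' @param out_dir Output directory.
#' @param annotations Optional long annotation data frame (`gene_id`,
#'   `label`).
#' @param alpha Significance threshold (default 0.05).
#' @param procedure "backward" (default), "forward", or "aic".
#' @param iqr_factor Fence multiplier for the response filter.
#' @param min_prevalence Passed to [model_plus_plus()].
#' @return Invisibly, list with `screen`, `model`, `model_pp`,
#'   `outliers`, `summary`, `filter`.
#' @export
run_model <- function(table, out_dir, annotations = NULL, alpha = 0.05,
                      procedure = c("backward", "forward", "aic"),
                      iqr_factor = 1.5, min_prevalence = 10L) {
  procedure <- match.arg(procedure)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_in <- sum(!is.na(table$response))
  filtered <- filter_response(table, factor = iqr_factor)
  flt <- attr(filtered, "filter")
  message(sprintf("response filter: %d genes in, %d excluded (%.2f%%), %d modeled",
                  n_in, length(flt$excluded), 100 * flt$excluded_fraction,
                  length(filtered$genes)))
  screen <- univariate_screen(filtered)
  model <- switch(procedure,
    backward = backward_stepwise(filtered, alpha, screen),
    forward = forward_stepwise(filtered, alpha, screen),
    aic = aic_reduce(filtered, screen$predictor[screen$p_value < alpha])
  )
  model_pp <- if (!is.null(annotations)) {
    model_plus_plus(filtered, model, annotations, min_prevalence)
  }
  outliers <- residual_outliers(model, filtered)
  summ <- variance_summary(screen, model, model_pp, filtered)
  write_tsv(screen, file.path(out_dir, "screen.tsv"))
  write_tsv(summ$table, file.path(out_dir, "variance_summary.tsv"))
  write_tsv(summ$scatter, file.path(out_dir, "predicted_vs_measured.tsv"))
  write_tsv(data.frame(gene_id = outliers$genes),
            file.path(out_dir, "residual_outliers.tsv"))
  jsonlite::write_json(
    list(procedure = procedure, alpha = alpha,
         steps = as.list(attr(model, "steps")),
         terms = model$terms,
         excluded_by_filter = length(flt$excluded),
         excluded_fraction = flt$excluded_fraction),
    file.path(out_dir, "decision_log.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "model",
                 list(alpha = alpha, procedure = procedure,
                      iqr_factor = iqr_factor,
                      min_prevalence = min_prevalence,
                      n_genes_in = n_in,
                      n_genes_modeled = length(filtered$genes)))
  invisible(list(screen = screen, model = model, model_pp = model_pp,
                 outliers = outliers, summary = summ, filter = flt))
}

#' Run the qPCR decay stage on a Ct table
#'
#' @param ct_table Data frame (`gene`, `time`, `replicate`, `ct_gene`,
#'   `ct_ref`) or path to such a CSV/TSV file.
#' @param out_dir Output directory.
#' @param convention Delta-Ct convention, see [relative_abundance()].
#' @param n_boot,seed Passed to [qpcr_pipeline()].
#' @return Invisibly, the [qpcr_pipeline()] result.
#' @export
run_qpcr <- function(ct_table, out_dir, convention = "standard",
                     n_boot = 1000L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(ct_table)) {
    sep <- if (grepl("\\.csv$", ct_table)) "," else "\t"
    ct_table <- read.delim(ct_table, sep = sep)
  }
  res <- qpcr_pipeline(ct_table, convention, n_boot, seed)
  write_tsv(res$fit_table, file.path(out_dir, "decay_fits.tsv"))
  band <- do.call(rbind, lapply(res$fits, function(f) {
    cbind(gene = f$gene, f$band)
  }))
  write_tsv(band, file.path(out_dir, "ci_bands.tsv"))
  if (!is.null(res$comparisons)) {
    write_tsv(res$comparisons, file.path(out_dir, "comparisons.tsv"))
  }
  write_tsv(res$aggregated, file.path(out_dir, "aggregated.tsv"))
  write_manifest(out_dir, "qpcr",
                 list(convention = convention, n_boot = n_boot, seed = seed,
                      genes = sort(unique(ct_table$gene))))
  invisible(res)
}
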