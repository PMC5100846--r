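# Synthetic-data generators with known ground truth: coding sequences
# with controlled GC3 and planted poly-proline runs, predictor tables
# with known linear structure on the transformed scale, categorical
# group effects, and shutoff qPCR Ct time courses from known decay
# constants. Every generator is a pure function of its arguments plus
# the seed: identical inputs give identical outputs.

#' Default predictor specification for the synthetic generator
#'
#' Names, transformations, and transformed-scale location/scale for a
#' yeast-like predictor set: coding length around 10^3.1 nt, TPM-scale
#' abundance, ribosome density (RPKM-like), positional GC proportions,
#' CAI around 0.15, nTE near 1, transcript folding energy in kcal/mol,
#' and protein half-life in minutes.
#'
#' @return Data frame with columns `name`, `transform`, `mean`, `sd`
#'   (mean/sd on the transformed scale).
#' @export
default_predictor_spec <- function() {
  data.frame(
    name = c("coding_length", "utr5_length", "abundance", "ribosome_density",
             "gc2", "gc3", "cai", "nte", "dg", "protein_halflife"),
    transform = c("log10", "log10_plus1", "log10", "log10_plus1",
                  "none", "none", "log10", "none", "none", "log10"),
    mean = c(3.1, 1.8, 1.0, 1.1, 0.38, 0.40, -0.82, 1.00, -150, 1.6),
    sd = c(0.25, 0.45, 0.60, 0.40, 0.04, 0.06, 0.12, 0.15, 60, 0.40)
  )
}

#' Default true coefficients for the synthetic generator
#'
#' Effects in response units (min^-1) per 1-SD change of the transformed
#' predictor. Signs follow the biology being emulated: longer transcripts
#' degrade faster; densely translated, codon-optimized, GC3-rich
#' transcripts degrade more slowly; less negative folding energy (weaker
#' structure) associates with faster decay.
#'
#' @return Named numeric vector of per-SD effects.
#' @export
default_beta <- function() {
  c(coding_length = 0.018, ribosome_density = -0.012, cai = -0.010,
    gc3 = -0.008, nte = -0.006, dg = 0.008)
}

#' Generate a synthetic predictor table with known linear structure
#'
#' Predictors are multivariate normal on the transformed scale with the
#' given correlation matrix, then back-transformed to original units per
#' their declared transformation. The response is
#' k = intercept + sum(beta_j * z_j) + Normal(0, sigma), where z_j is the
#' standardized transformed predictor, so `beta` is expressed per
#' predictor SD. Exactly one of `sigma` and `target_r_squared` must be
#' given; with a target R^2, sigma is solved from the realized signal
#' variance so the expected model R^2 matches the target.
#'
#' @param n_genes Number of genes (default 4000, the typical
#'   complete-case scale of genome-wide yeast datasets).
#' @param seed Integer RNG seed.
#' @param predictors Specification data frame as from
#'   [default_predictor_spec()].
#' @param beta Named vector of true per-SD effects; predictors absent
#'   from `beta` have no effect.
#' @param intercept Mean response, min^-1 (default 0.12).
#' @param sigma Residual SD of the response, or NULL.
#' @param target_r_squared Target model R^2, or NULL.
#' @param correlation Optional correlation matrix (predictor order of
#'   `predictors`); identity when NULL.
#' @return List with `table` (a `predictor_table`) and `truth` (list:
#'   `beta_sd` per-SD effects, `beta_transformed` slopes on the
#'   transformed scale, `intercept_transformed`, `sigma`, `signal_sd`,
#'   `target_r_squared`, `seed`).
#' @export
sim_predictor_table <- function(n_genes = 4000L, seed,
                                predictors = default_predictor_spec(),
                                beta = default_beta(),
                                intercept = 0.12,
                                sigma = NULL,
                                target_r_squared = 0.43,
                                correlation = NULL) {
  stopifnot(!missing(seed))
  if (is.null(sigma) == is.null(target_r_squared)) {
    stop("exactly one of sigma and target_r_squared must be set", call. = FALSE)
  }
  extra <- setdiff(names(beta), predictors$name)
  if (length(extra)) {
    stop("beta names not in predictor spec: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  p <- nrow(predictors)
  if (is.null(correlation)) correlation <- diag(p)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("correlation matrix must be positive-definite", call. = FALSE)
  }
  set.seed(seed)
  Z <- MASS::mvrnorm(n_genes, mu = rep(0, p), Sigma = correlation)
  colnames(Z) <- predictors$name
  b <- setNames(numeric(p), predictors$name)
  b[names(beta)] <- beta
  signal <- drop(Z %*% b)
  signal_sd <- sd(signal)
  if (!is.null(target_r_squared)) {
    stopifnot(target_r_squared > 0, target_r_squared < 1)
    if (signal_sd == 0) {
      stop("cannot solve sigma for a target R^2 when all effects are zero; ",
           "set sigma directly", call. = FALSE)
    }
    sigma <- signal_sd * sqrt((1 - target_r_squared) / target_r_squared)
  }
  response <- intercept + signal + rnorm(n_genes, 0, sigma)
  genes <- sprintf("g%05d", seq_len(n_genes))
  nonpos <- response <= 0
  if (any(nonpos)) response[nonpos] <- NA_real_
  names(response) <- genes
  sources <- lapply(seq_len(p), function(j) {
    tv <- predictors$mean[j] + predictors$sd[j] * Z[, j]
    setNames(inverse_transform(tv, predictors$transform[j]), genes)
  })
  names(sources) <- predictors$name
  transforms <- setNames(predictors$transform, predictors$name)
  table <- assemble_predictor_table(sources, transforms, response)
  beta_transformed <- setNames(b / predictors$sd, predictors$name)
  truth <- list(
    beta_sd = b,
    beta_transformed = beta_transformed,
    intercept_transformed = intercept -
      sum(beta_transformed * predictors$mean),
    sigma = sigma,
    signal_sd = signal_sd,
    target_r_squared = target_r_squared,
    n_nonphysical = sum(nonpos),
    seed = as.integer(seed)
  )
  list(table = table, truth = truth)
}

#' Add categorical group effects to a synthetic table
#'
#' Assigns each category independently to genes at its stated prevalence
#' (non-exclusive membership, like GO SLIM terms or RNA-binding-protein
#' target sets) and shifts the response of member genes by the category's
#' mean shift.
#'
#' @param sim Output of [sim_predictor_table()].
#' @param seed Integer RNG seed.
#' @param categories Data frame with columns `label`, `prevalence` (in
#'   (0,1)), `shift` (response units, min^-1).
#' @return List with `table` (response shifted), `annotations` (long data
#'   frame `gene_id`, `label`), and `truth` (the category table plus
#'   per-gene memberships).
#' @export
sim_categorical <- function(sim, seed, categories) {
  stopifnot(all(c("label", "prevalence", "shift") %in% names(categories)),
            all(categories$prevalence > 0 & categories$prevalence < 1))
  table <- sim$table
  n <- length(table$genes)
  set.seed(seed)
  ann <- list()
  response <- table$response
  membership <- matrix(FALSE, n, nrow(categories),
                       dimnames = list(table$genes, categories$label))
  for (i in seq_len(nrow(categories))) {
    member <- runif(n) < categories$prevalence[i]
    membership[, i] <- member
    response[member] <- response[member] + categories$shift[i]
    if (any(member)) {
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = table$genes[member], label = categories$label[i])
    }
  }
  table$response <- response
  list(
    table = table,
    annotations = if (length(ann)) do.call(rbind, ann) else
      data.frame(gene_id = character(), label = character()),
    truth = list(categories = categories, membership = membership,
                 seed = as.integer(seed))
  )
}

# Third-position G/C and A/T codon subsets per synonymous family.
.gc3_partition <- function() {
  fams <- codon_families()
  lapply(fams, function(codons) {
    third <- substr(codons, 3L, 3L)
    list(gc = codons[third %in% c("G", "C")],
         at = codons[third %in% c("A", "T")])
  })
}

#' Generate coding sequences with a controlled GC3 target
#'
#' Samples amino acids uniformly and, within each synonymous family,
#' chooses a G/C-ending codon with the tilt probability that makes the
#' expected wobble-position GC content equal `gc3_target`. Each sequence
#' starts with ATG, ends with TAA, and is rejected and redrawn until its
#' realized GC3 (terminal stop excluded) is within `tolerance` of the
#' target. A declared fraction of genes receives a planted run of
#' `min_run` consecutive proline codons; unplanted genes are redrawn if a
#' run arises by chance, so the poly-proline truth is exact.
#'
#' @param n_genes Number of sequences.
#' @param seed Integer RNG seed.
#' @param gc3_target Target wobble-position GC proportion. Feasible range
#'   under uniform amino-acid usage is about \[0.10, 1\] (Met and Trp have
#'   fixed G-ending codons).
#' @param length_meanlog,length_sdlog Log-normal parameters of the
#'   internal codon count (defaults: median 400 codons).
#' @param polyproline_fraction Fraction of genes with a planted run.
#' @param min_run Planted run length (default 4).
#' @param tolerance Per-gene GC3 tolerance (default 0.02).
#' @return List with `records` (list of [coding_sequence()]) and `truth`
#'   (data frame `gene_id`, `gc3`, `polyproline`).
#' @export
sim_cds <- function(n_genes = 50L, seed, gc3_target = 0.45,
                    length_meanlog = log(400), length_sdlog = 0.35,
                    polyproline_fraction = 0.1, min_run = 4L,
                    tolerance = 0.02) {
  stopifnot(!missing(seed))
  part <- .gc3_partition()
  has_both <- vapply(part, function(f) length(f$gc) > 0 && length(f$at) > 0,
                     logical(1))
  gc_only <- vapply(part, function(f) length(f$at) == 0, logical(1))
  n_fam <- length(part)
  # expected GC3 = (n_both * p + n_gc_only) / n_fam under uniform AA use
  p_tilt <- (gc3_target * n_fam - sum(gc_only)) / sum(has_both)
  if (p_tilt < 0 || p_tilt > 1) {
    stop(sprintf("gc3_target %.2f outside feasible range [%.2f, %.2f]",
                 gc3_target, sum(gc_only) / n_fam,
                 (sum(gc_only) + sum(has_both)) / n_fam), call. = FALSE)
  }
  set.seed(seed)
  fam_names <- names(part)
  planted <- seq_len(n_genes) <= round(polyproline_fraction * n_genes)
  sample_codon <- function(fam) {
    f <- part[[fam]]
    use_gc <- if (length(f$gc) == 0) FALSE else if (length(f$at) == 0) TRUE
      else runif(1) < p_tilt
    pool <- if (use_gc) f$gc else f$at
    pool[sample.int(length(pool), 1L)]
  }
  records <- vector("list", n_genes)
  gc3_real <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    len <- max(20L, round(rlnorm(1, length_meanlog, length_sdlog)))
    repeat {
      aas <- fam_names[sample.int(n_fam, len, replace = TRUE)]
      codons <- vapply(aas, sample_codon, character(1))
      if (planted[i]) {
        run <- vapply(rep("P", min_run), sample_codon, character(1))
        at <- sample.int(len - 1L, 1L)
        codons <- append(codons, run, after = at)
      }
      cds <- coding_sequence(sprintf("g%05d", i),
                             paste(c("ATG", codons, "TAA"), collapse = ""))
      has_run <- polyproline_class(cds, min_run)
      gc3 <- gc_by_codon_position(cds)[["gc3"]]
      if (has_run == planted[i] && abs(gc3 - gc3_target) <= tolerance) {
        records[[i]] <- cds
        gc3_real[i] <- gc3
        break
      }
    }
  }
  truth <- data.frame(
    gene_id = vapply(records, function(r) r$gene_id, character(1)),
    gc3 = gc3_real,
    polyproline = planted
  )
  list(records = records, truth = truth)
}

#' Generate shutoff qPCR Ct time courses from known decay constants
#'
#' True abundance follows A(t) = A0 exp(-k t); the gene Ct rises by one
#' cycle per halving, ct_gene(t) = ct0 + k t / ln(2) + noise, while the
#' reference gene Ct stays at its mean plus the same Gaussian Ct-scale
#' noise (noise on the Ct scale is multiplicative on abundance, matching
#' qPCR practice). Replicates represent independent cultures.
#'
#' @param k_true Named vector of true decay constants per construct,
#'   min^-1 (all > 0). Defaults emulate reporter constructs with
#'   half-lives of roughly 12-28 min.
#' @param seed Integer RNG seed.
#' @param times Sampling times in minutes (must include 0; >= 2 points).
#' @param replicates Biological replicates per construct (default 3).
#' @param ct_noise_sd Gaussian SD on the Ct scale (default 0.2).
#' @param ct0 Mean gene Ct at t = 0 (default 22).
#' @param ref_ct_mean Reference-gene Ct mean (default 15).
#' @return List with `ct_table` (data frame `gene`, `time`, `replicate`,
#'   `ct_gene`, `ct_ref`) and `truth` (named `k_true`, `seed`).
#' @export
sim_qpcr <- function(k_true = c(GFP2 = 0.060, GFP3 = 0.040, GFP4 = 0.025),
                     seed,
                     times = c(0, 5, 10, 15, 20, 30),
                     replicates = 3L, ct_noise_sd = 0.2,
                     ct0 = 22, ref_ct_mean = 15) {
  stopifnot(!missing(seed), all(k_true > 0), length(times) >= 2L,
            0 %in% times)
  if (ct_noise_sd < 0) stop("ct_noise_sd must be non-negative", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(gene = names(k_true), replicate = seq_len(replicates),
                      time = times, stringsAsFactors = FALSE)
  grid <- grid[order(grid$gene, grid$replicate, grid$time), ]
  k <- k_true[grid$gene]
  n <- nrow(grid)
  ct_gene <- ct0 + k * grid$time / log(2) + rnorm(n, 0, ct_noise_sd)
  ct_ref <- ref_ct_mean + rnorm(n, 0, ct_noise_sd)
  ct_table <- data.frame(gene = grid$gene, time = grid$time,
                         replicate = grid$replicate,
                         ct_gene = unname(ct_gene), ct_ref = ct_ref)
  rownames(ct_table) <- NULL
  list(ct_table = ct_table,
       truth = list(k_true = k_true, seed = as.integer(seed)))
}
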