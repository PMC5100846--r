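# Transcriptional-shutoff qRT-PCR decay analysis: delta-Ct relative
# quantification against a reference gene, t = 0 normalization,
# replicate aggregation, log-linear decay fitting, case-resampling
# bootstrap confidence intervals, and between-construct comparison.

#' Relative mRNA level from paired Ct values
#'
#' Delta-Ct quantification against a reference gene measured in the same
#' sample, assuming amplification efficiency 2. Under the standard
#' convention Y = 2^(ct_ref - ct_gene), so a decaying transcript (rising
#' ct_gene) shows decreasing Y. The `as_printed` convention,
#' Y = 2^(ct_gene - ct_ref), is the reciprocal and is provided for
#' compatibility with protocols written that way.
#'
#' @param ct_gene Cycle threshold(s) of the gene of interest.
#' @param ct_ref Cycle threshold(s) of the reference gene.
#' @param convention "standard" (default) or "as_printed".
#' @return Relative level(s) Y.
#' @export
relative_abundance <- function(ct_gene, ct_ref,
                               convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (convention == "standard") 2^(ct_ref - ct_gene) else 2^(ct_gene - ct_ref)
}

#' Normalize a time course to its t = 0 level
#'
#' Divides each replicate's relative levels by that replicate's level at
#' t = 0, which is thereby set to exactly 1.
#'
#' @param df Data frame with columns `gene`, `time`, `replicate`, `y`.
#' @return The data frame with `y` replaced by the normalized level.
#' @export
normalize_to_t0 <- function(df) {
  stopifnot(all(c("gene", "time", "replicate", "y") %in% names(df)))
  key <- interaction(df$gene, df$replicate, drop = TRUE)
  out <- df
  for (k in levels(key)) {
    idx <- which(key == k)
    at0 <- idx[df$time[idx] == 0]
    if (length(at0) == 0L) {
      stop("missing t = 0 observation for gene ", df$gene[idx[1L]],
           ", replicate ", df$replicate[idx[1L]], call. = FALSE)
    }
    out$y[idx] <- df$y[idx] / df$y[at0[1L]]
  }
  out
}

#' Aggregate replicate time courses to mean and SEM
#'
#' @param df Normalized data frame (`gene`, `time`, `replicate`, `y`).
#' @param sem_min_n Minimum replicates for reporting a SEM (default 2;
#'   set to 3 to mirror the reporting convention of showing error bars
#'   only for three or more biological replicates and plain means for
#'   two).
#' @return Data frame with `gene`, `time`, `mean`, `sem`, `n`. SEM is NA
#'   below `sem_min_n` replicates.
#' @export
aggregate_replicates <- function(df, sem_min_n = 2L) {
  stopifnot(all(c("gene", "time", "y") %in% names(df)))
  agg <- aggregate(y ~ gene + time, data = df, FUN = function(v) {
    c(mean = mean(v), sem = if (length(v) > 1L) sd(v) / sqrt(length(v))
      else NA_real_, n = length(v))
  })
  out <- data.frame(gene = agg$gene, time = agg$time,
                    mean = agg$y[, "mean"], sem = agg$y[, "sem"],
                    n = as.integer(agg$y[, "n"]))
  if (sem_min_n > 2L) out$sem[out$n < sem_min_n] <- NA_real_
  out[order(out$gene, out$time), ]
}

# Closed-form slope/intercept of least squares on (x, y); used directly
# so that bootstrap resampling stays cheap.
.ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

#' Fit a first-order decay constant to a normalized time course
#'
#' Unweighted least squares of ln(Y) on time over all points. The decay
#' constant is minus the slope; the half-life is ln(2)/k. A non-positive
#' estimated k (non-decaying signal) is allowed but flagged.
#'
#' @param time Times since shutoff, minutes.
#' @param y Normalized relative levels (> 0).
#' @param gene Optional gene label carried into the result.
#' @return Object of class `decay_fit`: list with `gene`, `k`,
#'   `half_life`, `intercept` (log scale), `n_points`, `flagged`.
#' @export
fit_decay <- function(time, y, gene = NA_character_) {
  stopifnot(length(time) == length(y))
  ok <- !is.na(time) & !is.na(y)
  time <- time[ok]; y <- y[ok]
  if (any(y <= 0)) stop("all normalized levels must be > 0 to fit on the log scale",
                        call. = FALSE)
  if (length(time) < 3L || length(unique(time)) < 2L) {
    stop("need >= 3 points spanning >= 2 distinct times", call. = FALSE)
  }
  line <- .ls_line(time, log(y))
  k <- -line[["slope"]]
  structure(
    list(gene = gene, k = k,
         half_life = if (k > 0) log(2) / k else Inf,
         intercept = line[["intercept"]],
         n_points = length(time),
         flagged = k <= 0),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s: k = %.5f min^-1 (t1/2 = %.2f min, n = %d)%s\n",
              x$gene, x$k, x$half_life, x$n_points,
              if (isTRUE(x$flagged)) " [flagged: non-decaying]" else ""))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI on k: [%.5f, %.5f] (n_boot = %d, seed = %d)\n",
                x$ci[1L], x$ci[2L], x$n_boot, x$seed))
  }
  invisible(x)
}

#' Bootstrap confidence interval for a decay constant
#'
#' Case-resampling bootstrap of the (time, ln Y) points with percentile
#' 2.5/97.5 bounds on k, plus a confidence band of the fitted line over
#' the observed times. Resamples with fewer than 2 distinct times are
#' redrawn. The seed is mandatory and recorded, making the interval
#' reproducible.
#'
#' @inheritParams fit_decay
#' @param n_boot Number of bootstrap resamples (default 1000; < 100
#'   warns, < 2 is an error).
#' @param seed Integer RNG seed.
#' @return A `decay_fit` with elements `ci` (c(low, high) on k), `band`
#'   (data frame time, lo, hi on the normalized scale), `draws` (the
#'   bootstrap k values), `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(time, y, n_boot = 1000L, seed, gene = NA_character_) {
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  if (n_boot < 100L) warning("n_boot < 100 gives unstable percentile intervals",
                             call. = FALSE)
  fit <- fit_decay(time, y, gene)
  ok <- !is.na(time) & !is.na(y)
  time <- time[ok]; ly <- log(y[ok])
  n <- length(time)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  # redraw degenerate resamples (all one time point)
  degen <- apply(idx, 1L, function(i) length(unique(time[i])) < 2L)
  while (any(degen)) {
    idx[degen, ] <- sample.int(n, n * sum(degen), replace = TRUE)
    degen <- apply(idx, 1L, function(i) length(unique(time[i])) < 2L)
  }
  tx <- matrix(time[idx], nrow = n_boot)
  ty <- matrix(ly[idx], nrow = n_boot)
  mx <- rowMeans(tx); my <- rowMeans(ty)
  sxx <- rowSums((tx - mx)^2)
  sxy <- rowSums((tx - mx) * (ty - my))
  slopes <- sxy / sxx
  intercepts <- my - slopes * mx
  draws <- -slopes
  ci <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  times_u <- sort(unique(time))
  band <- t(vapply(times_u, function(tt) {
    vals <- exp(intercepts + slopes * tt)
    unname(quantile(vals, c(0.025, 0.975), type = 7))
  }, numeric(2)))
  fit$ci <- ci
  fit$band <- data.frame(time = times_u, lo = band[, 1L], hi = band[, 2L])
  fit$draws <- draws
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- as.integer(seed)
  fit
}

#' Compare decay constants between constructs
#'
#' For each pair of fits, reports the difference in k and its bootstrap
#' confidence interval from the paired resample draws (fits must carry
#' draws from [bootstrap_ci()] with equal `n_boot`); a difference whose
#' 95% interval excludes zero is flagged significant.
#'
#' @param fits List of `decay_fit` objects with stored bootstrap draws.
#' @return Data frame with one row per pair: `gene_a`, `gene_b`,
#'   `delta_k`, `ci_low`, `ci_high`, `significant`.
#' @export
compare_decay <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  for (f in fits) {
    if (is.null(f$draws)) {
      stop("all fits must carry bootstrap draws (use bootstrap_ci)",
           call. = FALSE)
    }
  }
  nb <- unique(vapply(fits, function(f) length(f$draws), integer(1)))
  if (length(nb) != 1L) stop("fits have differing n_boot", call. = FALSE)
  pairs <- utils::combn(length(fits), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    a <- fits[[ij[1L]]]; b <- fits[[ij[2L]]]
    d <- a$draws - b$draws
    ci <- unname(quantile(d, c(0.025, 0.975), type = 7))
    data.frame(gene_a = a$gene, gene_b = b$gene,
               delta_k = a$k - b$k,
               ci_low = ci[1L], ci_high = ci[2L],
               significant = ci[1L] > 0 | ci[2L] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full qPCR shutoff pipeline for a Ct table
#'
#' Runs delta-Ct quantification, t = 0 normalization, decay fitting with
#' bootstrap confidence intervals per gene, and all pairwise
#' comparisons.
#'
#' @param ct_table Data frame with columns `gene`, `time`, `replicate`,
#'   `ct_gene`, `ct_ref`.
#' @param convention Passed to [relative_abundance()].
#' @param n_boot,seed Passed to [bootstrap_ci()]; per-gene seeds are
#'   derived deterministically from `seed`.
#' @return List with `fits` (named list of `decay_fit`), `fit_table`
#'   (data frame), `comparisons`, `aggregated` (mean +/- SEM per time),
#'   `convention`.
#' @export
qpcr_pipeline <- function(ct_table, convention = "standard",
                          n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("gene", "time", "replicate", "ct_gene", "ct_ref") %in%
                  names(ct_table)))
  ct_table$y <- relative_abundance(ct_table$ct_gene, ct_table$ct_ref,
                                   convention)
  norm <- normalize_to_t0(ct_table)
  genes <- sort(unique(norm$gene))
  fits <- lapply(seq_along(genes), function(i) {
    sub <- norm[norm$gene == genes[i], ]
    bootstrap_ci(sub$time, sub$y, n_boot = n_boot,
                 seed = seed + i - 1L, gene = genes[i])
  })
  names(fits) <- genes
  fit_table <- do.call(rbind, lapply(fits, function(f) {
    data.frame(gene = f$gene, k = f$k, half_life = f$half_life,
               ci_low = f$ci[1L], ci_high = f$ci[2L],
               n_boot = f$n_boot, seed = f$seed, n_points = f$n_points)
  }))
  rownames(fit_table) <- NULL
  list(fits = fits, fit_table = fit_table,
       comparisons = if (length(fits) >= 2L) compare_decay(fits) else NULL,
       aggregated = aggregate_replicates(norm),
       convention = convention)
}
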