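# Assembly of the gene-by-predictor matrix, per-column transformations,
# and Tukey-fence outlier filtering of the response (degradation rate
# constants).

TRANSFORMS <- c("none", "log10", "log10_plus1")

#' Apply a declared transformation to a predictor column
#'
#' Predictors that are approximately log-normal are log10-transformed;
#' count-like predictors that may be zero use log10(x + 1); proportions
#' and already-normal predictors are left untransformed. Values outside
#' the domain of the transform (x <= 0 for log10, x <= -1 for
#' log10_plus1) become NA with a warning; missing values propagate.
#'
#' @param values Numeric vector.
#' @param transform One of "none", "log10", "log10_plus1".
#' @return Transformed numeric vector of the same length.
#' @export
apply_transform <- function(values, transform) {
  if (!transform %in% TRANSFORMS) {
    stop("unknown transform '", transform, "'; must be one of: ",
         paste(TRANSFORMS, collapse = ", "), call. = FALSE)
  }
  switch(transform,
    none = values,
    log10 = {
      bad <- !is.na(values) & values <= 0
      if (any(bad)) {
        warning(sum(bad), " non-positive value(s) set to NA under log10",
                call. = FALSE)
        values[bad] <- NA_real_
      }
      log10(values)
    },
    log10_plus1 = {
      bad <- !is.na(values) & values <= -1
      if (any(bad)) {
        warning(sum(bad), " value(s) <= -1 set to NA under log10_plus1",
                call. = FALSE)
        values[bad] <- NA_real_
      }
      log10(values + 1)
    }
  )
}

#' Analytic inverse of a declared transformation
#'
#' @param values Numeric vector on the transformed scale.
#' @param transform One of "none", "log10", "log10_plus1".
#' @return Vector on the original scale.
#' @export
inverse_transform <- function(values, transform) {
  if (!transform %in% TRANSFORMS) {
    stop("unknown transform '", transform, "'", call. = FALSE)
  }
  switch(transform,
    none = values,
    log10 = 10^values,
    log10_plus1 = 10^values - 1
  )
}

#' Assemble a gene-by-predictor table
#'
#' Outer-joins per-predictor gene-to-value maps onto the genes present in
#' the response. No row is dropped at assembly time: genes missing from a
#' source get NA in that column and complete-case handling is deferred to
#' model fitting, mirroring how per-predictor coverage differs between
#' genome-wide datasets.
#'
#' @param sources Named list; each element is a named numeric vector
#'   (gene_id -> value) or a two-column data frame (gene_id, value).
#' @param transforms Named character vector mapping each source name to a
#'   transform in `c("none", "log10", "log10_plus1")`.
#' @param response Named numeric vector of degradation rate constants
#'   (min^-1) keyed by gene_id; defines the row set.
#' @return An object of class `predictor_table`: list with `genes`,
#'   `data` (data frame of original-unit predictor columns), `transforms`,
#'   `response`, and a `coverage` attribute of per-column non-missing
#'   counts.
#' @export
assemble_predictor_table <- function(sources, transforms, response) {
  stopifnot(is.list(sources), length(sources) >= 1L,
            !is.null(names(sources)), !is.null(names(response)))
  if (!all(names(sources) %in% names(transforms))) {
    stop("every source needs a transform; missing: ",
         paste(setdiff(names(sources), names(transforms)), collapse = ", "),
         call. = FALSE)
  }
  genes <- names(response)
  cols <- lapply(names(sources), function(nm) {
    src <- sources[[nm]]
    if (is.data.frame(src)) src <- setNames(src[[2L]], src[[1L]])
    if (anyDuplicated(names(src))) {
      stop("duplicate gene_id in source '", nm, "'", call. = FALSE)
    }
    unname(src[genes])
  })
  names(cols) <- names(sources)
  data <- as.data.frame(cols, optional = TRUE)
  rownames(data) <- genes
  coverage <- vapply(data, function(x) sum(!is.na(x)), integer(1))
  structure(
    list(genes = genes, data = data,
         transforms = transforms[names(sources)],
         response = unname(response)),
    coverage = coverage,
    class = "predictor_table"
  )
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("<predictor_table> %d genes x %d predictors\n",
              length(x$genes), ncol(x$data)))
  cov <- attr(x, "coverage")
  for (nm in names(cov)) {
    cat(sprintf("  %-22s %s  n=%d\n", nm, x$transforms[[nm]], cov[[nm]]))
  }
  invisible(x)
}

#' Predictor matrix on the transformed scale
#'
#' @param table A `predictor_table`.
#' @param terms Predictor names to extract (default: all).
#' @return Data frame of transformed predictor columns, row-aligned to
#'   `table$genes`.
#' @export
transformed_predictors <- function(table, terms = names(table$data)) {
  stopifnot(inherits(table, "predictor_table"))
  missing_terms <- setdiff(terms, names(table$data))
  if (length(missing_terms)) {
    stop("unknown predictor(s): ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(terms, function(nm) {
    suppressWarnings(apply_transform(table$data[[nm]], table$transforms[[nm]]))
  })
  names(out) <- terms
  df <- as.data.frame(out, optional = TRUE)
  rownames(df) <- table$genes
  df
}

#' Tukey-fence outlier filter for the response
#'
#' Computes quartiles by linear interpolation (quantile type 7) on the
#' non-missing response and excludes values outside
#' \[Q1 - factor x IQR, Q3 + factor x IQR\]. With `one_sided_upper = TRUE`
#' only the upper fence is applied, which can be preferable for rate
#' constants that are bounded below by zero. Single-pass: fences are
#' computed once on the input, never recomputed on the survivors.
#'
#' @param response Numeric vector of degradation rate constants; NAs
#'   allowed (ignored for fences, never counted as excluded).
#' @param factor Fence multiplier (default 1.5).
#' @param one_sided_upper Apply only the upper fence?
#' @return List with `kept` and `excluded` (integer indices into
#'   `response`), `excluded_fraction` (of non-missing values), and
#'   `fences`.
#' @export
iqr_filter <- function(response, factor = 1.5, one_sided_upper = FALSE) {
  ok <- !is.na(response)
  if (sum(ok) < 4L) {
    stop("need at least 4 non-missing response values", call. = FALSE)
  }
  q <- quantile(response[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- if (one_sided_upper) -Inf else q[1] - factor * iqr
  upper <- q[2] + factor * iqr
  out_of_fence <- ok & (response < lower | response > upper)
  list(
    kept = which(ok & !out_of_fence),
    excluded = which(out_of_fence),
    excluded_fraction = sum(out_of_fence) / sum(ok),
    fences = c(lower = lower, upper = upper)
  )
}

#' Filter a predictor table's response for outliers
#'
#' Applies [iqr_filter()] to the response and subsets the table to the
#' kept genes (genes with a missing response are also dropped here, since
#' they cannot enter any model).
#'
#' @param table A `predictor_table`.
#' @inheritParams iqr_filter
#' @return The filtered `predictor_table`, with attribute `filter`
#'   holding the [iqr_filter()] report.
#' @export
filter_response <- function(table, factor = 1.5, one_sided_upper = FALSE) {
  stopifnot(inherits(table, "predictor_table"))
  flt <- iqr_filter(table$response, factor, one_sided_upper)
  keep <- flt$kept
  out <- structure(
    list(genes = table$genes[keep],
         data = table$data[keep, , drop = FALSE],
         transforms = table$transforms,
         response = table$response[keep]),
    coverage = vapply(table$data[keep, , drop = FALSE],
                      function(x) sum(!is.na(x)), integer(1)),
    filter = flt,
    class = "predictor_table"
  )
  out
}
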