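# Multiple regression machinery: univariate screening, the two stepwise
# model-building procedures, AIC reduction, categorical variance
# analysis, rank-sum group comparison, residual-outlier
# characterization, and variance-decomposition reporting.
#
# The response is always the degradation rate constant (min^-1),
# untransformed; predictors enter on their declared transformed scale.

#' Fit an ordinary least-squares model on transformed predictors
#'
#' Fits the response (degradation rate constant) on the selected
#' predictors after applying each column's declared transformation.
#' Complete-case rows for the chosen terms are used; per-term two-sided
#' p-values come from t-statistics.
#'
#' @param table A `predictor_table`.
#' @param terms Character vector of predictor names (>= 1).
#' @return An object of class `rate_model`: list with `terms`,
#'   `coefficients` (including intercept), `p_values`, `r_squared`,
#'   `adj_r_squared`, `aic`, `n_used`, `residuals` and `fitted` (named by
#'   gene), `genes_used`, and the underlying `lm` fit.
#' @export
fit_ols <- function(table, terms) {
  stopifnot(inherits(table, "predictor_table"), length(terms) >= 1L)
  X <- transformed_predictors(table, terms)
  df <- cbind(data.frame(.k = table$response), X)
  cc <- complete.cases(df)
  if (sum(cc) < length(terms) + 2L) {
    stop("insufficient complete cases (", sum(cc), ") for ",
         length(terms), " term(s)", call. = FALSE)
  }
  df <- df[cc, , drop = FALSE]
  fit <- lm(.k ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(
    list(
      terms = terms,
      coefficients = cf,
      p_values = sm$coefficients[, "Pr(>|t|)"],
      std_errors = sm$coefficients[, "Std. Error"],
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      aic = AIC(fit),
      n_used = nrow(df),
      residuals = setNames(residuals(fit), rownames(df)),
      fitted = setNames(fitted(fit), rownames(df)),
      genes_used = rownames(df),
      lm = fit
    ),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %d term(s), n = %d, R^2 = %.4f (adj %.4f), AIC = %.1f\n",
              length(x$terms), x$n_used, x$r_squared, x$adj_r_squared, x$aic))
  print(data.frame(coefficient = x$coefficients, p_value = x$p_values))
  invisible(x)
}

# p-values of the non-intercept terms of a rate_model, named by term.
term_p_values <- function(model) {
  p <- model$p_values
  p[setdiff(names(p), "(Intercept)")]
}

#' Univariate predictor screen
#'
#' Fits each predictor alone against the response and reports the
#' variance it explains, the coefficient p-value, and the sign of the
#' association. Results are sorted by ascending p (ties broken
#' alphabetically for determinism). Columns that fail to fit (e.g.
#' constant columns) are recorded in a `failures` attribute, not fatal.
#'
#' @param table A `predictor_table`.
#' @return Data frame with columns `predictor`, `r_squared`, `p_value`,
#'   `sign`, `n`.
#' @export
univariate_screen <- function(table) {
  stopifnot(inherits(table, "predictor_table"))
  preds <- names(table$data)
  rows <- list()
  failures <- character()
  for (nm in preds) {
    res <- tryCatch({
      m <- fit_ols(table, nm)
      data.frame(predictor = nm,
                 r_squared = m$r_squared,
                 p_value = unname(term_p_values(m)),
                 sign = if (unname(m$coefficients[2L]) >= 0) "+" else "-",
                 n = m$n_used)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, setNames(conditionMessage(res), nm))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

# Candidate predictors passing the univariate screen at alpha.
screen_candidates <- function(table, alpha, screen = NULL) {
  if (is.null(screen)) screen <- univariate_screen(table)
  cands <- screen$predictor[screen$p_value < alpha]
  if (length(cands) == 0L) {
    stop("no predictors pass screening at alpha = ", alpha, call. = FALSE)
  }
  list(candidates = cands, screen = screen)
}

#' Backward stepwise model selection
#'
#' Starts from all predictors whose univariate p-value is below `alpha`,
#' then repeatedly refits and removes the single term with the highest
#' p-value while any term has p >= alpha. The final model retains only
#' significant terms. Ties are broken alphabetically; the removal order
#' is recorded in the `steps` attribute.
#'
#' @param table A `predictor_table`.
#' @param alpha Significance threshold (default 0.05), used both for the
#'   univariate screen and for term retention.
#' @param screen Optional precomputed [univariate_screen()] result.
#' @return A `rate_model` with attribute `steps` (removal log).
#' @export
backward_stepwise <- function(table, alpha = 0.05, screen = NULL) {
  sc <- screen_candidates(table, alpha, screen)
  terms <- sort(sc$candidates)
  steps <- character()
  repeat {
    model <- fit_ols(table, terms)
    p <- term_p_values(model)
    if (all(p < alpha) || length(terms) == 1L) break
    worst <- names(p)[order(-p, names(p))][1L]
    steps <- c(steps, sprintf("removed %s (p = %.3g)", worst, p[[worst]]))
    terms <- setdiff(terms, worst)
  }
  # a single remaining non-significant term is still removed if possible
  p <- term_p_values(model)
  if (length(terms) == 1L && any(p >= alpha)) {
    stop("no term remains significant at alpha = ", alpha, call. = FALSE)
  }
  attr(model, "steps") <- steps
  attr(model, "screen") <- sc$screen
  model
}

#' Forward stepwise model selection
#'
#' Adds predictors in order of ascending univariate p-value, skipping any
#' predictor that was not significant in the univariate screen. After
#' each addition: if the new term is not significant it is removed; if an
#' existing term loses significance, the model with the new term and the
#' model with the displaced term are compared and the one explaining more
#' variation is retained. The decision log is stored in the `steps`
#' attribute.
#'
#' @inheritParams backward_stepwise
#' @return A `rate_model` with attribute `steps` (decision log).
#' @export
forward_stepwise <- function(table, alpha = 0.05, screen = NULL) {
  sc <- screen_candidates(table, alpha, screen)
  order_in <- sc$screen$predictor[sc$screen$p_value < alpha]
  terms <- character()
  steps <- character()
  for (cand in order_in) {
    trial <- sort(c(terms, cand))
    model <- tryCatch(fit_ols(table, trial), error = function(e) e)
    if (inherits(model, "error")) {
      steps <- c(steps, sprintf("skipped %s (%s)", cand, conditionMessage(model)))
      next
    }
    p <- term_p_values(model)
    if (p[[cand]] >= alpha) {
      steps <- c(steps, sprintf("tried %s, not significant (p = %.3g), removed",
                                cand, p[[cand]]))
      next
    }
    added <- FALSE
    lost <- setdiff(names(p)[p >= alpha], cand)
    while (length(lost)) {
      # resolve the worst-affected existing term first
      displaced <- lost[order(-p[lost], lost)][1L]
      with_new <- fit_ols(table, setdiff(trial, displaced))
      with_old <- fit_ols(table, setdiff(trial, cand))
      if (with_new$r_squared >= with_old$r_squared) {
        steps <- c(steps, sprintf(
          "added %s, displaced %s (R^2 %.4f vs %.4f)",
          cand, displaced, with_new$r_squared, with_old$r_squared))
        model <- with_new
        added <- TRUE
      } else {
        steps <- c(steps, sprintf(
          "tried %s, kept %s instead (R^2 %.4f vs %.4f)",
          cand, displaced, with_old$r_squared, with_new$r_squared))
        model <- with_old
      }
      trial <- model$terms
      p <- term_p_values(model)
      lost <- if (cand %in% trial) setdiff(names(p)[p >= alpha], cand)
              else character()
    }
    if (cand %in% model$terms && !added) {
      steps <- c(steps, sprintf("added %s (p = %.3g)", cand, p[[cand]]))
    }
    terms <- model$terms
  }
  final <- fit_ols(table, sort(terms))
  attr(final, "steps") <- steps
  attr(final, "screen") <- sc$screen
  final
}

#' AIC-based backward reduction
#'
#' Greedy backward elimination: starting from a fitted model on
#' `start_terms`, repeatedly drops the single term whose removal lowers
#' AIC the most, stopping when no removal lowers AIC. Equivalent to
#' `step(direction = "backward")` restricted to main effects.
#'
#' @param table A `predictor_table`.
#' @param start_terms Character vector of starting predictors.
#' @return A `rate_model` with attribute `steps` (drop log). Final AIC is
#'   never above the starting AIC.
#' @export
aic_reduce <- function(table, start_terms) {
  terms <- sort(start_terms)
  model <- fit_ols(table, terms)
  steps <- character()
  repeat {
    if (length(terms) == 1L) break
    drops <- vapply(terms, function(tm) {
      fit_ols(table, setdiff(terms, tm))$aic
    }, numeric(1))
    best <- names(drops)[order(drops, names(drops))][1L]
    if (drops[[best]] >= model$aic) break
    steps <- c(steps, sprintf("dropped %s (AIC %.2f -> %.2f)",
                              best, model$aic, drops[[best]]))
    terms <- setdiff(terms, best)
    model <- fit_ols(table, terms)
  }
  attr(model, "steps") <- steps
  model
}

#' One-way ANOVA of rates on a categorical label
#'
#' Variance in the response explained by group membership: R^2 is the
#' between-group sum of squares over the total sum of squares, with the
#' usual F-test p-value.
#'
#' @param response Numeric vector of rates.
#' @param labels Category assignment, same length as `response`.
#' @return List with `r_squared`, `p_value`, `n`, `n_groups`.
#' @export
categorical_anova <- function(response, labels) {
  ok <- !is.na(response) & !is.na(labels)
  response <- response[ok]
  labels <- factor(labels[ok])
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 categories", call. = FALSE)
  if (any(tab < 2L)) stop("every category needs >= 2 members", call. = FALSE)
  fit <- lm(response ~ labels)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(
    r_squared = sm$r.squared,
    p_value = unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)),
    n = length(response),
    n_groups = length(tab)
  )
}

# Build a 0/1 indicator matrix over table genes from a long annotation
# data frame (gene_id, label), keeping labels with prevalence >=
# min_prevalence among the table's genes.
annotation_indicators <- function(table, annotations, min_prevalence = 10L) {
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "label") %in% names(annotations)))
  ann <- annotations[annotations$gene_id %in% table$genes, , drop = FALSE]
  keep <- names(which(table(ann$label) >= min_prevalence))
  ind <- matrix(0, nrow = length(table$genes), ncol = length(keep),
                dimnames = list(table$genes, keep))
  for (lab in keep) {
    ind[unique(ann$gene_id[ann$label == lab]), lab] <- 1
  }
  ind
}

#' Extend a reduced model with categorical indicators ("model++")
#'
#' Refits the reduced model's continuous terms together with one binary
#' indicator column per annotation label (GO SLIM terms, RNA-binding
#' protein targets) whose prevalence among the table's genes is at least
#' `min_prevalence`. Both models are evaluated on the same complete-case
#' rows, so the extended model's R^2 can never be lower; the gain is
#' tested with a nested-model F-test.
#'
#' @param table A `predictor_table`.
#' @param reduced A `rate_model` (e.g. from [backward_stepwise()]).
#' @param annotations Long data frame with columns `gene_id`, `label`.
#' @param min_prevalence Minimum genes per label (default 10).
#' @return A `rate_model` with attributes `indicator_terms`,
#'   `r_squared_reduced`, `r_squared_gain`, and `gain_p_value`.
#' @export
model_plus_plus <- function(table, reduced, annotations,
                            min_prevalence = 10L) {
  stopifnot(inherits(table, "predictor_table"), inherits(reduced, "rate_model"))
  ind <- annotation_indicators(table, annotations, min_prevalence)
  X <- transformed_predictors(table, reduced$terms)
  df <- cbind(data.frame(.k = table$response), X)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  ind <- ind[cc, , drop = FALSE]
  # drop indicators constant on the complete-case rows
  ind <- ind[, apply(ind, 2L, function(x) length(unique(x)) > 1L), drop = FALSE]
  fit_red <- lm(.k ~ ., data = df)
  if (ncol(ind) == 0L) {
    full <- fit_ols(table, reduced$terms)
    attr(full, "indicator_terms") <- character()
    attr(full, "r_squared_reduced") <- summary(fit_red)$r.squared
    attr(full, "r_squared_gain") <- 0
    attr(full, "gain_p_value") <- NA_real_
    return(full)
  }
  colnames(ind) <- make.names(paste0("cat_", colnames(ind)), unique = TRUE)
  df_full <- cbind(df, as.data.frame(ind))
  fit_full <- lm(.k ~ ., data = df_full)
  sm_full <- summary(fit_full)
  sm_red <- summary(fit_red)
  cmp <- anova(fit_red, fit_full)
  cf <- coef(fit_full)
  cf <- cf[!is.na(cf)]
  structure(
    list(
      terms = c(reduced$terms, colnames(ind)),
      coefficients = cf,
      p_values = sm_full$coefficients[, "Pr(>|t|)"],
      std_errors = sm_full$coefficients[, "Std. Error"],
      r_squared = sm_full$r.squared,
      adj_r_squared = sm_full$adj.r.squared,
      aic = AIC(fit_full),
      n_used = nrow(df_full),
      residuals = setNames(residuals(fit_full), rownames(df_full)),
      fitted = setNames(fitted(fit_full), rownames(df_full)),
      genes_used = rownames(df_full),
      lm = fit_full
    ),
    indicator_terms = colnames(ind),
    r_squared_reduced = sm_red$r.squared,
    r_squared_gain = sm_full$r.squared - sm_red$r.squared,
    gain_p_value = cmp$`Pr(>F)`[2L],
    class = "rate_model"
  )
}

#' Wilcoxon rank-sum comparison of two rate groups
#'
#' Two-sided Wilcoxon rank-sum test. With both groups of size <= 10 (and
#' no ties) the exact enumeration p-value is used; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b Numeric vectors of rates (non-empty).
#' @param method "auto" (default; exact when both n <= 10 and no ties),
#'   "exact", or "normal".
#' @return List with `statistic` (W), `p_value`, `method`.
#' @export
rank_sum_compare <- function(group_a, group_b,
                             method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- switch(method,
    auto = length(group_a) <= 10L && length(group_b) <= 10L && !has_ties,
    exact = TRUE,
    normal = FALSE
  )
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal")
}

#' Identify and characterize transcripts the model fits poorly
#'
#' Flags genes whose residual exceeds the mean residual by more than
#' `sd_threshold` standard deviations (one-sided: transcripts degraded
#' faster than the model predicts have positive residuals when the
#' response is a degradation rate). If the predictor table is supplied,
#' the feature medians of the outliers are compared with the rest on the
#' transformed scale.
#'
#' @param model A `rate_model`.
#' @param table Optional `predictor_table` for the feature summary.
#' @param sd_threshold Threshold in residual standard deviations
#'   (default 2).
#' @return List with `genes`, `fraction`, and (when `table` is given)
#'   `summary` (data frame of per-predictor medians for outliers vs
#'   rest).
#' @export
residual_outliers <- function(model, table = NULL, sd_threshold = 2) {
  r <- model$residuals
  s <- sd(r)
  flagged <- if (is.na(s) || s == 0) character() else
    names(r)[r > mean(r) + sd_threshold * s]
  out <- list(genes = flagged, fraction = length(flagged) / length(r))
  if (!is.null(table)) {
    X <- transformed_predictors(table)
    X <- X[model$genes_used, , drop = FALSE]
    is_out <- rownames(X) %in% flagged
    out$summary <- data.frame(
      predictor = names(X),
      median_outliers = vapply(X, function(v) median(v[is_out], na.rm = TRUE),
                               numeric(1)),
      median_rest = vapply(X, function(v) median(v[!is_out], na.rm = TRUE),
                           numeric(1)),
      row.names = NULL
    )
  }
  out
}

#' Variance-decomposition summary report
#'
#' Tabulates signed univariate R^2 per screened predictor alongside the
#' R^2 of the reduced continuous model and of the model extended with
#' categorical indicators, and exports predicted-vs-measured scatter
#' data.
#'
#' @param screen A [univariate_screen()] result.
#' @param model A `rate_model` (continuous model).
#' @param model_pp Optional `rate_model` from [model_plus_plus()].
#' @param table The `predictor_table` the fits came from.
#' @return List with `table` (component, r_squared, signed_r_squared,
#'   p_value) and `scatter` (gene, measured, predicted from the richest
#'   model).
#' @export
variance_summary <- function(screen, model, model_pp = NULL, table) {
  rows <- data.frame(
    component = screen$predictor,
    r_squared = screen$r_squared,
    signed_r_squared = screen$r_squared *
      ifelse(screen$sign == "+", 1, -1),
    p_value = screen$p_value
  )
  rows <- rbind(rows, data.frame(
    component = "model", r_squared = model$r_squared,
    signed_r_squared = NA_real_, p_value = NA_real_))
  best <- model
  if (!is.null(model_pp)) {
    rows <- rbind(rows, data.frame(
      component = "model++", r_squared = model_pp$r_squared,
      signed_r_squared = NA_real_, p_value = NA_real_))
    best <- model_pp
  }
  idx <- match(best$genes_used, table$genes)
  scatter <- data.frame(
    gene = best$genes_used,
    measured = table$response[idx],
    predicted = unname(best$fitted)
  )
  list(table = rows, scatter = scatter)
}
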