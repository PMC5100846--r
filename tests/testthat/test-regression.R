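# Helper: wrap plain vectors into a predictor_table with no transforms.
make_table <- function(response, ...) {
  cols <- list(...)
  genes <- sprintf("g%04d", seq_along(response))
  sources <- lapply(cols, function(v) setNames(v, genes))
  assemble_predictor_table(sources,
                           setNames(rep("none", length(cols)), names(cols)),
                           setNames(response, genes))
}

test_that("OLS recovers an exact linear relationship", {
  x <- 1:10
  tab <- make_table(response = 2 * x, x = x)
  m <- fit_ols(tab, "x")
  expect_equal(unname(m$coefficients["x"]), 2.0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(m$n_used, 10L)
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- 0.5 + 0.3 * x1 - 0.2 * x2 + rnorm(n, 0, 0.5)
    tab <- make_table(y, x1 = x1, x2 = x2, x3 = x3)
    m <- fit_ols(tab, c("x1", "x2", "x3"))
    X <- cbind(1, x1, x2, x3)
    beta_hat <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(m$coefficients), unname(drop(beta_hat)),
                 tolerance = 1e-10)
  }
})

test_that("OLS rejects degenerate designs with informative errors", {
  x <- rnorm(30)
  tab <- make_table(0.1 * x + rnorm(30), x = x, x2 = 2 * x)
  expect_error(fit_ols(tab, c("x", "x2")), "collinear")
  tiny <- make_table(c(1, 2, 3), a = c(1, 2, 3), b = c(2, 1, 3))
  expect_error(fit_ols(tiny, c("a", "b")), "insufficient")
})

test_that("y independent of x yields near-zero R^2 and a null p-value", {
  set.seed(100)
  x <- rnorm(1000); y <- rnorm(1000)
  m <- fit_ols(make_table(y, x = x), "x")
  expect_lt(m$r_squared, 0.01)
  expect_gt(unname(m$p_values["x"]), 0.05)
})

test_that("univariate screen ranks predictors and matches the correlation identity", {
  set.seed(18)
  x <- rnorm(200)
  noise <- rnorm(200)
  y <- x  # perfect predictor
  tab <- make_table(y, perfect = x, pure_noise = noise)
  sc <- univariate_screen(tab)
  expect_equal(sc$predictor[1], "perfect")
  expect_equal(sc$r_squared[1], 1, tolerance = 1e-12)
  # screen R^2 equals squared Pearson correlation
  set.seed(19)
  y2 <- 0.4 * x + rnorm(200)
  tab2 <- make_table(y2, x = x, z = noise)
  sc2 <- univariate_screen(tab2)
  expect_equal(sc2$r_squared[sc2$predictor == "x"], cor(x, y2)^2,
               tolerance = 1e-10)
  # duplicated predictor column gives identical results
  tab3 <- make_table(y2, a = x, b = x)
  sc3 <- univariate_screen(tab3)
  expect_equal(sc3$r_squared[1], sc3$r_squared[2], tolerance = 1e-14)
  expect_equal(sc3$p_value[1], sc3$p_value[2], tolerance = 1e-14)
})

test_that("backward stepwise keeps exactly the true predictors in a seeded design", {
  sim <- selection_sim(seed = 101, n = 2000L)
  m <- backward_stepwise(sim$table)
  expect_setequal(m$terms, c("p1", "p2", "p3"))
  expect_true(all(term_p <- m$p_values[m$terms] < 0.05))
})

test_that("backward stepwise matches the exhaustive best-subset oracle", {
  for (seed in c(301, 302, 303, 304, 305)) {
    sim <- selection_sim(seed)
    sc <- univariate_screen(sim$table)
    cands <- sort(sc$predictor[sc$p_value < 0.05])
    m <- backward_stepwise(sim$table, screen = sc)
    expect_equal(sort(m$terms), best_subset_oracle(sim$table, cands))
  }
})

test_that("forward stepwise agrees with backward on well-separated designs", {
  sim <- selection_sim(seed = 102, n = 2000L)
  fwd <- forward_stepwise(sim$table)
  bwd <- backward_stepwise(sim$table)
  expect_setequal(fwd$terms, bwd$terms)
})

test_that("forward stepwise keeps one of two collinear copies by the R^2 rule", {
  set.seed(55)
  n <- 500
  x <- rnorm(n)
  x_copy <- x + rnorm(n, 0, 0.05)  # nearly identical information
  z <- rnorm(n)
  y <- 0.15 + 0.02 * x + rnorm(n, 0, 0.02)
  tab <- make_table(y, a_x = x, b_copy = x_copy, c_noise = z)
  m <- forward_stepwise(tab)
  expect_equal(sum(c("a_x", "b_copy") %in% m$terms), 1L)
  expect_true(all(m$p_values[m$terms] < 0.05))
})

test_that("forward stepwise with a single candidate equals the plain fit", {
  set.seed(56)
  x <- rnorm(100); z <- rnorm(100)
  y <- 0.1 + 0.05 * x + rnorm(100, 0, 0.05)
  tab <- make_table(y, x = x, z = z)
  sc <- univariate_screen(tab)
  # force a single candidate by choosing alpha between the two p-values
  stopifnot(sc$predictor[1] == "x")
  alpha <- min(0.05, mean(sc$p_value))
  m <- forward_stepwise(tab, alpha = alpha)
  direct <- fit_ols(tab, "x")
  expect_equal(m$coefficients, direct$coefficients)
  expect_equal(m$r_squared, direct$r_squared)
})

test_that("screening failure raises a clear error", {
  set.seed(57)
  tab <- make_table(rnorm(100, 0.1, 0.01), x = rnorm(100))
  sc <- univariate_screen(tab)
  if (all(sc$p_value >= 0.05)) {
    expect_error(backward_stepwise(tab, screen = sc), "no predictors pass")
  } else {
    succeed("seeded noise predictor happened to pass screening")
  }
})

test_that("AIC reduction drops pure-noise terms and never raises the AIC", {
  sim <- selection_sim(seed = 103, n = 2000L)
  start <- names(sim$table$data)
  m <- aic_reduce(sim$table, start)
  full_aic <- fit_ols(sim$table, start)$aic
  expect_lte(m$aic, full_aic)
  expect_true(all(c("p1", "p2", "p3") %in% m$terms))
  expect_false(all(c("p4", "p5") %in% m$terms))
})

test_that("AIC reduction agrees with the stats::step reference", {
  sim <- selection_sim(seed = 104)
  mine <- aic_reduce(sim$table, names(sim$table$data))
  df <- cbind(data.frame(.k = sim$table$response),
              transformed_predictors(sim$table))
  df <- df[stats::complete.cases(df), ]
  ref <- stats::step(stats::lm(.k ~ ., data = df), direction = "backward",
                     trace = 0)
  ref_terms <- sort(attr(stats::terms(ref), "term.labels"))
  expect_equal(sort(mine$terms), ref_terms)
})

test_that("one-way ANOVA decomposes variance and matches the indicator-regression oracle", {
  # perfect separation
  res <- categorical_anova(c(1, 1, 1, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(res$r_squared, 1)
  # equivalence with one-hot OLS
  set.seed(77)
  y <- rnorm(120)
  labs <- sample(letters[1:4], 120, replace = TRUE)
  av <- categorical_anova(y, labs)
  ind <- stats::model.matrix(~ labs)[, -1]
  fit <- summary(stats::lm(y ~ ind))
  expect_equal(av$r_squared, fit$r.squared, tolerance = 1e-10)
  # permuted labels carry roughly the null expectation (k-1)/(n-1)
  set.seed(78)
  r2 <- replicate(50, categorical_anova(y, sample(labs))$r_squared)
  expect_lt(abs(mean(r2) - 3 / 119), 0.01)
  expect_error(categorical_anova(y, rep("a", 120)), "2 categories")
})

test_that("model++ detects a constructed category effect and never loses R^2", {
  sim <- sim_predictor_table(n_genes = 1500, seed = 200)
  cats <- data.frame(label = "ribosome_biogenesis", prevalence = 0.1,
                     shift = 2 * sim$truth$sigma)
  with_cat <- sim_categorical(sim, seed = 201, categories = cats)
  reduced <- fit_ols(with_cat$table, names(default_beta()))
  mpp <- model_plus_plus(with_cat$table, reduced, with_cat$annotations)
  expect_gte(attr(mpp, "r_squared_gain"), 0)
  expect_lt(attr(mpp, "gain_p_value"), 0.05)
  ind_term <- attr(mpp, "indicator_terms")
  expect_length(ind_term, 1L)
  expect_lt(mpp$p_values[ind_term], 0.05)
})

test_that("model++ with no usable annotations reduces to the continuous model", {
  sim <- sim_predictor_table(n_genes = 300, seed = 202)
  reduced <- fit_ols(sim$table, c("coding_length", "cai"))
  empty <- data.frame(gene_id = character(), label = character())
  mpp <- model_plus_plus(sim$table, reduced, empty)
  expect_equal(mpp$r_squared, reduced$r_squared, tolerance = 1e-12)
  expect_equal(attr(mpp, "r_squared_gain"), 0)
})

test_that("rank-sum comparison is exact for tiny groups and symmetric", {
  res <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  swapped <- rank_sum_compare(c(3, 4), c(1, 2))
  expect_equal(res$p_value, swapped$p_value)
  # identical groups show no shift
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3), method = "normal")
  expect_gt(same$p_value, 0.99)
  expect_error(rank_sum_compare(numeric(), c(1)), "non-empty")
})

test_that("residual outliers follow the one-sided normal tail expectation", {
  set.seed(400)
  r <- rnorm(10000)
  fake <- structure(
    list(residuals = setNames(r, sprintf("g%05d", 1:10000)),
         genes_used = sprintf("g%05d", 1:10000)),
    class = "rate_model")
  out <- residual_outliers(fake)
  expect_gt(out$fraction, 0.015)
  expect_lt(out$fraction, 0.032)
  # zero-variance residuals flag nothing
  fake0 <- structure(list(residuals = setNames(rep(0.5, 10), letters[1:10]),
                          genes_used = letters[1:10]),
                     class = "rate_model")
  expect_length(residual_outliers(fake0)$genes, 0L)
})

test_that("outlier feature summary compares medians on the transformed scale", {
  sim <- sim_predictor_table(n_genes = 1000, seed = 401)
  m <- fit_ols(sim$table, names(default_beta()))
  out <- residual_outliers(m, sim$table)
  expect_true(is.data.frame(out$summary))
  expect_setequal(out$summary$predictor, names(sim$table$data))
})

test_that("variance summary reports screen, model, and model++ rows", {
  sim <- sim_predictor_table(n_genes = 1500, seed = 402)
  cats <- data.frame(label = "stress", prevalence = 0.15,
                     shift = sim$truth$sigma)
  wc <- sim_categorical(sim, seed = 403, categories = cats)
  sc <- univariate_screen(wc$table)
  m <- backward_stepwise(wc$table, screen = sc)
  mpp <- model_plus_plus(wc$table, m, wc$annotations)
  vs <- variance_summary(sc, m, mpp, wc$table)
  expect_equal(nrow(vs$table), nrow(sc) + 2L)
  r2_model <- vs$table$r_squared[vs$table$component == "model"]
  r2_mpp <- vs$table$r_squared[vs$table$component == "model++"]
  expect_gte(r2_mpp, r2_model)
  expect_equal(names(vs$scatter), c("gene", "measured", "predicted"))
  expect_equal(nrow(vs$scatter), mpp$n_used)
})
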