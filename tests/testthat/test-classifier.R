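sim_logistic <- function(n, p, beta, seed, intercept = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  eta <- intercept + drop(X[, seq_along(beta), drop = FALSE] %*% beta)
  list(X = X, y = rbinom(n, 1, plogis(eta)))
}

test_that("training pixel sampling is stratified, reproducible and guarded", {
  mask <- matrix(FALSE, 60, 60)
  mask[10:50, 30] <- TRUE; mask[20, 5:55] <- TRUE
  s1 <- sample_training_pixels(mask, 50, 50, seed = 3)
  s2 <- sample_training_pixels(mask, 50, 50, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100L)
  expect_true(all(mask[s1[s1[, "label"] == 1, 1:2]]))
  expect_true(all(!mask[s1[s1[, "label"] == 0, 1:2]]))
  expect_equal(sum(s1[, "label"]), 50L)
  expect_identical(formals(sample_training_pixels)$n_pos, 500L)
  expect_error(sample_training_pixels(mask, 500, 10, seed = 1), "outline pixels")
})

test_that("the null model holds at lambda_max: all beta zero, intercept = log class ratio", {
  d <- sim_logistic(300, 20, c(1.5, -1.5), seed = 2)
  path <- fit_l1_logistic_path(d$X, d$y)
  expect_true(all(path$beta[, 1] == 0))
  expect_equal(path$intercept[1], log(mean(d$y) / (1 - mean(d$y))),
               tolerance = 1e-6)
  # beyond lambda_max everything stays at the null model
  lam <- c(10 * path$lambdas[1], 2 * path$lambdas[1])
  p2 <- fit_l1_logistic_path(d$X, d$y, lambdas = lam)
  expect_true(all(p2$beta == 0))
})

test_that("a tiny penalty reproduces the unpenalized maximum likelihood fit", {
  d <- sim_logistic(400, 2, c(0.8, -0.6), seed = 5, intercept = 0.3)
  path <- fit_l1_logistic_path(d$X, d$y, lambdas = c(1e-4, 1e-6), tol = 1e-12)
  # oracle: direct maximization of the unpenalized log-likelihood on the
  # same standardized design
  xs <- scale(d$X, scale = apply(d$X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  nll <- function(b) {
    eta <- b[1] + xs %*% b[2:3]
    -sum(d$y * eta - log(1 + exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS")
  expect_equal(unname(path$beta[, 2]), opt$par[2:3], tolerance = 1e-3)
  expect_equal(path$intercept[2], opt$par[1], tolerance = 1e-3)
})

test_that("the path agrees with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  d <- sim_logistic(250, 12, c(1.2, -0.9, 0.7), seed = 8)
  path <- fit_l1_logistic_path(d$X, d$y, tol = 1e-10)
  for (l in c(15, 40, 70)) {
    g <- glmnet::glmnet(d$X, d$y, family = "binomial",
                        lambda = path$lambdas[l], standardize = TRUE,
                        thresh = 1e-12)
    # convert our standardized-scale coefficients to the original scale
    ours <- path$beta[, l] / path$standardization$scale
    expect_equal(unname(ours), as.numeric(g$beta), tolerance = 5e-3)
  }
})

test_that("sparsity is monotone along the path and the objective decreases within IRLS", {
  d <- sim_logistic(200, 30, c(2, -2, 2), seed = 3)
  path <- fit_l1_logistic_path(d$X, d$y)
  nz <- colSums(path$beta != 0)
  # lambdas decrease with index, so nonzero counts grow (ties allowed)
  expect_true(all(diff(nz) >= -2))  # small local ties/drops allowed
  expect_equal(nz[1], 0L)
  for (tr in path$objective[c(10, 50, 90)])
    expect_true(all(diff(tr) <= 1e-8))
})

test_that("KKT conditions hold at convergence for zero coefficients", {
  d <- sim_logistic(200, 25, c(1.5, -1), seed = 10)
  path <- fit_l1_logistic_path(d$X, d$y, tol = 1e-10)
  xs <- scale(d$X, scale = apply(d$X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  for (l in c(10, 40, 80)) {
    eta <- drop(xs %*% path$beta[, l]) + path$intercept[l]
    score <- abs(crossprod(xs, d$y - plogis(eta))) / nrow(xs)
    zero <- path$beta[, l] == 0
    if (any(zero))
      expect_lt(max(score[zero]), path$lambdas[l] + 1e-3)
  }
})

test_that("cross-validation selects plausibly and the 1se rule is at least as sparse", {
  d <- sim_logistic(300, 25, c(2, -2, 2), seed = 4)
  path <- fit_l1_logistic_path(d$X, d$y)
  expect_identical(formals(cross_validate_select)$folds, 10L)
  m_min <- cross_validate_select(path, rule = "min", seed = 1)
  m_1se <- cross_validate_select(path, rule = "1se", seed = 1)
  expect_lte(length(m_1se$coefficients), length(m_min$coefficients))
  expect_gte(m_1se$lambda, m_min$lambda)
  # "min" picks the unique CV minimum
  expect_equal(m_min$lambda, m_min$cv$lambda[which.min(m_min$cv$mean_deviance)])
  expect_error(cross_validate_select(path, folds = 1), "folds")
})

test_that("probability predictions follow the stored link convention", {
  m0 <- outline_model(intercept = 0, coefficients = c(VAR_3x3 = 0))
  X <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "VAR_3x3"))
  expect_equal(predict_outline_probability(m0, X), rep(0.5, 5))

  eq8 <- read_outline_model(system.file("models", "eq8_tc1.json",
                                        package = "cellcontour"))
  X8 <- matrix(0, 2, length(eq8$coefficients),
               dimnames = list(NULL, names(eq8$coefficients)))
  # printed-form models use p = 1/(1 + exp(+eta)); at zero features
  # eta = 0.2415 so p < 0.5 (regression-pins the shipped convention)
  expect_equal(predict_outline_probability(eq8, X8),
               rep(1 / (1 + exp(0.2415)), 2), tolerance = 1e-12)
  expect_equal(predict_outline_probability(eq8, X8)[1], 0.440, tolerance = 1e-3)

  eq9 <- read_outline_model(system.file("models", "eq9_tc2.json",
                                        package = "cellcontour"))
  X9 <- matrix(0, 1, length(eq9$coefficients),
               dimnames = list(NULL, names(eq9$coefficients)))
  expect_equal(predict_outline_probability(eq9, X9)[1],
               1 / (1 + exp(1.120)), tolerance = 1e-12)
  expect_equal(predict_outline_probability(eq9, X9)[1], 0.246, tolerance = 1e-3)

  expect_error(predict_outline_probability(eq8, matrix(0, 1, 1,
                 dimnames = list(NULL, "VAR_3x3"))), "missing feature")
})

test_that("predicted probabilities are calibrated on data from a known model", {
  set.seed(21)
  n <- 5000
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("a", "b", "c")
  p_true <- plogis(0.5 + X %*% c(1, -1, 0.5))
  y <- rbinom(n, 1, p_true)
  path <- fit_l1_logistic_path(X, y, lambdas = c(1e-2, 1e-4))
  m <- outline_model(intercept = path$intercept[2],
                     coefficients = path$beta[, 2],
                     standardization = path$standardization)
  p_hat <- predict_outline_probability(m, X)
  expect_lt(mean(abs(p_hat - p_true)), 0.05)
})

test_that("image classification computes only model features and thresholds at 0.5", {
  m_empty <- outline_model(intercept = -1, coefficients = numeric(0),
                           link_sign = -1)
  img <- gray_image(matrix(runif(100, 0, 4095), 10, 10), 12)
  expect_false(any(classify_outlines(m_empty, img)))
  expect_equal(m_empty$threshold, 0.5)

  m <- outline_model(intercept = 0, coefficients = c(VAR_3x3 = 1),
                     link_sign = -1)
  out <- classify_outlines(m, img)
  v <- compute_feature(img, parse_feature_name("VAR_3x3"))
  expect_identical(out, matrix(plogis(v) >= 0.5, 10, 10))
})

test_that("models round-trip through JSON", {
  m <- outline_model(intercept = 1.5,
                     coefficients = c(VAR_3x3 = -2, ENT_5x5 = 0.25),
                     lambda = 0.01, threshold = 0.4, link_sign = -1,
                     standardization = list(
                       mean = c(VAR_3x3 = 10, ENT_5x5 = 1),
                       scale = c(VAR_3x3 = 5, ENT_5x5 = 0.5)))
  path <- file.path(tempdir(), "model.json")
  write_outline_model(m, path)
  m2 <- read_outline_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$threshold, m$threshold)
  expect_equal(m2$link_sign, m$link_sign)
  expect_equal(m2$standardization$scale, m$standardization$scale)
  expect_error(read_outline_model(file.path(tempdir(), "nope.json")), "no such")
})
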