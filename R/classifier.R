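#' Sample training pixels from a benchmark outline mask
#'
#' Draws outline (positive) and non-outline (negative) pixels uniformly at
#' random without replacement within each class, reproducibly for a given
#' seed. The defaults (500 + 500) give the 1000-sample training set used to
#' fit the outline classifier.
#'
#' @param outline_mask logical matrix, \code{TRUE} = outline pixel.
#' @param n_pos,n_neg samples per class, default 500 each.
#' @param seed integer seed.
#' @return Integer matrix with columns \code{row}, \code{col}, \code{label}
#'   (1 = outline, 0 = non-outline), 1-based indices.
#' @export
sample_training_pixels <- function(outline_mask, n_pos = 500L, n_neg = 500L,
                                   seed = 1L) {
  pos <- which(outline_mask)
  neg <- which(!outline_mask)
  if (length(pos) < n_pos)
    stop(sprintf("only %d outline pixels available, %d requested", length(pos), n_pos))
  if (length(neg) < n_neg)
    stop(sprintf("only %d non-outline pixels available, %d requested", length(neg), n_neg))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  sel_pos <- sample(pos, n_pos)
  sel_neg <- sample(neg, n_neg)
  nr <- nrow(outline_mask)
  lin <- c(sel_pos, sel_neg)
  cbind(row = (lin - 1L) %% nr + 1L,
        col = (lin - 1L) %/% nr + 1L,
        label = rep(c(1L, 0L), c(n_pos, n_neg)))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Coerce x/y inputs for fitting.
as_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  list(x = x, y = y)
}

#' Fit an L1-penalized logistic regression path
#'
#' Maximizes the penalized binomial log-likelihood
#' \deqn{\frac{1}{N}\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)] - \lambda \|\beta\|_1}
#' over a decreasing sequence of \eqn{\lambda}, by iteratively re-weighted
#' least squares with cyclic coordinate descent on the quadratic
#' approximation, warm-started along the path. The intercept is unpenalized.
#' Features are standardized internally (zero mean, unit population variance);
#' coefficients are reported on the standardized scale with the
#' standardization parameters stored for prediction.
#'
#' The path starts at \eqn{\lambda_{max} = \max_j |x_j^T (y - \bar y)| / N},
#' the smallest \eqn{\lambda} at which all coefficients are zero and the
#' intercept equals the log class ratio.
#'
#' @param x feature matrix (rows = samples) or a \code{feature_matrix}.
#' @param y binary labels (1 = outline).
#' @param lambdas optional decreasing positive sequence; by default 100
#'   log-spaced values from \eqn{\lambda_{max}} down to
#'   \eqn{10^{-3}\lambda_{max}}.
#' @param nlambda,lambda_min_ratio default grid size and extent.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change, default \code{1e-7}.
#' @param maxit maximum IRLS iterations / coordinate-descent sweeps.
#' @return Object of class \code{lasso_logistic_path}: lambdas, coefficient
#'   matrix (features x lambdas, standardized scale), intercepts, per-lambda
#'   objective traces, standardization, and the training data (for
#'   cross-validation).
#' @seealso [cross_validate_select()] to pick a single model off the path.
#' @export
fit_l1_logistic_path <- function(x, y, lambdas = NULL, nlambda = 100L,
                                 lambda_min_ratio = 1e-3, tol = 1e-7,
                                 maxit = 1000L) {
  d <- as_xy(x, y)
  n <- nrow(d$x); p <- ncol(d$x)
  mu <- colMeans(d$x)
  sc <- sqrt(colMeans(sweep(d$x, 2, mu)^2))
  sc[sc == 0] <- 1  # constant features: keep column, coefficient stays 0
  xs <- sweep(sweep(d$x, 2, mu), 2, sc, "/")
  if (is.null(lambdas)) {
    # tiny relative margin so the path start sits at (not epsilon below)
    # the smallest lambda annihilating all features
    lmax <- max(abs(crossprod(xs, d$y - mean(d$y)))) / n * (1 + 1e-8)
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  } else {
    lambdas <- as.numeric(lambdas)
    if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
    if (any(lambdas <= 0)) stop("lambdas must be positive")
  }
  fit <- .cc_lasso_logistic_path(xs, d$y, lambdas, tol, as.integer(maxit))
  rownames(fit$beta) <- colnames(d$x)
  structure(list(lambdas = lambdas, beta = fit$beta,
                 intercept = as.numeric(fit$intercept),
                 objective = fit$objective,
                 standardization = list(mean = mu, scale = sc),
                 feature_names = colnames(d$x),
                 x = d$x, y = d$y, tol = tol, maxit = maxit),
            class = "lasso_logistic_path")
}

#' @export
print.lasso_logistic_path <- function(x, ...) {
  nz <- colSums(x$beta != 0)
  cat(sprintf("<lasso_logistic_path> %d lambdas in [%.3g, %.3g], %d features\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas), nrow(x$beta)))
  cat(sprintf("  nonzero coefficients: %d (densest) .. %d (sparsest)\n",
              max(nz), min(nz)))
  invisible(x)
}

#' @export
coef.lasso_logistic_path <- function(object, s = NULL, ...) {
  i <- if (is.null(s)) length(object$lambdas) else which.min(abs(object$lambdas - s))
  c(`(Intercept)` = object$intercept[i], object$beta[, i])
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated model selection along the lasso path
#'
#' Performs k-fold cross-validation (folds stratified by class) of the
#' penalized logistic path and selects a single model: rule \code{"min"}
#' picks the \eqn{\lambda} with minimum mean CV binomial deviance; rule
#' \code{"1se"} (the default) picks the sparsest \eqn{\lambda} whose mean CV
#' deviance lies within one standard error of that minimum — sparser models
#' in that band change the classifier output very little.
#'
#' @param path a [fit_l1_logistic_path()] object fitted on the full
#'   training set.
#' @param folds number of folds, default 10.
#' @param rule \code{"1se"} (default) or \code{"min"}.
#' @param seed seed for the fold assignment.
#' @param threshold class-probability cutoff stored in the returned model.
#' @return An [outline_model] refit on the full data at the selected
#'   \eqn{\lambda}, with \code{cv} (lambda, mean deviance, SE per lambda)
#'   attached.
#' @export
cross_validate_select <- function(path, folds = 10L, rule = c("1se", "min"),
                                  seed = 1L, threshold = 0.5) {
  if (!inherits(path, "lasso_logistic_path")) stop("path must be a lasso_logistic_path")
  rule <- match.arg(rule)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  y <- path$y; x <- path$x
  if (min(table(y)) < folds)
    stop("each class needs at least `folds` samples for stratified CV")
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  fold_id <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  nl <- length(path$lambdas)
  dev <- matrix(NA_real_, folds, nl)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sub <- fit_l1_logistic_path(x[tr, , drop = FALSE], y[tr],
                                lambdas = path$lambdas,
                                tol = path$tol, maxit = path$maxit)
    xs <- sweep(sweep(x[!tr, , drop = FALSE], 2, sub$standardization$mean),
                2, sub$standardization$scale, "/")
    eta <- sweep(xs %*% sub$beta, 2, sub$intercept, "+")
    p <- 1 / (1 + exp(-eta))
    dev[f, ] <- vapply(seq_len(nl), function(l) binomial_deviance(y[!tr], p[, l]),
                       0)
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(folds)
  i_min <- which.min(cvm)
  i_sel <- if (rule == "min") i_min else
    min(which(cvm <= cvm[i_min] + cvse[i_min]))  # lambdas decreasing: first = sparsest
  beta <- path$beta[, i_sel]
  nz <- beta != 0
  outline_model(
    intercept = path$intercept[i_sel],
    coefficients = beta[nz],
    lambda = path$lambdas[i_sel],
    threshold = threshold,
    link_sign = -1,
    standardization = list(mean = path$standardization$mean[nz],
                           scale = path$standardization$scale[nz]),
    cv = list(lambda = path$lambdas, mean_deviance = cvm, se = cvse,
              rule = rule, index = i_sel))
}

#' Sparse outline classifier model
#'
#' Container for a fitted (or transcribed) sparse logistic outline
#' classifier: intercept, nonzero coefficients keyed by feature name, the
#' penalty \eqn{\lambda}, the probability cutoff, the link sign convention,
#' and the feature standardization applied at fit time.
#'
#' The linear predictor is \eqn{\eta = \beta_0 + \tilde x^T \beta} on
#' standardized features \eqn{\tilde x = (x - m)/s}. The outline probability
#' is \eqn{p = 1/(1 + e^{s_l \eta})} where \eqn{s_l} is \code{link_sign}:
#' \code{-1} (the textbook logistic, default for fitted models) makes
#' \eqn{p} increasing in \eqn{\eta}; \code{+1} matches models transcribed
#' from sources that place \eqn{+\eta} in the exponent.
#'
#' @param intercept,coefficients,lambda,threshold,link_sign,standardization,cv
#'   model fields; \code{coefficients} must be a named numeric vector and
#'   \code{standardization} a list with named \code{mean} and \code{scale}
#'   (identity, i.e. mean 0 / scale 1, for transcribed models applied to raw
#'   feature values).
#' @return An object of class \code{outline_model}.
#' @export
outline_model <- function(intercept, coefficients, lambda = NA_real_,
                          threshold = 0.5, link_sign = -1,
                          standardization = NULL, cv = NULL) {
  coefficients <- unlist(coefficients)
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named by feature")
  if (!(link_sign %in% c(-1, 1))) stop("link_sign must be -1 or +1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(standardization))
    standardization <- list(mean = stats::setNames(rep(0, length(coefficients)),
                                                   names(coefficients)),
                            scale = stats::setNames(rep(1, length(coefficients)),
                                                    names(coefficients)))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients, lambda = lambda,
                 threshold = threshold, link_sign = link_sign,
                 standardization = standardization, cv = cv),
            class = "outline_model")
}

#' @export
print.outline_model <- function(x, ...) {
  cat(sprintf("<outline_model> intercept %.4g, %d feature(s), lambda %.4g, threshold %.2f\n",
              x$intercept, length(x$coefficients), x$lambda, x$threshold))
  if (length(x$coefficients)) {
    for (nm in names(x$coefficients))
      cat(sprintf("  %-24s %+.4g\n", nm, x$coefficients[[nm]]))
  }
  invisible(x)
}

#' @export
coef.outline_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
summary.outline_model <- function(object, ...) {
  print(object)
  if (!is.null(object$cv))
    cat(sprintf("  selected by CV rule '%s' (deviance %.4g +/- %.4g)\n",
                object$cv$rule, object$cv$mean_deviance[object$cv$index],
                object$cv$se[object$cv$index]))
  invisible(object)
}

#' Predict per-pixel outline probabilities
#'
#' @param model an [outline_model].
#' @param x a \code{feature_matrix} or numeric matrix whose columns cover the
#'   model's feature names.
#' @return Numeric vector of outline probabilities, one per row of \code{x}.
#' @export
predict_outline_probability <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  need <- names(model$coefficients)
  missing <- setdiff(need, colnames(x))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  eta <- rep(model$intercept, nrow(x))
  if (length(need)) {
    xs <- sweep(sweep(x[, need, drop = FALSE], 2,
                      model$standardization$mean[need]),
                2, model$standardization$scale[need], "/")
    eta <- eta + drop(xs %*% model$coefficients)
  }
  1 / (1 + exp(model$link_sign * eta))
}

#' @export
predict.outline_model <- function(object, newdata,
                                  type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  p <- predict_outline_probability(object, newdata)
  switch(type,
         response = p,
         class = as.integer(p >= object$threshold),
         link = if (object$link_sign == -1) stats::qlogis(p) else -stats::qlogis(p))
}

#' Classify image pixels as outline / non-outline
#'
#' Computes only the features named by the model, evaluates the outline
#' probability at every pixel, and thresholds at the model's cutoff
#' (default 0.5).
#'
#' @param model an [outline_model].
#' @param img a [gray_image] (or matrix, taken as 12-bit), normally the
#'   preprocessed cytoplasm image.
#' @return Logical matrix, \code{TRUE} = outline pixel.
#' @export
classify_outlines <- function(model, img) {
  img <- as_gray_image(img)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (length(model$coefficients) == 0L) {
    p <- 1 / (1 + exp(model$link_sign * model$intercept))
    return(matrix(p >= model$threshold, nr, nc))
  }
  specs <- lapply(names(model$coefficients), parse_feature_name)
  fm <- compute_feature_matrix(img, specs)
  p <- predict_outline_probability(model, fm)
  matrix(p >= model$threshold, nr, nc)
}

#' Read / write serialized outline models
#'
#' Models are stored as JSON with fields \code{intercept},
#' \code{coefficients} (name to value map), \code{lambda}, \code{threshold},
#' \code{link_sign} and \code{standardization}. The package ships two
#' transcribed reference models under \code{system.file("models", package =
#' "cellcontour")}: \code{eq8_tc1.json} (7 features, HeLa-type images) and
#' \code{eq9_tc2.json} (5 features, Kc167-type images); both apply to raw
#' feature values (identity standardization) with \code{link_sign = +1}.
#'
#' @param path JSON file path.
#' @return \code{read_outline_model}: an [outline_model].
#' @export
read_outline_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  j <- jsonlite::fromJSON(path)
  if (is.null(j$intercept) || is.null(j$coefficients))
    stop("malformed model JSON (need intercept and coefficients): ", path)
  coefs <- unlist(j$coefficients)
  std <- if (!is.null(j$standardization))
    list(mean = unlist(j$standardization$mean)[names(coefs)],
         scale = unlist(j$standardization$scale)[names(coefs)])
  else NULL
  outline_model(intercept = j$intercept, coefficients = coefs,
                lambda = if (is.null(j$lambda)) NA_real_ else j$lambda,
                threshold = if (is.null(j$threshold)) 0.5 else j$threshold,
                link_sign = if (is.null(j$link_sign)) -1 else j$link_sign,
                standardization = std)
}

#' @rdname read_outline_model
#' @param model an [outline_model].
#' @export
write_outline_model <- function(model, path) {
  j <- list(intercept = model$intercept,
            coefficients = as.list(model$coefficients),
            lambda = model$lambda, threshold = model$threshold,
            link_sign = model$link_sign,
            standardization = list(mean = as.list(model$standardization$mean),
                                   scale = as.list(model$standardization$scale)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
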