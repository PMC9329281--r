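#' Bayesian ridge regression via the evidence approximation
#'
#' Gaussian linear model `y = X w + e` with an isotropic Gaussian prior on
#' the weights, `w ~ N(0, lambda^{-1} I)`, and Gaussian noise of precision
#' `alpha`. The two precisions carry conjugate Gamma hyperpriors and are
#' chosen by type-II maximum likelihood: iterate the closed-form posterior
#' `S = (lambda I + alpha X'X)^{-1}`, `m = alpha S X' y_c` (`y_c` the
#' centred response), effective degrees of freedom
#' `gamma = sum_j alpha l_j / (lambda + alpha l_j)` over the eigenvalues
#' `l_j` of `X'X`, then
#' `lambda <- (gamma + 2 s1) / (m'm + 2 s2)` and
#' `alpha <- (n - gamma + 2 r1) / (||y_c - X m||^2 + 2 r2)`
#' until the weights stabilise. The eigendecomposition of `X'X` is computed
#' once and reused across iterations. The intercept is handled by centring
#' `y`; `X` is expected column-standardized (the deconfounding stage
#' guarantees this), so the fitted intercept is `mean(y)`.
#'
#' @param x Numeric matrix of standardized predictors (n x p).
#' @param y Numeric response (ages, years).
#' @param alpha0,lambda0 Initial noise and weight precisions; defaults
#'   `1/var(y)` and 1.
#' @param update_hyperparams If `FALSE`, `alpha0`/`lambda0` are held fixed
#'   and the posterior mean is computed in one step (useful as a
#'   closed-form ridge with penalty `lambda0/alpha0`).
#' @param shape_lambda,rate_lambda,shape_alpha,rate_alpha Gamma hyperprior
#'   parameters (defaults `1e-6`, effectively non-informative).
#' @param tol Convergence threshold on the maximum absolute weight change.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE` with
#'   a warning, not an error.
#' @return An object of class `bayes_ridge`: `coefficients` (weights),
#'   `intercept`, `alpha` (noise precision, 1/years^2), `lambda` (weight
#'   precision), `n_iter`, `converged`, `log_evidence` (per-iteration log
#'   marginal likelihood trace), `fitted.values`, `residuals`.
#' @examples
#' x <- scale(matrix(rnorm(200), 50, 4))
#' y <- 60 + x[, 1] * 3 + rnorm(50, 0, 0.5)
#' fit <- bayes_ridge(x, y)
#' coef(fit)
#' @export
bayes_ridge <- function(x, y, alpha0 = NULL, lambda0 = 1,
                        update_hyperparams = TRUE,
                        shape_lambda = 1e-6, rate_lambda = 1e-6,
                        shape_alpha = 1e-6, rate_alpha = 1e-6,
                        tol = 1e-3, max_iter = 300L) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite")
  }
  n <- nrow(x)
  if (length(y) != n) stop("length of y does not match rows of x")
  if (n < 2L) stop("need at least 2 observations")
  p <- ncol(x)
  intercept <- mean(y)
  yc <- y - intercept

  if (is.null(alpha0)) {
    vy <- stats::var(y)
    alpha0 <- if (vy > 0) 1 / vy else 1
  }
  alpha <- alpha0
  lambda <- lambda0

  if (p == 0L) {
    return(structure(list(
      coefficients = numeric(0), intercept = intercept,
      alpha = alpha, lambda = lambda, n_iter = 0L, converged = TRUE,
      log_evidence = numeric(0),
      fitted.values = rep(intercept, n), residuals = yc,
      feature_names = character(0), call = match.call()
    ), class = "bayes_ridge"))
  }

  xtx <- crossprod(x)
  xty <- crossprod(x, yc)
  eig <- eigen(xtx, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vty <- crossprod(eig$vectors, xty)  # V' X' y, fixed across iterations

  post_mean <- function(alpha, lambda) {
    d <- lambda + alpha * ev
    drop(eig$vectors %*% (alpha * vty / d))
  }
  log_ml <- function(alpha, lambda, m) {
    rss <- sum((yc - x %*% m)^2)
    0.5 * (p * log(lambda) + n * log(alpha) -
             alpha * rss - lambda * sum(m^2) -
             sum(log(lambda + alpha * ev)) - n * log(2 * pi))
  }

  m <- post_mean(alpha, lambda)
  trace <- log_ml(alpha, lambda, m)
  converged <- !update_hyperparams
  n_iter <- 0L
  if (update_hyperparams) {
    for (it in seq_len(max_iter)) {
      gam <- sum(alpha * ev / (lambda + alpha * ev))
      rss <- sum((yc - x %*% m)^2)
      lambda <- (gam + 2 * shape_lambda) / (sum(m^2) + 2 * rate_lambda)
      alpha <- (n - gam + 2 * shape_alpha) / (rss + 2 * rate_alpha)
      m_new <- post_mean(alpha, lambda)
      trace <- c(trace, log_ml(alpha, lambda, m_new))
      n_iter <- it
      delta <- max(abs(m_new - m))
      m <- m_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning("bayes_ridge did not converge in ", max_iter, " iterations")
    }
  }

  fitted <- drop(x %*% m) + intercept
  structure(list(
    coefficients = stats::setNames(m, colnames(x)),
    intercept = intercept,
    alpha = alpha, lambda = lambda,
    n_iter = n_iter, converged = converged,
    log_evidence = trace,
    fitted.values = fitted,
    residuals = y - fitted,
    feature_names = colnames(x),
    call = match.call()
  ), class = "bayes_ridge")
}

#' Predict ages from a Bayesian ridge fit
#'
#' @param object A `bayes_ridge` fit.
#' @param newdata Matrix with the same columns (and order) as at fit time;
#'   if omitted, fitted values are returned.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (years).
#' @export
predict.bayes_ridge <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  if (length(object$coefficients) == 0L) {
    return(rep(object$intercept, nrow(newdata)))
  }
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns; fit used ",
         length(object$coefficients))
  }
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop("newdata columns do not match the fit")
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.bayes_ridge <- function(x, ...) {
  cat("Bayesian ridge (evidence approximation)\n")
  cat(sprintf("  %d features, intercept %.3f years\n",
              length(x$coefficients), x$intercept))
  cat(sprintf("  noise precision alpha = %.4g, weight precision lambda = %.4g\n",
              x$alpha, x$lambda))
  cat(sprintf("  %d iterations, %s\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.bayes_ridge <- function(object, ...) {
  w <- object$coefficients
  out <- list(
    n_features = length(w),
    intercept = object$intercept,
    alpha = object$alpha,
    lambda = object$lambda,
    effective_shrinkage = object$lambda / object$alpha,
    weight_range = if (length(w)) range(w) else c(NA_real_, NA_real_),
    n_iter = object$n_iter,
    converged = object$converged,
    final_log_evidence = utils::tail(object$log_evidence, 1L)
  )
  class(out) <- "summary.bayes_ridge"
  out
}

#' @export
print.summary.bayes_ridge <- function(x, ...) {
  cat("Bayesian ridge summary\n")
  cat(sprintf("  features: %d   intercept: %.3f\n", x$n_features, x$intercept))
  cat(sprintf("  alpha: %.4g   lambda: %.4g   ridge penalty lambda/alpha: %.4g\n",
              x$alpha, x$lambda, x$effective_shrinkage))
  cat(sprintf("  weights in [%.4g, %.4g]\n", x$weight_range[1], x$weight_range[2]))
  cat(sprintf("  log evidence: %.4f after %d iterations (%s)\n",
              x$final_log_evidence, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.bayes_ridge <- function(object, ...) object$coefficients

#' @export
residuals.bayes_ridge <- function(object, ...) object$residuals

#' Serialize a Bayesian ridge fit to JSON
#'
#' @param fit A `bayes_ridge`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
bayes_ridge_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "bayes_ridge"))
  jsonlite::write_json(list(
    weights = as.list(fit$coefficients),
    intercept = fit$intercept,
    alpha = fit$alpha,
    lambda = fit$lambda,
    n_iter = fit$n_iter,
    converged = fit$converged,
    log_evidence = fit$log_evidence
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
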