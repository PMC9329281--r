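#' Fit a confound residualizer
#'
#' Fits, per target column, an ordinary-least-squares regression on the
#' confounds (with intercept), and records the mean and standard deviation
#' of the in-sample residuals so that later applications standardize with
#' the moments learned here (strict fit/apply separation). Columns whose
#' residuals have zero variance (e.g. a column that is an exact linear
#' function of the confounds) are recorded as dropped.
#'
#' @param x Numeric matrix or data frame of target columns (features or
#'   exposures); rows aligned with `confounds`.
#' @param confounds Numeric matrix or data frame of confound columns
#'   (e.g. height, weight, or height/weight/age). Must be full rank and
#'   free of missing values.
#' @return An object of class `residualizer`: list with `coefficients`
#'   ((1 + n_confounds) x n_columns matrix), `center`/`scale` (residual
#'   moments per retained column), `confound_names`, `dropped`.
#' @examples
#' r <- residualizer(cbind(f = c(1, 2, 4)), cbind(height = c(160, 170, 180)))
#' r$coefficients
#' @export
residualizer <- function(x, confounds) {
  x <- as.matrix(x)
  confounds <- as.matrix(confounds)
  if (nrow(x) != nrow(confounds)) stop("rows of x and confounds differ")
  if (anyNA(confounds)) stop("confounds contain missing values")
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(colnames(confounds))) {
    colnames(confounds) <- paste0("C", seq_len(ncol(confounds)))
  }
  design <- cbind(`(Intercept)` = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    collinear <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("confound design matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "))
  }
  coefs <- qr.coef(qrd, x)
  resid <- qr.resid(qrd, x)
  ctr <- colMeans(resid)
  sds <- apply(resid, 2L, stats::sd)
  # relative tolerance: a column collapsing to numerical zero after the
  # projection carries no information
  tol <- 1e-10 * pmax(apply(abs(x), 2L, max), 1)
  dropped <- colnames(x)[!is.finite(sds) | sds <= tol]
  keep <- setdiff(colnames(x), dropped)
  if (length(dropped)) {
    warning("residualizer: ", length(dropped),
            " column(s) have zero residual variance and are dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  structure(list(
    coefficients = coefs,
    center = ctr[keep],
    scale = sds[keep],
    confound_names = colnames(confounds),
    columns = colnames(x),
    dropped = dropped
  ), class = "residualizer")
}

#' Apply a fitted residualizer
#'
#' Removes the confound predictions learned at fit time and standardizes
#' with the stored residual moments:
#' `(x - predicted_from_confounds - center) / scale` per retained column.
#' Dropped columns are excluded from the output.
#'
#' @param model A `residualizer`.
#' @param x Target columns; must match the columns seen at fit.
#' @param confounds Confound columns; must match the confound set at fit.
#' @return Matrix of standardized residuals (columns = retained columns).
#' @export
apply_residualizer <- function(model, x, confounds) {
  stopifnot(inherits(model, "residualizer"))
  x <- as.matrix(x)
  confounds <- as.matrix(confounds)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(colnames(confounds))) {
    colnames(confounds) <- paste0("C", seq_len(ncol(confounds)))
  }
  if (!identical(colnames(x), model$columns)) {
    stop("columns of x do not match the residualizer fit")
  }
  if (!identical(colnames(confounds), model$confound_names)) {
    stop("confound columns do not match the residualizer fit")
  }
  design <- cbind(1, confounds)
  resid <- x - design %*% model$coefficients
  keep <- setdiff(model$columns, model$dropped)
  resid <- resid[, keep, drop = FALSE]
  sweep(sweep(resid, 2L, model$center, "-"), 2L, model$scale, "/")
}

#' @export
print.residualizer <- function(x, ...) {
  cat("Confound residualizer:", length(x$columns), "column(s) on confounds {",
      paste(x$confound_names, collapse = ", "), "}\n")
  if (length(x$dropped)) {
    cat("  dropped (zero residual variance):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore a residualizer as JSON
#'
#' @param model A `residualizer`.
#' @param path File path to write to / read from.
#' @return `residualizer_to_json` returns `path` invisibly;
#'   `residualizer_from_json` returns the restored model.
#' @export
residualizer_to_json <- function(model, path) {
  stopifnot(inherits(model, "residualizer"))
  obj <- list(
    coefficients = as.data.frame(model$coefficients),
    center = as.list(model$center),
    scale = as.list(model$scale),
    confound_names = model$confound_names,
    columns = model$columns,
    dropped = model$dropped
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname residualizer_to_json
#' @export
residualizer_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  coefs <- as.matrix(obj$coefficients)
  rownames(coefs) <- c("(Intercept)", obj$confound_names)
  structure(list(
    coefficients = coefs,
    center = unlist(obj$center),
    scale = unlist(obj$scale),
    confound_names = obj$confound_names,
    columns = obj$columns,
    dropped = if (length(obj$dropped)) obj$dropped else character()
  ), class = "residualizer")
}
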