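#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' after pairwise complete-case filtering. A constant vector gives a
#' flagged not-a-value result rather than an error. The raw p-value is
#' floored at the smallest positive double, so `-log10` stays finite.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List: `r`, `p`, `n_used`, `ok` (FALSE when undefined).
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_used = n, ok = FALSE))
  }
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1)
  p <- if (r2 >= 1) {
    0
  } else {
    tt <- abs(r) * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = max(p, .Machine$double.xmin), n_used = n, ok = TRUE)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` where `m` is the number of tests in the variable's
#' family (its catalogue category, or the feature count).
#'
#' @param p_raw Raw p-value(s) in (0, 1].
#' @param m Number of tests in the family (>= 1).
#' @return Corrected p-value(s), capped at 1.
#' @export
bonferroni_p <- function(p_raw, m) {
  if (any(m < 1)) stop("family size m must be at least 1")
  pmin(1, p_raw * m)
}

# Shared machinery: deconfound each column (pairwise complete-case),
# correlate with `target`, Bonferroni-correct within the declared family.
associate_columns <- function(cols, target, confounds, m_family,
                              min_n = 100L, alpha = 0.05) {
  stopifnot(nrow(cols) == length(target), nrow(confounds) == length(target))
  out <- lapply(colnames(cols), function(v) {
    xv <- cols[, v]
    keep <- is.finite(xv) & is.finite(target) &
      apply(is.finite(as.matrix(confounds)), 1L, all)
    n_used <- sum(keep)
    if (n_used < max(min_n, 3L)) {
      return(data.frame(variable = v, n_used = n_used, r = NA_real_,
                        p_raw = NA_real_, m = m_family[[v]],
                        p_corrected = NA_real_, neg_log10_p = NA_real_,
                        significant = NA, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    }
    rz <- residualizer(matrix(xv[keep], dimnames = list(NULL, v)),
                       as.matrix(confounds)[keep, , drop = FALSE])
    if (length(rz$dropped)) {
      return(data.frame(variable = v, n_used = n_used, r = NA_real_,
                        p_raw = NA_real_, m = m_family[[v]],
                        p_corrected = NA_real_, neg_log10_p = NA_real_,
                        significant = NA, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    }
    xr <- drop(apply_residualizer(rz,
                                  matrix(xv[keep], dimnames = list(NULL, v)),
                                  as.matrix(confounds)[keep, , drop = FALSE]))
    pr <- pearson_with_p(xr, target[keep])
    if (!pr$ok) {
      return(data.frame(variable = v, n_used = n_used, r = NA_real_,
                        p_raw = NA_real_, m = m_family[[v]],
                        p_corrected = NA_real_, neg_log10_p = NA_real_,
                        significant = NA, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    }
    pc <- bonferroni_p(pr$p, m_family[[v]])
    data.frame(variable = v, n_used = pr$n_used, r = pr$r, p_raw = pr$p,
               m = m_family[[v]], p_corrected = pc,
               neg_log10_p = -log10(pc), significant = pc < alpha,
               evaluable = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Ranking rule: ascending corrected p, ties broken by descending |r|;
# non-evaluable rows go last.
rank_associations <- function(df) {
  ord <- order(!df$evaluable, df$p_corrected, -abs(df$r),
               df$variable, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Profile radiomics feature associations with heart age
#'
#' Correlates each radiomics feature with biological heart age (the
#' bias-corrected CPHA by default) after residualizing height, weight and
#' age from the features. P-values are Bonferroni-corrected by the number
#' of features tested, and the table is ranked "most informative first":
#' ascending corrected p, ties broken by descending `|r|`.
#'
#' @param features Raw feature matrix (not deconfounded; the stated
#'   confounds are regressed out here).
#' @param heart_age_vec Per-participant biological heart age, years.
#' @param confounds Data frame or matrix with height, weight and age
#'   columns aligned with `features`.
#' @param manifest Optional `feature_manifest`; category/region are carried
#'   into the result.
#' @param alpha Significance level on the corrected p (default 0.05).
#' @return A data frame of class `association_result`, one row per
#'   feature: `variable`, optional `category`/`region`, `n_used`, `r`,
#'   `p_raw`, `m`, `p_corrected`, `neg_log10_p`, `significant`, `rank`.
#' @export
profile_feature_age <- function(features, heart_age_vec, confounds,
                                manifest = NULL, alpha = 0.05) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  if (ncol(features) == 0L) stop("feature family is empty")
  m_fam <- stats::setNames(rep(ncol(features), ncol(features)),
                           colnames(features))
  df <- associate_columns(features, heart_age_vec, confounds, m_fam,
                          min_n = 3L, alpha = alpha)
  if (!is.null(manifest)) {
    i <- match(df$variable, manifest$feature_id)
    df$category <- manifest$category[i]
    df$region <- manifest$region[i]
  }
  df <- rank_associations(df)
  class(df) <- c("association_result", "data.frame")
  df
}

#' Phenome-wide association study of exposures with heart-age delta
#'
#' For the requested sex, filters the catalogue to applicable variables,
#' regresses the stated confounds (age, height, weight) from each exposure
#' (pairwise complete-case), correlates the deconfounded exposure with the
#' heart-age delta, and applies a per-category Bonferroni correction: each
#' raw p is multiplied by the number of catalogue variables in its
#' category for that sex. A positive `r` means increasing exposure levels
#' accompany a larger heart-age delta (older-than-actual heart). Variables
#' with fewer than `min_n` usable observations are reported but flagged
#' not evaluable.
#'
#' @param delta Heart-age deltas, years (one per row of `exposures`).
#' @param exposures Numeric matrix of exposures, columns named by
#'   catalogue variable ids (`NA`s allowed).
#' @param catalogue An `exposure_catalogue`.
#' @param confounds Data frame or matrix with age, height, weight columns.
#' @param sex `"female"` or `"male"`; selects applicable variables.
#' @param min_n Minimum pairwise-complete sample size (default 100).
#' @param alpha Significance level on the corrected p (default 0.05).
#' @return A data frame of class `phewas_result`: one row per applicable
#'   variable with `variable`, `category`, `n_used`, `r`, `p_raw`, `m`,
#'   `p_corrected`, `neg_log10_p`, `significant`, `rank` (within
#'   category).
#' @export
phewas <- function(delta, exposures, catalogue, confounds, sex,
                   min_n = 100L, alpha = 0.05) {
  sex <- match.arg(sex, c("female", "male"))
  catalogue <- validate_catalogue(catalogue)
  exposures <- as.matrix(exposures)
  applicable <- catalogue[catalogue$sex_applicability %in% c("both", sex), ,
                          drop = FALSE]
  missing_cols <- setdiff(applicable$variable_id, colnames(exposures))
  if (length(missing_cols)) {
    stop("exposure table lacks catalogue variable(s): ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  fam_sizes <- table(applicable$category)
  m_fam <- stats::setNames(as.integer(fam_sizes[applicable$category]),
                           applicable$variable_id)
  cols <- exposures[, applicable$variable_id, drop = FALSE]
  df <- associate_columns(cols, delta, confounds, m_fam,
                          min_n = min_n, alpha = alpha)
  df$category <- applicable$category[match(df$variable,
                                           applicable$variable_id)]
  df <- do.call(rbind, lapply(split(df, df$category), rank_associations))
  rownames(df) <- NULL
  df <- df[order(df$category, df$rank), ]
  rownames(df) <- NULL
  class(df) <- c("phewas_result", "association_result", "data.frame")
  attr(df, "sex") <- sex
  df
}

#' @export
print.association_result <- function(x, n = 10L, ...) {
  cat("Association results:", nrow(x), "variables;",
      sum(x$significant, na.rm = TRUE), "significant after Bonferroni\n")
  print.data.frame(utils::head(x[order(x$p_corrected), ], n), digits = 3,
                   row.names = FALSE)
  if (nrow(x) > n) cat("  ... (", nrow(x) - n, " more rows)\n", sep = "")
  invisible(x)
}

#' Manhattan-style plot of association results
#'
#' Plots `-log10` corrected p per variable, grouped by category where
#' present, with the significance threshold line.
#'
#' @param x An `association_result` or `phewas_result`.
#' @param alpha Significance level (default 0.05).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.association_result <- function(x, alpha = 0.05, ...) {
  grp <- if (!is.null(x$category)) factor(x$category) else factor("all")
  ok <- x$evaluable & is.finite(x$neg_log10_p)
  graphics::plot(seq_len(nrow(x))[ok], x$neg_log10_p[ok],
                 col = as.integer(grp)[ok], pch = 16, cex = 0.6,
                 xlab = "Variable", ylab = "-log10 corrected p", ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}
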