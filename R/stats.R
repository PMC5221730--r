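#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank ties. The two-sided p-value is exact
#' (from the null U distribution) when there are no ties and
#' `n1 * n2 <= 400`; otherwise a normal approximation with tie correction
#' and continuity correction is used. `U` counts the pairs in which `x`
#' exceeds `y` (midranks contribute 1/2).
#'
#' @param x,y Numeric samples (non-empty).
#' @return One-row tibble: `u`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p <- 2 * min(pwilcox(u, n1, n2), pwilcox(n1 * n2 - u, n1, n2))
    p <- min(p, 1)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    if (sigma == 0) return(tibble(u = u, p_value = 1, method = "degenerate"))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(2 * stats::pnorm(-abs(z)), 1)
    method <- "normal_tie_corrected"
  }
  tibble(u = u, p_value = p, method = method)
}

#' Partial correlation of predictors with an outcome
#'
#' For each predictor, the Pearson correlation between the residuals of the
#' outcome and of that predictor after linear regression of both on all the
#' remaining predictors (computed through the precision matrix of
#' `[y, X]`).
#'
#' @param data Data frame containing the predictors and outcome.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns (default: the
#'   eleven sampled conductances present in `data`).
#' @return An `af_pcr` tibble: `term`, `pcr`, with attribute `outcome`.
#' @export
partial_correlation <- function(data, outcome,
                                predictors = NULL) {
  if (is.null(predictors))
    predictors <- intersect(conductance_names(), names(data))
  if (!outcome %in% names(data)) abort(paste0("missing outcome: ", outcome))
  miss <- setdiff(predictors, names(data))
  if (length(miss))
    abort(paste0("missing predictor(s): ", paste(miss, collapse = ", ")))
  d <- data[stats::complete.cases(data[, c(outcome, predictors)]),
            c(outcome, predictors), drop = FALSE]
  X <- as.matrix(d[, predictors, drop = FALSE])
  y <- d[[outcome]]
  if (nrow(X) < length(predictors) + 2)
    abort("need at least (number of predictors + 2) complete rows")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    abort(paste0("constant predictor(s): ",
                 paste(predictors[sds == 0], collapse = ", ")))
  qr_pred <- qr(scale(X))
  if (qr_pred$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_pred$pivot[(qr_pred$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(drop_cols, collapse = ", ")))
  }
  M <- cbind(y, X)
  if (qr(scale(M))$rank == ncol(M)) {
    P <- solve(cor(M))
    pcr <- -P[1, -1] / sqrt(P[1, 1] * diag(P)[-1])
  } else {
    # outcome perfectly explained by the predictors: the precision matrix is
    # singular, but the residual definition is still well posed
    pcr <- vapply(seq_len(ncol(X)), function(j) {
      Z <- cbind(1, X[, -j, drop = FALSE])
      ry <- stats::lm.fit(Z, y)$residuals
      rx <- stats::lm.fit(Z, X[, j])$residuals
      if (sd(ry) == 0 || sd(rx) == 0) return(0)
      cor(ry, rx)
    }, numeric(1))
  }
  out <- tibble(term = predictors, pcr = unname(pcr))
  attr(out, "outcome") <- outcome
  attr(out, "n") <- nrow(d)
  class(out) <- c("af_pcr", class(out))
  out
}

#' Compare conductance distributions between outcome groups
#'
#' One Mann-Whitney comparison per scale factor between the two levels of a
#' logical outcome (e.g. sustained vs unsustained reentry, or terminated vs
#' persisting under block), with group medians and interquartile ranges.
#' No multiple-testing correction is applied by default (a fixed two-sided
#' alpha across the eleven comparisons); set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param data Data frame with the factor columns and the outcome column.
#' @param outcome Name of a logical column.
#' @param factors Factor columns (default: sampled conductances present).
#' @param alpha Significance level (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An `af_group_comparison` tibble: one row per factor with group
#'   medians/IQRs, `u`, `p_value`, `significant`.
#' @export
build_group_comparison <- function(data, outcome, factors = NULL,
                                   alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(factors))
    factors <- intersect(conductance_names(), names(data))
  if (!outcome %in% names(data)) abort(paste0("missing outcome: ", outcome))
  g <- data[[outcome]]
  if (!is.logical(g)) abort("outcome must be a logical column")
  if (all(g) || all(!g))
    abort("both outcome groups must be non-empty")
  rows <- purrr::map(factors, function(f) {
    a <- data[[f]][g]; b <- data[[f]][!g]
    mw <- mann_whitney_u(a, b)
    tibble(term = f,
           median_true = median(a), iqr_true = stats::IQR(a),
           median_false = median(b), iqr_false = stats::IQR(b),
           u = mw$u, p_value = mw$p_value)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  attr(out, "outcome") <- outcome
  attr(out, "alpha") <- alpha
  attr(out, "n_true") <- sum(g)
  attr(out, "n_false") <- sum(!g)
  class(out) <- c("af_group_comparison", class(out))
  out
}

#' Signed coefficient of determination between two variables
#'
#' Pearson correlation reported in signed "R^2 = r" style used for
#' DF-vs-RM couplings: the magnitude is the correlation coefficient and the
#' sign carries the direction (this is a signed coefficient, not a literal
#' square).
#'
#' @param x,y Numeric vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
signed_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  cor(x[keep], y[keep])
}
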