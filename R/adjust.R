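#' Remove covariate effects from every ROI column
#'
#' Fits an ordinary least-squares model of each ROI's thickness on an
#' intercept plus all covariate columns (age, gender, education by default),
#' pooled across both groups, and replaces the column by its residuals.
#' Pooled (group-blind) adjustment keeps subjects exchangeable under the
#' permutation null used downstream. Residual columns have mean zero.
#'
#' @param thickness a [thickness_table()].
#' @param covs a [covariate_table()] covering every subject.
#' @return a residualized `thickness_table`.
#' @export
residualize <- function(thickness, covs) {
  stopifnot(inherits(thickness, "thickness_table"))
  X0 <- covariate_matrix(covs, thickness$subject_id)
  vars <- colnames(X0)
  sds <- apply(X0, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate makes the design rank-deficient: ",
         paste(vars[sds == 0], collapse = ", "))
  X <- cbind(`(Intercept)` = 1, X0)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; linearly dependent: ",
         paste(dropped, collapse = ", "))
  }
  resid <- thickness$values - X %*% qr.coef(qx, thickness$values)
  out <- thickness
  out$values <- resid
  out$residualized <- TRUE
  out
}

#' Per-ROI two-sample comparison of group mean thickness
#'
#' Welch's unequal-variance t-test per ROI by default (set
#' `var_equal = TRUE` for the pooled-variance version). ROIs with zero
#' variance in both groups and equal means are reported with t = 0, p = 1 and
#' flagged.
#'
#' @param thickness a [thickness_table()] (raw or residualized).
#' @param var_equal use pooled variance instead of Welch.
#' @return data.frame with one row per ROI: `roi`, `mean_g1`, `mean_g2`,
#'   `t`, `df`, `p`, `zero_variance`.
#' @export
roi_group_test <- function(thickness, var_equal = FALSE) {
  stopifnot(inherits(thickness, "thickness_table"))
  g <- thickness$group
  v1 <- thickness$values[g == levels(g)[1], , drop = FALSE]
  v2 <- thickness$values[g == levels(g)[2], , drop = FALSE]
  n1 <- nrow(v1); n2 <- nrow(v2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 subjects")
  m1 <- colMeans(v1); m2 <- colMeans(v2)
  s1 <- apply(v1, 2, stats::var); s2 <- apply(v2, 2, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(s1 / n1 + s2 / n2)
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  }
  zerovar <- se == 0
  tstat <- ifelse(zerovar & m1 == m2, 0,
                  ifelse(zerovar, sign(m1 - m2) * Inf, (m1 - m2) / se))
  df[zerovar] <- n1 + n2 - 2
  p <- ifelse(zerovar & m1 == m2, 1, 2 * pt(-abs(tstat), df))
  data.frame(roi = thickness$roi_labels, mean_g1 = m1, mean_g2 = m2,
             t = tstat, df = df, p = p, zero_variance = zerovar,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partial correlation of two subject-level variables given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing both
#' on an intercept plus the covariates; the two-tailed p-value uses a t
#' reference distribution with n - 2 - k degrees of freedom (k covariates).
#' With no covariates this reduces exactly to the plain Pearson correlation
#' test.
#'
#' @param x,y numeric vectors over the same subjects.
#' @param covs optional [covariate_table()] or numeric matrix/data.frame
#'   aligned with `x`; `NULL` for plain correlation.
#' @param subject_id subject ids used to align a `covariate_table`; required
#'   when `covs` carries a `subject_id` column.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covs = NULL, subject_id = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain missing values")
  if (is.null(covs)) {
    C <- NULL
  } else if (inherits(covs, "covariate_table") ||
             (is.data.frame(covs) && "subject_id" %in% names(covs))) {
    if (is.null(subject_id))
      stop("subject_id is required to align a covariate table")
    C <- covariate_matrix(covs, subject_id)
  } else {
    C <- as.matrix(covs)
  }
  k <- if (is.null(C)) 0L else ncol(C)
  if (n <= k + 2)
    stop(sprintf("need n > k + 2 subjects (n = %d, k = %d)", n, k))
  if (!is.null(C)) {
    X <- cbind(1, C)
    qx <- qr(X)
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = p, df = df, n = n)
}
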