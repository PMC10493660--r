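#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of a topological property across the density grid,
#' giving a single threshold-free summary per metric (units: metric-units x
#' density).
#'
#' @param values numeric vector with one finite value per grid density.
#' @param grid a [density_grid()].
#' @return the trapezoidal AUC.
#' @export
metric_auc <- function(values, grid) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$densities
  if (length(values) != length(d))
    stop(sprintf("need one value per density (%d != %d)",
                 length(values), length(d)))
  if (anyNA(values) || any(!is.finite(values)))
    stop("metric values must all be finite")
  sum(diff(d) * (values[-1] + values[-length(values)]) / 2)
}

# rowwise trapezoid for an N x ndens matrix of curves
row_auc <- function(mat, d) {
  w <- diff(d)
  as.numeric(mat[, -1, drop = FALSE] %*% w +
               mat[, -ncol(mat), drop = FALSE] %*% w) / 2
}

#' Benjamini-Hochberg discovery flags
#'
#' Step-up false discovery rate control at level `alpha` over a family of
#' p-values (Benjamini-Yekutieli available for dependence-robust control).
#'
#' @param p_values p-values in (0, 1].
#' @param alpha FDR level.
#' @param method `"BH"` (default) or `"BY"`.
#' @return logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_correct <- function(p_values, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("empty p-value list")
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = method) <= alpha
}

# mean rewired-ensemble cp/lp at every density, for sigma normalization
ensemble_means_curve <- function(w, kvec, N, n_random, iter_per_edge) {
  ord <- cpp_edge_order(w)
  cp_m <- numeric(length(kvec))
  lp_m <- numeric(length(kvec))
  for (d in seq_along(kvec)) {
    k <- kvec[d]
    g <- igraph::make_empty_graph(N, directed = FALSE)
    g <- igraph::add_edges(g, t(ord[seq_len(k), , drop = FALSE]))
    niter <- max(1L, as.integer(iter_per_edge * k))
    cps <- numeric(n_random)
    lps <- numeric(n_random)
    for (i in seq_len(n_random)) {
      rg <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      A <- as.matrix(igraph::as_adjacency_matrix(rg, type = "both",
                                                 sparse = FALSE))
      storage.mode(A) <- "integer"
      m <- cpp_graph_metrics(A, spl = TRUE, bc = FALSE, cp = TRUE,
                             eloc = FALSE)
      cps[i] <- m$cp
      lps[i] <- m$lp
    }
    cp_m[d] <- mean(cps)
    lp_m[d] <- mean(lps)
  }
  list(cp = cp_m, lp = lp_m)
}

GLOBAL_METRICS <- c("eglob", "eloc", "cp", "lp", "sigma")
REGIONAL_METRICS <- c("degree", "betweenness", "nodal_efficiency")

#' Compare two groups' structural covariance networks by permutation
#'
#' The central inference routine. For each group it builds the Pearson
#' covariance matrix of the (residualized) ROI thickness columns, binarizes
#' it at every density of the grid, computes the selected topological
#' properties, and summarizes each property by its area under the curve
#' (AUC) across densities. The observed group-1 minus group-2 AUC difference
#' is then referred to a permutation null distribution obtained by randomly
#' relabeling subjects (group sizes preserved) and rerunning the entire
#' covariance -> binarize -> metrics -> AUC pipeline. Covariate
#' residualization, when requested, is done once on the pooled sample before
#' permuting, which keeps subjects exchangeable under the null.
#'
#' Significance is reported two ways, mirroring common practice: an add-one
#' permutation p-value, `p = (1 + #{|null| >= |observed|}) / (1 + P)`, and a
#' 95% confidence-interval rule (`significant` is `TRUE` when the observed
#' difference falls outside the null's 2.5th-97.5th percentile band). For
#' regional (per-ROI) metrics, Benjamini-Hochberg FDR across ROIs is applied
#' per metric (`fdr_significant`).
#'
#' @param thickness a [thickness_table()]. If not already residualized and
#'   `covariates` is supplied, [residualize()] is applied first.
#' @param covariates optional [covariate_table()].
#' @param grid a [density_grid()]; defaults to `density_grid(n_rois)`.
#' @param metrics character vector from `eglob`, `eloc`, `cp`, `lp`,
#'   `sigma`, `degree`, `betweenness`, `nodal_efficiency`.
#' @param n_perm number of permutations P (>= 40; the study-scale default is
#'   5000).
#' @param alpha significance / FDR level.
#' @param seed RNG seed; the whole run is deterministic given it.
#' @param sigma_n_random,sigma_iter_per_edge rewired-ensemble parameters used
#'   when `sigma` is selected.
#' @param sigma_null `"regenerate"` builds a fresh rewired ensemble inside
#'   every permutation (exact but slow); `"reuse"` normalizes all
#'   permutations by the observed groups' ensemble means.
#' @param fdr_method passed to [fdr_correct()].
#' @param keep_null which null AUC-difference distributions to keep in the
#'   returned object (`"global"` keeps only global metrics; regional nulls
#'   for hundreds of ROIs are large).
#' @return object of class `scn_compare` with elements `results` (one row
#'   per statistic), `null` (matrix of kept null differences), `curves`
#'   (observed global metric-versus-density curves per group), `grid`,
#'   `n_perm`, `alpha`, `seed`, `groups`.
#' @export
scn_compare <- function(thickness, covariates = NULL, grid = NULL,
                        metrics = c("eglob", "eloc", "cp", "lp", "sigma",
                                    "degree", "betweenness",
                                    "nodal_efficiency"),
                        n_perm = 5000, alpha = 0.05, seed = 1,
                        sigma_n_random = 100, sigma_iter_per_edge = 10,
                        sigma_null = c("regenerate", "reuse"),
                        fdr_method = "BH",
                        keep_null = c("global", "all", "none")) {
  stopifnot(inherits(thickness, "thickness_table"))
  sigma_null <- match.arg(sigma_null)
  keep_null <- match.arg(keep_null)
  bad <- setdiff(metrics, c(GLOBAL_METRICS, REGIONAL_METRICS))
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "))
  if (n_perm < 40)
    stop("n_perm must be >= 40 for a 95% permutation interval")
  if (!is.null(covariates) && !thickness$residualized)
    thickness <- residualize(thickness, covariates)

  # canonical subject order: results do not depend on input row order
  ordr <- order(as.integer(thickness$group), thickness$subject_id)
  vals <- thickness$values[ordr, , drop = FALSE]
  grp <- thickness$group[ordr]
  lev <- levels(grp)
  n1 <- sum(grp == lev[1])
  n2 <- sum(grp == lev[2])
  if (min(n1, n2) < 3) stop("each group needs at least 3 subjects")
  ntot <- n1 + n2
  N <- ncol(vals)
  labels <- thickness$roi_labels

  if (is.null(grid)) grid <- density_grid(N)
  dens <- grid$densities
  kvec <- vapply(dens, edges_at_density, integer(1), N = N)

  gsel <- intersect(GLOBAL_METRICS, metrics)
  rsel <- intersect(REGIONAL_METRICS, metrics)
  want_sigma <- "sigma" %in% gsel
  need_bc <- "betweenness" %in% rsel
  need_spl <- need_bc || any(c("eglob", "lp", "sigma") %in% gsel) ||
    "nodal_efficiency" %in% rsel
  need_cp <- any(c("cp", "sigma") %in% gsel)
  need_eloc <- "eloc" %in% gsel
  need_deg <- "degree" %in% rsel

  stat_names <- c(gsel,
                  unlist(lapply(rsel, function(m) paste(m, labels, sep = "|"))))
  nstat <- length(stat_names)
  if (nstat == 0) stop("no metrics selected")

  group_stats <- function(v1, v2, ref_means = NULL, return_curves = FALSE) {
    out <- vector("list", 2)
    curves <- vector("list", 2)
    for (gi in 1:2) {
      v <- if (gi == 1) v1 else v2
      r <- cor(v)
      diag(r) <- 0
      w <- abs(r)
      gm <- cpp_grid_metrics(w, kvec, need_spl, need_bc, need_cp,
                             need_eloc, need_deg)
      glob <- gm$global
      sig_curve <- NULL
      if (want_sigma) {
        em <- if (!is.null(ref_means)) ref_means[[gi]] else
          ensemble_means_curve(w, kvec, N, sigma_n_random,
                               sigma_iter_per_edge)
        sig_curve <- (glob[, "cp"] / em$cp) / (glob[, "lp"] / em$lp)
      }
      aucs <- numeric(0)
      for (m in gsel) {
        cv <- if (m == "sigma") sig_curve else glob[, m]
        aucs <- c(aucs, metric_auc(cv, grid))
      }
      for (m in rsel) {
        cm <- switch(m, degree = gm$degree, betweenness = gm$betweenness,
                     nodal_efficiency = gm$nodal_efficiency)
        aucs <- c(aucs, row_auc(cm, dens))
      }
      out[[gi]] <- aucs
      if (return_curves)
        curves[[gi]] <- cbind(glob,
                              if (want_sigma) cbind(sigma = sig_curve))
    }
    list(auc1 = out[[1]], auc2 = out[[2]], curves = curves)
  }

  set.seed(seed)
  perm_idx <- matrix(0L, n_perm, ntot)
  for (p in seq_len(n_perm)) perm_idx[p, ] <- sample.int(ntot)

  # observed statistics (and, with sigma_null = "reuse", the ensemble means
  # that every permutation will share)
  reuse_means <- NULL
  if (want_sigma && sigma_null == "reuse") {
    reuse_means <- lapply(list(vals[seq_len(n1), , drop = FALSE],
                               vals[n1 + seq_len(n2), , drop = FALSE]),
                          function(v) {
                            r <- cor(v); diag(r) <- 0
                            ensemble_means_curve(abs(r), kvec, N,
                                                 sigma_n_random,
                                                 sigma_iter_per_edge)
                          })
  }
  obs <- group_stats(vals[seq_len(n1), , drop = FALSE],
                     vals[n1 + seq_len(n2), , drop = FALSE],
                     ref_means = reuse_means, return_curves = TRUE)
  obs_diff <- obs$auc1 - obs$auc2

  null_diff <- matrix(NA_real_, n_perm, nstat)
  for (p in seq_len(n_perm)) {
    idx <- perm_idx[p, ]
    st <- group_stats(vals[idx[seq_len(n1)], , drop = FALSE],
                      vals[idx[n1 + seq_len(n2)], , drop = FALSE],
                      ref_means = reuse_means)
    null_diff[p, ] <- st$auc1 - st$auc2
  }
  colnames(null_diff) <- stat_names

  pvals <- (1 + colSums(abs(null_diff) >= rep(abs(obs_diff),
                                              each = n_perm))) / (1 + n_perm)
  ci <- apply(null_diff, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  signif_ci <- obs_diff < ci[1, ] | obs_diff > ci[2, ]

  scope <- c(rep("global", length(gsel)),
             rep("roi", length(rsel) * length(labels)))
  metric_col <- c(gsel, rep(rsel, each = length(labels)))
  roi_col <- c(rep(NA_character_, length(gsel)),
               rep(labels, times = length(rsel)))
  fdr_flag <- rep(NA, nstat)
  for (m in rsel) {
    sel <- which(metric_col == m)
    fdr_flag[sel] <- fdr_correct(pvals[sel], alpha = alpha,
                                 method = fdr_method)
  }
  results <- data.frame(scope = scope, metric = metric_col, roi = roi_col,
                        auc_g1 = obs$auc1, auc_g2 = obs$auc2,
                        diff = obs_diff, p = pvals,
                        ci_low = ci[1, ], ci_high = ci[2, ],
                        significant = signif_ci, fdr_significant = fdr_flag,
                        row.names = NULL, stringsAsFactors = FALSE)

  kept_null <- switch(keep_null,
                      all = null_diff,
                      global = null_diff[, scope == "global", drop = FALSE],
                      none = NULL)
  curves <- lapply(obs$curves, function(cm) {
    rownames(cm) <- NULL
    cm
  })
  names(curves) <- lev
  structure(list(results = results, null = kept_null, curves = curves,
                 grid = grid, n_perm = n_perm, alpha = alpha, seed = seed,
                 metrics = metrics,
                 groups = stats::setNames(c(n1, n2), lev),
                 fdr_method = fdr_method, call = match.call()),
            class = "scn_compare")
}
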