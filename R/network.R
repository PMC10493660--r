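#' Group structural covariance matrix
#'
#' Pearson correlation across subjects between every pair of ROI thickness
#' columns, computed within a single group. The diagonal is set to zero by
#' definition (self-edges carry no information).
#'
#' @param thickness a [thickness_table()]; when it holds two groups, `group`
#'   selects which one. A plain subjects-x-ROIs matrix is also accepted.
#' @param group group level to restrict to (default: first level).
#' @return object of class `scn_cov`: list with `r` (ROI x ROI), `n_subjects`,
#'   `roi_labels`.
#' @export
scn_covariance <- function(thickness, group = NULL) {
  if (inherits(thickness, "thickness_table")) {
    g <- thickness$group
    group <- group %||% levels(g)[1]
    if (!group %in% levels(g)) stop("unknown group: ", group)
    v <- thickness$values[g == group, , drop = FALSE]
    labels <- thickness$roi_labels
  } else {
    v <- as.matrix(thickness)
    labels <- colnames(v) %||% sprintf("ROI_%03d", seq_len(ncol(v)))
  }
  if (nrow(v) < 3) stop("need at least 3 subjects to estimate covariance")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant ROI column(s): ", paste(labels[sds == 0], collapse = ", "))
  r <- cor(v)
  diag(r) <- 0
  dimnames(r) <- list(labels, labels)
  structure(list(r = r, n_subjects = nrow(v), roi_labels = labels),
            class = "scn_cov")
}

#' @export
print.scn_cov <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("scn_cov: %d ROIs, n = %d subjects; |r| median %.3f, max %.3f\n",
              length(x$roi_labels), x$n_subjects,
              stats::median(abs(off)), max(abs(off))))
  invisible(x)
}

#' Density grid for network thresholding
#'
#' The minimum density is 2*log10(N)/(N-1) rounded up to the next multiple of
#' `step` (this keeps the sparsest network estimable while the grid stays
#' aligned to the step); the grid then runs in `step` increments up to
#' `d_max`. For N = 360 ROIs with the defaults this gives 0.02, 0.03, ...,
#' 0.47 (46 points).
#'
#' @param n_rois number of network nodes (>= 3).
#' @param d_max upper end of the grid, fraction in (0, 1).
#' @param step grid spacing, fraction.
#' @param log_base base of the logarithm in the minimum-density formula;
#'   base 10 is the default.
#' @return object of class `density_grid`: list with `densities`, `step`,
#'   `d_min`, `d_max` and the unrounded `d_min_raw`.
#' @export
density_grid <- function(n_rois, d_max = 0.47, step = 0.01, log_base = 10) {
  if (n_rois < 3) stop("n_rois must be >= 3")
  if (!(step > 0 && step < d_max && d_max < 1))
    stop("require 0 < step < d_max < 1")
  d_min_raw <- 2 * log(n_rois, base = log_base) / (n_rois - 1)
  d_min <- ceiling(d_min_raw / step - 1e-9) * step
  d_min <- round(d_min, 10)
  if (d_min >= d_max)
    stop(sprintf("minimum density %.4g is not below d_max = %.4g", d_min, d_max))
  densities <- round(seq(d_min, d_max + 1e-9, by = step), 10)
  densities <- densities[densities <= d_max + 1e-9]
  structure(list(densities = densities, step = step, d_min = d_min,
                 d_max = max(densities), d_min_raw = d_min_raw),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %.3g to %.3g by %.3g (%d points)\n",
              x$d_min, x$d_max, x$step, length(x$densities)))
  invisible(x)
}

n_pairs <- function(N) N * (N - 1) / 2

edges_at_density <- function(density, N) {
  k <- round(density * n_pairs(N))
  if (k < 1)
    stop(sprintf("density %.4g yields no edges for %d nodes", density, N))
  as.integer(min(k, n_pairs(N)))
}

#' Binarize a covariance matrix at an exact edge density
#'
#' Connects the `k = round(density * N(N-1)/2)` node pairs with the largest
#' absolute correlation, so the requested density is realized exactly. Ties
#' in |r| are broken by (row, column) order, making the edge set
#' deterministic; the families of networks produced over a grid are nested
#' (the edge set at a lower density is a subset of that at any higher one).
#'
#' @param cov an [scn_covariance()] result.
#' @param density target edge density in (0, 1).
#' @param positive_only if `TRUE`, only positive correlations are eligible
#'   (edges are still ranked by magnitude); by default the absolute value is
#'   used so strong negative covariance also forms an edge.
#' @return object of class `scn_network`: list with binary `adjacency`
#'   (0/1 integer matrix, zero diagonal), realized `density`, `roi_labels`.
#' @export
scn_binarize <- function(cov, density, positive_only = FALSE) {
  stopifnot(inherits(cov, "scn_cov"))
  if (!(density > 0 && density < 1)) stop("density must lie in (0, 1)")
  N <- length(cov$roi_labels)
  k <- edges_at_density(density, N)
  w <- if (positive_only) pmax(cov$r, 0) else abs(cov$r)
  ord <- cpp_edge_order(w)
  A <- matrix(0L, N, N, dimnames = list(cov$roi_labels, cov$roi_labels))
  sel <- ord[seq_len(k), , drop = FALSE]
  A[sel] <- 1L
  A[sel[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(adjacency = A, density = k / n_pairs(N),
                 target_density = density, roi_labels = cov$roi_labels),
            class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf("scn_network: %d nodes, %d edges (density %.4f)\n",
              length(x$roi_labels), sum(x$adjacency) / 2, x$density))
  invisible(x)
}

#' Truncate a density grid where the reference group stops being small-world
#'
#' Evaluates the small-worldness index (sigma) of the reference (control)
#' group's network at every candidate density and truncates the grid at the
#' largest density where sigma >= `sigma_min`. This implements the common
#' rule that the density range should only extend as far as the control
#' network retains small-world organization.
#'
#' @param cov_reference [scn_covariance()] of the reference (control) group.
#' @param grid_candidate a [density_grid()].
#' @param sigma_min minimum admissible small-worldness (default 1.1).
#' @param n_random,iter_per_edge rewired-ensemble parameters passed to
#'   [reference_ensemble()].
#' @param seed RNG seed for the ensembles.
#' @return the truncated `density_grid`, with the per-density sigma values in
#'   attribute `"sigma"`.
#' @export
sigma_bounded_dmax <- function(cov_reference, grid_candidate, sigma_min = 1.1,
                               n_random = 100, iter_per_edge = 10,
                               seed = NULL) {
  stopifnot(inherits(cov_reference, "scn_cov"),
            inherits(grid_candidate, "density_grid"))
  dens <- grid_candidate$densities
  sig <- vapply(seq_along(dens), function(i) {
    net <- scn_binarize(cov_reference, dens[i])
    ref <- reference_ensemble(net, n_random = n_random,
                              iter_per_edge = iter_per_edge,
                              seed = if (is.null(seed)) NULL else seed + i)
    global_metrics(net, ref)$sigma
  }, numeric(1))
  ok <- which(sig >= sigma_min)
  if (!length(ok))
    stop(sprintf("no candidate density reaches sigma >= %.3g", sigma_min))
  keep <- seq_len(max(ok))
  out <- grid_candidate
  out$densities <- dens[keep]
  out$d_max <- max(out$densities)
  attr(out, "sigma") <- sig
  out
}
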