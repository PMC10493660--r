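#' @export
print.scn_compare <- function(x, ...) {
  g <- x$groups
  cat(sprintf("Structural covariance network comparison: %s (n=%d) vs %s (n=%d)\n",
              names(g)[1], g[1], names(g)[2], g[2]))
  cat(sprintf("  densities %.3g-%.3g (%d points), %d permutations, alpha = %g\n",
              x$grid$d_min, x$grid$d_max, length(x$grid$densities),
              x$n_perm, x$alpha))
  glob <- x$results[x$results$scope == "global", ]
  if (nrow(glob)) {
    cat("  global AUC differences (group1 - group2):\n")
    for (i in seq_len(nrow(glob)))
      cat(sprintf("    %-6s %+ .4g  (p = %.4g%s)\n", glob$metric[i],
                  glob$diff[i], glob$p[i],
                  if (glob$significant[i]) ", outside 95% null CI" else ""))
  }
  roi <- x$results[x$results$scope == "roi", ]
  if (nrow(roi)) {
    nsig <- sum(roi$fdr_significant)
    cat(sprintf("  regional: %d of %d ROI statistics FDR-significant\n",
                nsig, nrow(roi)))
  }
  invisible(x)
}

#' Summarize a network comparison
#'
#' @param object an [scn_compare()] result.
#' @param only_significant if `TRUE` (default) the regional table is limited
#'   to FDR-significant ROIs.
#' @param ... unused.
#' @return list with `global` and `regional` data.frames.
#' @export
summary.scn_compare <- function(object, only_significant = TRUE, ...) {
  res <- object$results
  glob <- res[res$scope == "global", setdiff(names(res), c("roi", "fdr_significant"))]
  roi <- res[res$scope == "roi", ]
  if (only_significant) roi <- roi[which(roi$fdr_significant), ]
  roi <- roi[order(roi$p), ]
  out <- list(global = glob, regional = roi, n_perm = object$n_perm,
              alpha = object$alpha, groups = object$groups)
  class(out) <- "summary.scn_compare"
  out
}

#' @export
print.summary.scn_compare <- function(x, ...) {
  cat("Global network properties (AUC over densities):\n")
  print(x$global, row.names = FALSE, digits = 4)
  cat(sprintf("\nRegional properties (FDR-significant, alpha = %g):\n", x$alpha))
  if (nrow(x$regional)) print(x$regional, row.names = FALSE, digits = 4)
  else cat("  none\n")
  invisible(x)
}

#' Plot observed global metric curves across densities
#'
#' One panel per selected global property showing the metric-versus-density
#' curve for both groups.
#'
#' @param x an [scn_compare()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scn_compare <- function(x, ...) {
  curves <- x$curves
  d <- x$grid$densities
  avail <- colnames(curves[[1]])
  avail <- avail[colSums(!is.na(curves[[1]])) > 0]
  if (!length(avail)) stop("no global curves stored in this object")
  nc <- ceiling(length(avail) / 2)
  old <- graphics::par(mfrow = c(min(2, length(avail)), nc),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in avail) {
    y <- cbind(curves[[1]][, m], curves[[2]][, m])
    graphics::matplot(d, y, type = "l", lty = 1, lwd = 2,
                      col = c("#1b6ca8", "#c0392b"),
                      xlab = "network density", ylab = m, main = m, ...)
    if (m == "sigma") graphics::abline(h = 1, lty = 3)
    graphics::legend("topright", legend = names(curves), bty = "n",
                     lty = 1, lwd = 2, col = c("#1b6ca8", "#c0392b"))
  }
  invisible(x)
}
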