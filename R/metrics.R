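#' Regional (nodal) graph metrics of a binary network
#'
#' Degree, shortest-path betweenness centrality (unnormalized, unordered-pair
#' counts; disconnected pairs contribute zero) and nodal efficiency (mean
#' inverse hop distance to all other nodes, with 1/infinity = 0).
#'
#' @param net an [scn_binarize()] network.
#' @return data.frame with one row per ROI: `roi`, `degree`, `betweenness`,
#'   `nodal_efficiency`.
#' @export
regional_metrics <- function(net) {
  stopifnot(inherits(net, "scn_network"))
  m <- cpp_graph_metrics(net$adjacency, spl = TRUE, bc = TRUE,
                         cp = FALSE, eloc = FALSE)
  data.frame(roi = net$roi_labels, degree = m$degree,
             betweenness = m$betweenness,
             nodal_efficiency = m$nodal_efficiency,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global graph metrics of a binary network
#'
#' Global efficiency (mean inverse hop distance over all node pairs), local
#' efficiency (mean, over nodes, of the efficiency of each node's
#' neighbour-induced subgraph), clustering coefficient (mean local
#' clustering, zero for degree < 2) and characteristic path length (mean hop
#' distance over *connected* pairs only, so sparse disconnected networks stay
#' finite). When a rewired [reference_ensemble()] is supplied, the
#' small-worldness index
#' \deqn{\sigma = (Cp / Cp_{rand}) / (Lp / Lp_{rand})}
#' is computed against the ensemble means.
#'
#' @param net an [scn_binarize()] network.
#' @param ref optional [reference_ensemble()] for sigma.
#' @return list of class `scn_global`: `eglob`, `eloc`, `cp`, `lp`, `sigma`
#'   (`NA` without a reference ensemble).
#' @export
global_metrics <- function(net, ref = NULL) {
  stopifnot(inherits(net, "scn_network"))
  m <- cpp_graph_metrics(net$adjacency, spl = TRUE, bc = FALSE,
                         cp = TRUE, eloc = TRUE)
  sigma <- NA_real_
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "scn_ref_ensemble"))
    if (!is.finite(ref$mean_cp_rand) || ref$mean_cp_rand == 0 ||
        !is.finite(ref$mean_lp_rand) || ref$mean_lp_rand == 0)
      stop("reference ensemble has zero or undefined mean Cp/Lp")
    sigma <- (m$cp / ref$mean_cp_rand) / (m$lp / ref$mean_lp_rand)
  }
  structure(list(eglob = m$eglob, eloc = m$eloc, cp = m$cp, lp = m$lp,
                 sigma = sigma), class = "scn_global")
}

#' @export
print.scn_global <- function(x, ...) {
  cat(sprintf("Eglob %.4f  Eloc %.4f  Cp %.4f  Lp %.4f  Sigma %s\n",
              x$eglob, x$eloc, x$cp, x$lp,
              if (is.na(x$sigma)) "NA" else sprintf("%.3f", x$sigma)))
  invisible(x)
}

net_to_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Degree-preserving random reference ensemble
#'
#' Generates `n_random` randomized versions of a network by Maslov-Sneppen
#' double-edge swaps (via [igraph::rewire()] with `keeping_degseq`), each
#' attempting `iter_per_edge` swaps per edge, and records the ensemble means
#' of the clustering coefficient and characteristic path length used to
#' normalize small-worldness. Every member has exactly the degree sequence of
#' the input. If the degree sequence admits no rewiring (e.g. a star graph),
#' the ensemble degenerates to copies of the original network and is flagged.
#'
#' @param net an [scn_binarize()] network with at least one edge.
#' @param n_random ensemble size.
#' @param iter_per_edge attempted swaps per edge per member.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `scn_ref_ensemble` with fields `n_random`,
#'   `iter_per_edge`, `mean_cp_rand`, `mean_lp_rand`, per-member `cp_rand`,
#'   `lp_rand`, `degenerate` flag and `seed`.
#' @export
reference_ensemble <- function(net, n_random = 100, iter_per_edge = 10,
                               seed = NULL) {
  stopifnot(inherits(net, "scn_network"))
  E <- sum(net$adjacency) / 2
  if (E < 1) stop("network has no edges")
  if (!is.null(seed)) set.seed(seed)
  g <- net_to_igraph(net)
  niter <- max(1L, as.integer(iter_per_edge * E))
  cp_rand <- numeric(n_random)
  lp_rand <- numeric(n_random)
  changed <- FALSE
  for (i in seq_len(n_random)) {
    rg <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    A <- as.matrix(igraph::as_adjacency_matrix(rg, type = "both", sparse = FALSE))
    storage.mode(A) <- "integer"
    if (!changed && !identical(unname(A), unname(net$adjacency))) changed <- TRUE
    m <- cpp_graph_metrics(A, spl = TRUE, bc = FALSE, cp = TRUE, eloc = FALSE)
    cp_rand[i] <- m$cp
    lp_rand[i] <- m$lp
  }
  degenerate <- !changed && n_random > 0
  if (degenerate)
    warning("degree sequence admits no rewiring; ensemble equals the original graph")
  structure(list(n_random = n_random, iter_per_edge = iter_per_edge,
                 mean_cp_rand = mean(cp_rand), mean_lp_rand = mean(lp_rand),
                 cp_rand = cp_rand, lp_rand = lp_rand,
                 degenerate = degenerate, seed = seed),
            class = "scn_ref_ensemble")
}
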