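# Fixtures are built in code; no data files.

# wrap a raw 0/1 adjacency matrix as the package's network class
as_scn_network <- function(A, labels = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  N <- nrow(A)
  labels <- labels %||% sprintf("ROI_%03d", seq_len(N))
  dimnames(A) <- list(labels, labels)
  structure(list(adjacency = A,
                 density = sum(A) / 2 / (N * (N - 1) / 2),
                 target_density = NA_real_, roi_labels = labels),
            class = "scn_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_adjacency <- function(n, p = 0.5, min_edges = 1L) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    on <- up[runif(length(up)) < p]
    if (length(on) >= min_edges) {
      A[on] <- 1L
      A <- A + t(A)
      return(A)
    }
  }
}

igraph_to_network <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
  as_scn_network(A)
}

ws_network <- function(n = 100, k = 6, p = 0.05) {
  igraph_to_network(igraph::sample_smallworld(1, n, k / 2, p))
}

er_network_matched <- function(n = 100, n_edges = 300) {
  igraph_to_network(igraph::sample_gnm(n, n_edges))
}

# small two-group thickness table from explicit per-group matrices
tt_from_matrices <- function(m1, m2, residualized = FALSE) {
  v <- rbind(m1, m2)
  thickness_table(v, rep(c("group1", "group2"), c(nrow(m1), nrow(m2))),
                  subject_id = sprintf("s%03d", seq_len(nrow(v))),
                  roi_labels = sprintf("R%02d", seq_len(ncol(v))),
                  residualized = residualized)
}
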