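# Independent brute-force oracle for graph metrics on tiny graphs.
# Shortest paths are found by exhaustive enumeration of all simple paths,
# with no shared code with the package's BFS/Brandes kernels.

enum_simple_paths <- function(A, s, t) {
  res <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1)) if (!(w %in% path)) rec(c(path, w))
  }
  rec(s)
  res
}

oracle_dist <- function(A) {
  N <- nrow(A)
  d <- matrix(Inf, N, N)
  diag(d) <- 0
  if (N < 2) return(d)
  for (s in 1:(N - 1)) for (t in (s + 1):N) {
    ps <- enum_simple_paths(A, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, 1L) - 1L
    d[s, t] <- d[t, s] <- min(lens)
  }
  d
}

oracle_eglob <- function(A) {
  N <- nrow(A)
  if (N < 2) return(0)
  d <- oracle_dist(A)
  invd <- 1 / d
  diag(invd) <- 0
  sum(invd[upper.tri(invd)]) / (N * (N - 1) / 2)
}

oracle_metrics <- function(A) {
  N <- nrow(A)
  deg <- rowSums(A)
  d <- matrix(Inf, N, N)
  diag(d) <- 0
  bc <- numeric(N)
  for (s in 1:(N - 1)) for (t in (s + 1):N) {
    ps <- enum_simple_paths(A, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, 1L) - 1L
    dm <- min(lens)
    d[s, t] <- d[t, s] <- dm
    sp <- ps[lens == dm]
    sigma <- length(sp)
    inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tb <- table(inner)
      idx <- as.integer(names(tb))
      bc[idx] <- bc[idx] + as.numeric(tb) / sigma
    }
  }
  invd <- 1 / d
  diag(invd) <- 0
  nodal_eff <- rowSums(invd) / (N - 1)
  eglob <- sum(invd[upper.tri(invd)]) / (N * (N - 1) / 2)
  off <- d[upper.tri(d)]
  lp <- if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_
  cp_i <- vapply(1:N, function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    nb <- which(A[i, ] == 1)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  eloc_i <- vapply(1:N, function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    nb <- which(A[i, ] == 1)
    oracle_eglob(A[nb, nb, drop = FALSE])
  }, numeric(1))
  list(degree = deg, betweenness = bc, nodal_efficiency = nodal_eff,
       eglob = eglob, eloc = mean(eloc_i), cp = mean(cp_i), lp = lp)
}

# textbook Welch t-test on two samples, written independently of the package
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
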