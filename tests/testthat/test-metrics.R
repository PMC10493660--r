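star_graph <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}

test_that("regional metrics match closed forms on canonical graphs", {
  # star on 5 nodes
  rm <- regional_metrics(as_scn_network(star_graph(5)))
  expect_equal(rm$degree, c(4, 1, 1, 1, 1))
  expect_equal(rm$betweenness, c(choose(4, 2), 0, 0, 0, 0))
  expect_equal(rm$nodal_efficiency, c(1, rep((1 + 3 * 0.5) / 4, 4)),
               tolerance = 1e-12)

  # complete graph K6
  K6 <- matrix(1L, 6, 6); diag(K6) <- 0L
  rm6 <- regional_metrics(as_scn_network(K6))
  expect_true(all(rm6$betweenness == 0))
  expect_true(all(abs(rm6$nodal_efficiency - 1) < 1e-12))
})

test_that("global metrics match closed forms on canonical graphs", {
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  gm <- global_metrics(as_scn_network(K5))
  expect_equal(gm$eglob, 1, tolerance = 1e-12)
  expect_equal(gm$cp, 1, tolerance = 1e-12)
  expect_equal(gm$lp, 1, tolerance = 1e-12)
  expect_equal(gm$eloc, 1, tolerance = 1e-12)

  # path graph on 3 nodes: distances 1, 1, 2
  P3 <- matrix(0L, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1L
  gm3 <- global_metrics(as_scn_network(P3))
  expect_equal(gm3$cp, 0, tolerance = 1e-12)
  expect_equal(gm3$lp, 4 / 3, tolerance = 1e-12)
  expect_equal(gm3$eglob, 5 / 6, tolerance = 1e-12)
})

test_that("metrics agree with the exhaustive path-enumeration oracle on small graphs", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    A <- random_adjacency(n, p = runif(1, 0.25, 0.9))
    net <- as_scn_network(A)
    o <- oracle_metrics(A)
    rm <- regional_metrics(net)
    gm <- global_metrics(net)
    expect_equal(rm$degree, unname(o$degree))
    expect_equal(rm$betweenness, o$betweenness, tolerance = 1e-12)
    expect_equal(rm$nodal_efficiency, o$nodal_efficiency, tolerance = 1e-12)
    expect_equal(gm$eglob, o$eglob, tolerance = 1e-12)
    expect_equal(gm$eloc, o$eloc, tolerance = 1e-12)
    expect_equal(gm$cp, o$cp, tolerance = 1e-12)
    expect_equal(gm$lp, o$lp, tolerance = 1e-12)
  }
})

test_that("betweenness also agrees with igraph on larger random graphs", {
  set.seed(23)
  for (i in 1:5) {
    A <- random_adjacency(40, p = 0.15)
    net <- as_scn_network(A)
    rm <- regional_metrics(net)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(rm$betweenness, unname(igraph::betweenness(g)),
                 tolerance = 1e-9)
    expect_equal(rm$degree, unname(igraph::degree(g)))
  }
})

test_that("degree sums to twice the edge count and efficiency is monotone in edges", {
  set.seed(29)
  for (i in 1:10) {
    A <- random_adjacency(15, p = 0.3)
    net <- as_scn_network(A)
    rm <- regional_metrics(net)
    expect_equal(sum(rm$degree), sum(A))

    # add one absent edge: eglob and every nodal efficiency never decrease
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    e <- off[sample(nrow(off), 1), ]
    A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1L
    net2 <- as_scn_network(A2)
    expect_gte(global_metrics(net2)$eglob, global_metrics(net)$eglob)
    expect_true(all(regional_metrics(net2)$nodal_efficiency >=
                      rm$nodal_efficiency - 1e-12))
  }
})

test_that("reference ensembles preserve degree sequences and destroy lattice clustering", {
  ring <- igraph_to_network(igraph::sample_smallworld(1, 100, 2, 0))
  ref <- reference_ensemble(ring, n_random = 15, seed = 61)
  expect_false(ref$degenerate)
  expect_lt(ref$mean_cp_rand, global_metrics(ring)$cp)

  # degree sequence invariance, checked member by member
  set.seed(71)
  A <- random_adjacency(30, p = 0.2)
  net <- as_scn_network(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  for (i in 1:5) {
    rg <- igraph::rewire(g, igraph::keeping_degseq(niter = 200))
    expect_equal(igraph::degree(rg), igraph::degree(g))
  }

  # determinism under a fixed seed
  r1 <- reference_ensemble(net, n_random = 8, seed = 99)
  r2 <- reference_ensemble(net, n_random = 8, seed = 99)
  expect_equal(r1$mean_cp_rand, r2$mean_cp_rand)
  expect_equal(r1$mean_lp_rand, r2$mean_lp_rand)

  # a star admits no rewiring: degenerate ensemble with a warning
  expect_warning(refs <- reference_ensemble(as_scn_network(star_graph(6)),
                                            n_random = 4, seed = 1),
                 "no rewiring")
  expect_true(refs$degenerate)
})

test_that("sigma normalization behaves sensibly and guards its preconditions", {
  ws <- ws_network(60, 6, 0.05)
  ref <- reference_ensemble(ws, n_random = 10, seed = 5)
  gm <- global_metrics(ws, ref)
  expect_gt(gm$sigma, 1)
  expect_true(is.na(global_metrics(ws)$sigma))

  bad <- structure(list(n_random = 1, iter_per_edge = 10, mean_cp_rand = 0,
                        mean_lp_rand = 2, cp_rand = 0, lp_rand = 2,
                        degenerate = FALSE, seed = 1),
                   class = "scn_ref_ensemble")
  expect_error(global_metrics(ws, bad), "zero")
})
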