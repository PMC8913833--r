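test_that("shortest path lengths match the Floyd-Warshall oracle", {
  # named cases
  k4 <- binary_network(matrix(1, 4, 4) - diag(4))
  expect_true(all(shortest_path_lengths(k4)[upper.tri(diag(4))] == 1))
  path3 <- binary_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(shortest_path_lengths(path3)[1, 3], 2)
  # randomized cases, including disconnected graphs
  for (s in 1:20) {
    adj <- random_adjacency(8, p = 0.3, seed = s)
    net <- binary_network(adj)
    expect_equal(unname(shortest_path_lengths(net)), fw_distances(adj))
  }
})

test_that("global efficiency handles complete, empty and path graphs exactly", {
  expect_equal(global_efficiency(binary_network(matrix(1, 5, 5) - diag(5))), 1)
  expect_equal(global_efficiency(binary_network(matrix(0, 4, 4))), 0)
  path3 <- binary_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_error(global_efficiency(binary_network(matrix(0, 1, 1))), "2 nodes")
})

test_that("local efficiency handles triangle, star and random graphs", {
  tri <- binary_network(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(local_efficiency(tri)), rep(1, 3))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(local_efficiency(binary_network(star))), rep(0, 5))
  for (s in 1:20) {
    adj <- random_adjacency(8, p = 0.4, seed = 100 + s)
    expect_equal(unname(local_efficiency(binary_network(adj))),
                 eloc_oracle(adj))
  }
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(5)
  for (rep in 1:10) {
    adj <- random_adjacency(9, p = 0.25, seed = 200 + rep)
    e0 <- global_efficiency(binary_network(adj))
    missing <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    if (!nrow(missing)) next
    pick <- missing[sample(nrow(missing), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(binary_network(adj2)), e0)
  }
})

test_that("node relabeling permutes e_local and preserves e_global", {
  adj <- random_adjacency(9, p = 0.4, seed = 77)
  colnames(adj) <- rownames(adj) <- paste0("m", 1:9)
  net <- binary_network(adj)
  perm <- sample(9)
  net_p <- binary_network(adj[perm, perm])
  expect_equal(global_efficiency(net_p), global_efficiency(net))
  expect_equal(local_efficiency(net_p),
               local_efficiency(net)[colnames(adj)[perm]])
})

test_that("degree-preserving rewiring keeps the degree sequence, always", {
  for (s in 1:50) {
    adj <- random_adjacency(11, p = 0.35, seed = 300 + s)
    net <- binary_network(adj)
    rew <- rewire_preserving_degree(net, n_swap_per_edge = 10, seed = s)
    expect_identical(unname(rowSums(rew$adjacency)), unname(rowSums(adj)))
    expect_identical(unname(diag(rew$adjacency)), rep(0L, 11))
    expect_identical(rew$adjacency, t(rew$adjacency))
  }
})

test_that("rewiring actually randomizes and is deterministic given a seed", {
  set.seed(41)
  adj <- random_adjacency(11, p = 0.35, seed = 9)  # ~19 edges
  net <- binary_network(adj)
  changed <- vapply(1:100, function(s) {
    !identical(rewire_preserving_degree(net, 10, seed = s)$adjacency, net$adjacency)
  }, logical(1))
  expect_gte(sum(changed), 95)
  expect_identical(rewire_preserving_degree(net, 10, seed = 4)$adjacency,
                   rewire_preserving_degree(net, 10, seed = 4)$adjacency)
})

test_that("saturated and near-edgeless graphs pass through rewiring safely", {
  k5 <- binary_network(matrix(1, 5, 5) - diag(5))
  expect_identical(rewire_preserving_degree(k5, 10, seed = 1)$adjacency,
                   k5$adjacency)
  one_edge <- matrix(0, 4, 4)
  one_edge[1, 2] <- one_edge[2, 1] <- 1
  expect_warning(rew <- rewire_preserving_degree(binary_network(one_edge), 10, 1),
                 "fewer than 2 edges")
  expect_identical(rew$adjacency, binary_network(one_edge)$adjacency)
})

test_that("a clustered ring lattice is detected as small-world", {
  net <- binary_network(ring_lattice(12, 4))
  sw <- small_worldness(net, n_random = 200, seed = 8)
  expect_gt(sw$sigma, 1)
  expect_true(sw$meets_criterion)
  # invariant structure of the result
  expect_equal(sw$gamma, sw$real$e_global / sw$rand_e_global_mean)
  expect_equal(sw$lam, mean(sw$real$e_local) / sw$rand_e_local_mean)
  expect_equal(sw$sigma, sw$lam / sw$gamma)
})

test_that("small_worldness is reproducible and validates its inputs", {
  net <- binary_network(random_adjacency(10, p = 0.4, seed = 17))
  a <- small_worldness(net, n_random = 50, seed = 3)
  b <- small_worldness(net, n_random = 50, seed = 3)
  expect_identical(a, b)
  empty <- binary_network(matrix(0, 5, 5))
  expect_error(small_worldness(empty, 10, seed = 1), "1 edge")
})

test_that("degenerate ensembles error by default and obey the limit mode", {
  # two disjoint edges: no rewiring can ever create a triangle
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- 1
  net <- binary_network(adj)
  expect_error(small_worldness(net, n_random = 20, seed = 2), "degenerate")
  sw <- small_worldness(net, n_random = 20, seed = 2, degenerate = "limit")
  expect_equal(sw$sigma, 0)
  expect_false(sw$meets_criterion)
})

test_that("efficiency agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    adj <- random_adjacency(9, p = 0.35, seed = 400 + s)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(global_efficiency(binary_network(adj)),
                 igraph::global_efficiency(g))
  }
})

test_that("small-world results serialize to JSON with all fields", {
  net <- binary_network(ring_lattice(10, 4))
  sw <- small_worldness(net, n_random = 20, seed = 5)
  parsed <- jsonlite::fromJSON(smallworld_to_json(sw))
  expect_equal(parsed$sigma, sw$sigma)
  expect_equal(parsed$n_random, 20)
  expect_equal(parsed$seed, 5)
})
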