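#' Construct a binary network from a raw adjacency matrix
#'
#' Convenience constructor used for lattice/benchmark graphs and tests; the
#' usual route into the class is [binarize()].
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param panel node names (defaults to colnames or V1..Vn).
#' @param threshold,group,time_point optional provenance fields.
#' @return a `binary_network`.
#' @export
binary_network <- function(adjacency, panel = NULL, threshold = NA_real_,
                           group = NA_character_, time_point = NA) {
  adjacency <- (adjacency != 0) * 1L
  if (!isTRUE(all.equal(unname(adjacency), unname(t(adjacency))))) {
    stop_invalid("adjacency must be symmetric")
  }
  diag(adjacency) <- 0L
  storage.mode(adjacency) <- "integer"
  panel <- panel %||% colnames(adjacency) %||%
    paste0("V", seq_len(ncol(adjacency)))
  dimnames(adjacency) <- list(panel, panel)
  structure(list(adjacency = adjacency, threshold = threshold, group = group,
                 time_point = time_point, panel = panel),
            class = "binary_network")
}

#' All-pairs shortest hop counts of a binary network
#'
#' Breadth-first distances; `Inf` marks pairs with no connecting path.
#'
#' @param net a `binary_network`.
#' @return symmetric numeric matrix of hop counts with zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- bfs_distances_cpp(net$adjacency)
  dimnames(d) <- dimnames(net$adjacency)
  d
}

#' Global efficiency of a binary network
#'
#' Mean over all ordered node pairs of the inverse shortest-path length, with
#' 1/Inf = 0 for disconnected pairs. Ranges from 0 (edgeless) to 1 (complete
#' graph) and, unlike mean path length, remains well defined and informative
#' on sparse or fragmented networks.
#'
#' @param net a `binary_network` with at least 2 nodes.
#' @return efficiency in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (ncol(net$adjacency) < 2L) stop_invalid("network must have >= 2 nodes")
  global_efficiency_cpp(net$adjacency)
}

#' Per-node local efficiency
#'
#' The global efficiency of the subgraph induced by each node's neighbours
#' (the node itself excluded); 0 for nodes of degree below 2. Measures the
#' fault tolerance of the network around each node.
#'
#' @param net a `binary_network` with at least 2 nodes.
#' @return named numeric vector over nodes.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (ncol(net$adjacency) < 2L) stop_invalid("network must have >= 2 nodes")
  setNames(local_efficiency_cpp(net$adjacency), net$panel)
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Maslov–Sneppen rewiring: repeatedly picks two edges and exchanges their
#' endpoints, rejecting swaps that would create self-loops or multi-edges, so
#' the degree of every node is exactly preserved. The retry budget is 100
#' attempts per target swap; if it is exhausted before the target number of
#' swaps (e.g. on nearly saturated graphs) the current state is returned with
#' an under-mixing warning.
#'
#' @param net a `binary_network`.
#' @param n_swap_per_edge target accepted swaps per edge (default 10).
#' @param seed integer seed making the rewiring reproducible.
#' @return a rewired `binary_network` with identical degree sequence.
#' @export
rewire_preserving_degree <- function(net, n_swap_per_edge = 10, seed = 1L) {
  stopifnot(inherits(net, "binary_network"))
  n_edges <- sum(net$adjacency) / 2
  if (n_edges < 2) {
    warning("fewer than 2 edges: returning network unchanged", call. = FALSE)
    return(net)
  }
  nswap <- as.integer(n_edges * n_swap_per_edge)
  set.seed(seed)
  adj <- double_edge_swap_cpp(net$adjacency, nswap, 100L * nswap)
  done <- attr(adj, "swaps_done")
  n <- ncol(adj)
  if (done < nswap && n_edges < choose(n, 2)) {
    warning("under-mixed rewiring: ", done, " of ", nswap,
            " swaps achieved within the retry budget", call. = FALSE)
  }
  attr(adj, "swaps_done") <- NULL
  dimnames(adj) <- dimnames(net$adjacency)
  out <- net
  out$adjacency <- adj
  out
}

#' Small-worldness against a degree-matched random ensemble
#'
#' Builds `n_random` independent degree-preserving rewirings of the network,
#' averages their global efficiency and mean local efficiency, and forms the
#' normalized ratios
#' gamma = E_global(real) / mean E_global(random),
#' lambda = mean E_local(real) / mean E_local(random),
#' sigma = lambda / gamma.
#' A network is flagged small-world when sigma > 1: locally it is more
#' clustered than chance while remaining about as globally integrated.
#'
#' A degenerate ensemble (mean ensemble local efficiency exactly 0, which can
#' happen on very sparse networks whose rewirings are all triangle-free) is an
#' error by default; with `degenerate = "limit"` the limiting convention is
#' applied instead: lambda = 0 when the real network also has zero local
#' efficiency (no clustering anywhere, sigma = 0, criterion unmet), and
#' lambda capped at `n_random + 1` when only the ensemble is flat (a finite
#' ensemble resolves the ratio only up to its size). The limit mode is what
#' the threshold sweep and permutation machinery use, so one empty cell
#' cannot abort a whole comparison.
#'
#' @param net a `binary_network` with at least one edge.
#' @param n_random ensemble size (default 1000).
#' @param n_swap_per_edge swaps per edge for each rewiring (default 10).
#' @param seed integer seed.
#' @param degenerate `"error"` (default) or `"limit"`; see Details.
#' @return a `smallworld_result` with the real efficiencies, ensemble means,
#'   gamma, lambda (`lam`), sigma and `meets_criterion`.
#' @export
small_worldness <- function(net, n_random = 1000, n_swap_per_edge = 10,
                            seed = 1L, degenerate = c("error", "limit")) {
  degenerate <- match.arg(degenerate)
  stopifnot(inherits(net, "binary_network"))
  if (sum(net$adjacency) < 2) {
    if (degenerate == "error") stop_invalid("network must have >= 1 edge")
    # limit mode: an edgeless network has no structure of any kind
    return(structure(
      list(real = list(e_global = 0,
                       e_local = setNames(numeric(length(net$panel)), net$panel)),
           rand_e_global_mean = 0, rand_e_local_mean = 0,
           gamma = 0, lam = 0, sigma = 0,
           n_random = as.integer(n_random), meets_criterion = FALSE,
           seed = as.integer(seed)),
      class = "smallworld_result"))
  }
  if (!is_count(n_random)) stop_invalid("n_random must be a positive integer")
  e_global <- global_efficiency(net)
  e_local <- local_efficiency(net)
  set.seed(seed)
  ens <- sw_ensemble_cpp(net$adjacency, as.integer(n_random),
                         as.integer(n_swap_per_edge))
  rand_eg <- mean(ens$e_global)
  rand_el <- mean(ens$e_local_mean)
  if (rand_eg == 0 || (rand_el == 0 && degenerate == "error")) {
    stop_invalid("degenerate random ensemble for (", net$group, ", ",
                 as.character(net$time_point), ") at threshold ",
                 net$threshold, ": mean ensemble efficiency is zero")
  }
  gamma <- e_global / rand_eg
  lam <- if (rand_el == 0) {
    # a finite ensemble that never produced local structure resolves the
    # ratio only up to its size: cap lambda at n_random + 1 (the value the
    # ratio takes if the real network is folded into its own ensemble)
    if (mean(e_local) == 0) 0 else n_random + 1
  } else {
    mean(e_local) / rand_el
  }
  sigma <- lam / gamma
  structure(
    list(real = list(e_global = e_global, e_local = e_local),
         rand_e_global_mean = rand_eg, rand_e_local_mean = rand_el,
         gamma = gamma, lam = lam, sigma = sigma,
         n_random = as.integer(n_random), meets_criterion = sigma > 1,
         seed = as.integer(seed)),
    class = "smallworld_result"
  )
}

#' @export
print.smallworld_result <- function(x, ...) {
  cat(sprintf(
    "Small-worldness: sigma = %.3f (gamma = %.3f, lambda = %.3f; %d random networks)\n",
    x$sigma, x$gamma, x$lam, x$n_random))
  cat("  criterion sigma > 1: ", if (x$meets_criterion) "met" else "NOT met", "\n",
      sep = "")
  invisible(x)
}

#' Serialize a small-world result to JSON
#'
#' @param result a `smallworld_result`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @export
smallworld_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "smallworld_result"))
  json <- jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
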