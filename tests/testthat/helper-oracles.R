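# Independent oracles and fixture generators, kept deliberately separate
# from the implementation paths they check.

# Random road network: n nodes scattered in a square, m random edges with
# Euclidean lengths and random one-way flags. Connectivity not enforced --
# unreachability must agree between implementation and oracle too.
random_network <- function(n = 20, m = 3 * n, box = 1000, p_oneway = 0.3,
                           seed = 1) {
  set.seed(seed)
  nodes <- data.frame(id = sprintf("n%03d", seq_len(n)),
                      x = runif(n, 0, box), y = runif(n, 0, box),
                      stringsAsFactors = FALSE)
  u <- sample.int(n, m, replace = TRUE)
  v <- sample.int(n, m, replace = TRUE)
  keep <- u != v
  u <- u[keep]; v <- v[keep]
  len <- sqrt((nodes$x[u] - nodes$x[v])^2 + (nodes$y[u] - nodes$y[v])^2)
  pos <- len > 0
  edges <- data.frame(u = nodes$id[u[pos]], v = nodes$id[v[pos]],
                      length = len[pos],
                      oneway = runif(sum(pos)) < p_oneway,
                      stringsAsFactors = FALSE)
  road_network(nodes, edges)
}

# All-pairs shortest travel times by Floyd-Warshall on the dense weight
# matrix -- an algorithm entirely distinct from the Dijkstra-based
# implementation path.
fw_all_pairs <- function(network, mode) {
  if (!inherits(mode, "travel_mode")) mode <- travel_mode(mode)
  ids <- network$nodes$id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  e <- network$edges
  secs <- e$length / 1000 / mode$speed_kmh * 3600
  for (k in seq_len(nrow(e))) {
    i <- match(e$u[k], ids); j <- match(e$v[k], ids)
    D[i, j] <- min(D[i, j], secs[k])
    if (mode$name == "walk" || !e$oneway[k])
      D[j, i] <- min(D[j, i], secs[k])
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Random binary coverage instance for the MCLP suite.
random_coverage <- function(n_demand = 15, n_cand = 10, density = 0.3,
                            seed = 1) {
  set.seed(seed)
  a <- matrix(as.integer(runif(n_demand * n_cand) < density), n_demand,
              dimnames = list(sprintf("d%03d", seq_len(n_demand)),
                              sprintf("c%03d", seq_len(n_cand))))
  a
}

# Exhaustive MCLP optimum over all candidate subsets of size <= p, via bit
# masks -- independent of the combn-based solver.
bitmask_mclp_optimum <- function(a, p, weights = rep(1, nrow(a))) {
  n <- ncol(a)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > p) next
    obj <- sum(weights[rowSums(a[, sel, drop = FALSE]) > 0])
    best <- max(best, obj)
  }
  best
}

# Exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# assignments (tie-free data).
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Small deterministic grid scene shared by coverage/pipeline tests.
tiny_city <- function(rows = 6, cols = 6, block_m = 150, seed = 7,
                      oneway_fraction = 0.25) {
  generate_grid_city(city_config(rows = rows, cols = cols, block_m = block_m,
                                 jitter_m = 0,
                                 oneway_fraction = oneway_fraction,
                                 n_demand = 10, n_candidates = 8,
                                 center_fraction = 0.8, seed = seed))
}
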