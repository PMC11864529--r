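#' Configuration of a synthetic grid city
#'
#' The generator emulates the planned, grid-like street layout of a
#' mid-sized Brazilian city: a `rows` x `cols` node lattice with blocks of
#' `block_m` meters, small uniform jitter on node positions, and a fraction
#' of street segments marked one-way with directions alternating along
#' parallel streets (so vehicular traffic is never trapped). Demand
#' (simulated cardiac-arrest occurrences) is sampled uniformly over a
#' concentric central sub-rectangle covering `center_fraction` of the
#' bounding box, mirroring a simulation concentrated on the densely
#' populated city center.
#'
#' Defaults describe the shipped replication scene: a 24 x 24 lattice of
#' 200 m blocks (a ~4.6 km square, commensurate with a city-center study
#' area), 50 demand points, 80 candidate AED sites, a single ambulance
#' station.
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param block_m block edge length in meters (> 0).
#' @param jitter_m maximum uniform perturbation of node coordinates (m).
#' @param oneway_fraction fraction of segments marked one-way (0..1;
#'   vehicular strong connectivity is verified, and the draw is repeated
#'   with a perturbed seed if it ever fails).
#' @param n_demand number of demand points (study default 50).
#' @param n_candidates number of candidate AED sites.
#' @param n_stations number of ambulance stations (study default 1).
#' @param center_fraction side fraction of the bounding box forming the
#'   central demand region (0 < f <= 1).
#' @param seed integer seed; every generator output is a pure function of
#'   config + seed.
#' @return A list of class `city_config`.
#' @export
city_config <- function(rows = 24, cols = 24, block_m = 200, jitter_m = 10,
                        oneway_fraction = 0.3, n_demand = 50,
                        n_candidates = 80, n_stations = 1,
                        center_fraction = 0.6, seed = 1) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              block_m = block_m, jitter_m = jitter_m,
              oneway_fraction = oneway_fraction, n_demand = as.integer(n_demand),
              n_candidates = as.integer(n_candidates),
              n_stations = as.integer(n_stations),
              center_fraction = center_fraction, seed = as.integer(seed))
  if (cfg$rows < 2 || cfg$cols < 2) stop("rows and cols must be >= 2")
  if (cfg$block_m <= 0) stop("block_m must be > 0")
  if (cfg$jitter_m < 0) stop("jitter_m must be >= 0")
  if (cfg$oneway_fraction < 0 || cfg$oneway_fraction > 1)
    stop("oneway_fraction must lie in [0, 1]")
  if (cfg$center_fraction <= 0 || cfg$center_fraction > 1)
    stop("center_fraction must lie in (0, 1]")
  if (cfg$n_demand < 1) stop("n_demand must be >= 1")
  class(cfg) <- "city_config"
  cfg
}

#' Generate a synthetic grid street network
#'
#' Builds the jittered lattice described by a [city_config()]: nodes at
#' `(col-1, row-1) * block_m` plus uniform jitter, horizontal and vertical
#' edges with exact Euclidean lengths, and a seeded subset of edges flagged
#' one-way. One-way directions alternate along parallel streets (eastbound
#' on even rows, westbound on odd; north/south likewise by column), which
#' preserves vehicular strong connectivity for moderate one-way fractions;
#' strong connectivity is verified and the assignment redrawn under a
#' perturbed seed in the rare case it fails. Deterministic for a fixed
#' seed.
#'
#' @param config a [city_config()].
#' @return a [road_network()].
#' @export
generate_grid_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  rows <- config$rows; cols <- config$cols; b <- config$block_m
  n_nodes <- rows * cols
  width <- max(3L, nchar(as.character(n_nodes)))
  idx <- function(i, j) (i - 1L) * cols + j   # row-major
  ids <- sprintf(paste0("n%0", width, "d"), seq_len(n_nodes))

  make_scene <- function(seed) with_seed(seed, {
    jx <- if (config$jitter_m > 0)
      stats::runif(n_nodes, -config$jitter_m, config$jitter_m) else numeric(n_nodes)
    jy <- if (config$jitter_m > 0)
      stats::runif(n_nodes, -config$jitter_m, config$jitter_m) else numeric(n_nodes)
    ii <- rep(seq_len(rows), each = cols)
    jj <- rep(seq_len(cols), times = rows)
    x <- (jj - 1) * b + jx
    y <- (ii - 1) * b + jy
    # horizontal edges (i, j)-(i, j+1); vertical (i, j)-(i+1, j)
    h <- expand.grid(i = seq_len(rows), j = seq_len(cols - 1))
    v <- expand.grid(i = seq_len(rows - 1), j = seq_len(cols))
    eu <- c(idx(h$i, h$j), idx(v$i, v$j))
    ev <- c(idx(h$i, h$j + 1L), idx(v$i + 1L, v$j))
    horiz <- c(rep(TRUE, nrow(h)), rep(FALSE, nrow(v)))
    street_parity <- c(h$i %% 2, v$j %% 2)  # street the segment lies on
    n_edges <- length(eu)
    n_ow <- round(config$oneway_fraction * n_edges)
    ow <- rep(FALSE, n_edges)
    if (n_ow > 0) ow[sample.int(n_edges, n_ow)] <- TRUE
    # alternate direction along parallel streets: odd-parity streets flow
    # in the increasing-index direction, even-parity reversed
    flip <- ow & street_parity == 0
    tmp <- eu[flip]; eu[flip] <- ev[flip]; ev[flip] <- tmp
    len <- sqrt((x[eu] - x[ev])^2 + (y[eu] - y[ev])^2)
    road_network(
      nodes = data.frame(id = ids, x = x, y = y, stringsAsFactors = FALSE),
      edges = data.frame(u = ids[eu], v = ids[ev], length = len,
                         oneway = ow, stringsAsFactors = FALSE))
  })

  seed <- config$seed
  for (attempt in 1:100) {
    net <- make_scene(seed)
    g <- mode_graph(net, travel_mode("car"))
    if (igraph::is_connected(g, mode = "strong")) return(net)
    seed <- seed + 1000003L  # redraw the one-way assignment
  }
  stop("failed to generate a strongly connected network in 100 attempts")
}

#' Sample demand points in the central region
#'
#' Draws `n` points uniformly over the concentric central sub-rectangle
#' whose sides are `center_fraction` of the network bounding box, in
#' continuous space (they are snapped to the network only when travel
#' times are needed). Ids are `d001`, `d002`, ...
#'
#' @param network a [road_network()].
#' @param n number of points (>= 1).
#' @param center_fraction side fraction of the bounding box (0 < f <= 1).
#' @param seed integer seed.
#' @return a demand [point_set()].
#' @export
sample_demand_points <- function(network, n, center_fraction = 0.6, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (center_fraction <= 0 || center_fraction > 1)
    stop("center_fraction must lie in (0, 1]")
  bb <- network_bbox(network)
  w <- bb["xmax"] - bb["xmin"]; h <- bb["ymax"] - bb["ymin"]
  if (w <= 0 || h <= 0) stop("degenerate bounding box")
  cx <- (bb["xmin"] + bb["xmax"]) / 2
  cy <- (bb["ymin"] + bb["ymax"]) / 2
  with_seed(seed, {
    x <- stats::runif(n, cx - w * center_fraction / 2,
                      cx + w * center_fraction / 2)
    y <- stats::runif(n, cy - h * center_fraction / 2,
                      cy + h * center_fraction / 2)
    width <- max(3L, nchar(as.character(n)))
    point_set(sprintf(paste0("d%0", width, "d"), seq_len(n)), x, y, "demand")
  })
}

#' Place candidate AED sites on network nodes
#'
#' The synthetic analog of selecting public, non-residential establishments:
#' a seeded sample of `n` distinct network nodes (establishment ~ street
#' corner). Ids are `c001`, `c002`, ...
#'
#' @param network a [road_network()].
#' @param n number of candidate sites (<= node count).
#' @param seed integer seed.
#' @return a candidate [point_set()], already snapped.
#' @export
place_candidates <- function(network, n, seed = 1) {
  n_nodes <- nrow(network$nodes)
  if (n > n_nodes) stop("n exceeds the number of network nodes")
  with_seed(seed, {
    pick <- sort(sample.int(n_nodes, n))
    width <- max(3L, nchar(as.character(n)))
    point_set(sprintf(paste0("c%0", width, "d"), seq_len(n)),
              network$nodes$x[pick], network$nodes$y[pick], "candidate",
              snapped_node = network$nodes$id[pick])
  })
}

#' Place an ambulance station
#'
#' Snaps a single station to the requested network node: `"corner"` picks
#' the node nearest the bounding box's (min-x, min-y) corner, `"centroid"`
#' the node nearest its center, and any other value is taken as a literal
#' node id.
#'
#' @param network a [road_network()].
#' @param position `"corner"`, `"centroid"`, or a node id.
#' @param seed unused; accepted for interface uniformity with the other
#'   generators.
#' @return a station [point_set()] with one point, already snapped.
#' @export
place_station <- function(network, position = "corner", seed = 1) {
  bb <- network_bbox(network)
  target <- switch(position,
    corner = c(bb["xmin"], bb["ymin"]),
    centroid = c((bb["xmin"] + bb["xmax"]) / 2, (bb["ymin"] + bb["ymax"]) / 2),
    NULL)
  if (is.null(target)) {
    if (!position %in% network$nodes$id)
      stop("unknown node id for station position: ", position)
    k <- match(position, network$nodes$id)
  } else {
    probe <- point_set("tmp", target[1], target[2], "station")
    k <- match(snap_points(network, probe)$snapped_node, network$nodes$id)
  }
  point_set("s001", network$nodes$x[k], network$nodes$y[k], "station",
            snapped_node = network$nodes$id[k])
}
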