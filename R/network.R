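#' Road network for travel-time computation
#'
#' A `road_network` is a planar street graph: nodes carry projected
#' coordinates in meters, edges carry a positive length, a one-way flag and
#' optional per-mode speed overrides. It is the routing substrate every other
#' module operates on. Pedestrians may traverse every edge in both directions
#' regardless of the one-way flag; vehicular modes (`car`, `bicycle`,
#' `ambulance`) may traverse a one-way edge only from `u` to `v`.
#'
#' Coordinates are planar meters: geographic (lon/lat) data must be
#' projected before being turned into a network.
#'
#' @param nodes data.frame with columns `id` (character, unique), `x`, `y`
#'   (meters).
#' @param edges data.frame with columns `u`, `v` (node ids), `length`
#'   (meters, > 0), and optionally `oneway` (logical, default `FALSE`) and
#'   `maxspeed_<mode>` columns (km/h) overriding a mode's default speed on
#'   that edge.
#' @return An object of class `road_network`.
#' @examples
#' nodes <- data.frame(id = c("a", "b"), x = c(0, 500), y = c(0, 0))
#' edges <- data.frame(u = "a", v = "b", length = 500)
#' net <- road_network(nodes, edges)
#' shortest_travel_time(net, "a", "b", travel_mode("walk"))
#' @export
road_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("u", "v", "length") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (nrow(edges) > 0) {
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    if (!all(edges$length > 0)) stop("every edge length must be > 0")
    unknown <- setdiff(c(edges$u, edges$v), nodes$id)
    if (length(unknown) > 0)
      stop("edge endpoints not declared as nodes: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (is.null(edges$oneway)) edges$oneway <- rep(FALSE, nrow(edges))
  edges$oneway <- as.logical(edges$oneway)
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges (%d one-way)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$oneway)))
  bb <- network_bbox(x)
  cat(sprintf("  bbox: [%.1f, %.1f] x [%.1f, %.1f] m\n",
              bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"]))
  invisible(x)
}

network_bbox <- function(network) {
  c(xmin = min(network$nodes$x), xmax = max(network$nodes$x),
    ymin = min(network$nodes$y), ymax = max(network$nodes$y))
}

#' Transport modes
#'
#' A `travel_mode` couples a mode name with a travel speed in km/h. The
#' standardized defaults are: bystander walking 10 km/h, ambulance 50 km/h
#' (typical urban average), bicycle 15 km/h and car 40 km/h. Only `walk`
#' ignores one-way restrictions.
#'
#' @param name one of `"walk"`, `"bicycle"`, `"car"`, `"ambulance"`.
#' @param speed_kmh optional speed override in km/h (> 0).
#' @return An object of class `travel_mode` with fields `name` and
#'   `speed_kmh`.
#' @export
travel_mode <- function(name, speed_kmh = NULL) {
  defaults <- c(walk = 10, bicycle = 15, car = 40, ambulance = 50)
  if (!is.character(name) || length(name) != 1L || !name %in% names(defaults))
    stop("unknown travel mode: ", paste(name, collapse = ", "),
         " (must be one of walk, bicycle, car, ambulance)")
  speed <- speed_kmh %||% defaults[[name]]
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0)
    stop("mode speed must be a single positive number (km/h)")
  structure(list(name = name, speed_kmh = as.numeric(speed)),
            class = "travel_mode")
}

#' @export
print.travel_mode <- function(x, ...) {
  cat(sprintf("<travel_mode> %s @ %g km/h\n", x$name, x$speed_kmh))
  invisible(x)
}

is_vehicular <- function(mode) mode$name != "walk"

# Per-edge traversal time in seconds for a mode, honouring maxspeed_<mode>
# overrides where present.
edge_seconds <- function(network, mode) {
  speed <- rep(mode$speed_kmh, nrow(network$edges))
  col <- paste0("maxspeed_", mode$name)
  if (col %in% names(network$edges)) {
    ov <- network$edges[[col]]
    use <- !is.na(ov)
    if (any(use & ov <= 0)) stop("speed overrides must be positive")
    speed[use] <- ov[use]
  }
  network$edges$length / 1000 / speed * 3600
}

# Directed igraph for a mode: walk traverses everything both ways; vehicular
# modes honour oneway (u -> v only).
mode_graph <- function(network, mode) {
  if (!inherits(mode, "travel_mode")) mode <- travel_mode(mode)
  e <- network$edges
  w <- edge_seconds(network, mode)
  if (nrow(e) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, nrow(network$nodes), name = network$nodes$id)
    return(g)
  }
  back <- if (is_vehicular(mode)) !e$oneway else rep(TRUE, nrow(e))
  from <- c(e$u, e$v[back])
  to <- c(e$v, e$u[back])
  wt <- c(w, w[back])
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network$nodes$id, stringsAsFactors = FALSE)
  )
  g
}

#' Shortest travel time between two network nodes
#'
#' Minimum traversal time in seconds over paths from `origin` to `dest`
#' under a mode's speed and traversal rules. Each edge costs
#' `length / speed`, using the edge's `maxspeed_<mode>` override when set.
#' Returns `Inf` when `dest` is unreachable under the mode's rules and 0
#' when `origin == dest`.
#'
#' @param network a [road_network()].
#' @param origin,dest node ids.
#' @param mode a [travel_mode()] or mode name.
#' @return travel time in seconds (possibly `Inf`).
#' @export
shortest_travel_time <- function(network, origin, dest, mode) {
  if (!inherits(mode, "travel_mode")) mode <- travel_mode(mode)
  ids <- network$nodes$id
  if (!origin %in% ids) stop("unknown origin node: ", origin)
  if (!dest %in% ids) stop("unknown destination node: ", dest)
  if (origin == dest) return(0)
  g <- mode_graph(network, mode)
  as.numeric(igraph::distances(g, v = origin, to = dest, mode = "out",
                               weights = igraph::E(g)$weight,
                               algorithm = "dijkstra"))
}
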