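#' Site points: demand, candidate AED locations, ambulance stations
#'
#' A `point_set` is an ordered collection of uniform-kind sites: `demand`
#' points are simulated out-of-hospital cardiac arrest occurrences,
#' `candidate` points are possible AED installation sites, and `station`
#' points are ambulance bases. Order is stable: travel-time and coverage
#' matrices follow it row by row / column by column.
#'
#' @param id character vector of unique ids.
#' @param x,y planar coordinates in meters.
#' @param kind one of `"demand"`, `"candidate"`, `"station"` (scalar; all
#'   points in a set share it).
#' @param snapped_node optional node ids assigned by [snap_points()].
#' @param crs_note free-text provenance of the projection.
#' @return A data.frame of class `point_set` with columns `id`, `x`, `y`,
#'   `kind`, `snapped_node`.
#' @export
point_set <- function(id, x, y, kind, snapped_node = NA_character_,
                      crs_note = "synthetic planar meters") {
  kind <- match.arg(kind, c("demand", "candidate", "station"))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("point ids must be unique within a set")
  stopifnot(length(x) == length(id), length(y) == length(id))
  df <- data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                   kind = kind,
                   snapped_node = rep_len(as.character(snapped_node),
                                          length(id)),
                   stringsAsFactors = FALSE)
  attr(df, "crs_note") <- crs_note
  class(df) <- c("point_set", "data.frame")
  df
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d %s point(s)%s\n", nrow(x),
              if (nrow(x)) x$kind[1] else "(empty)",
              if (all(!is.na(x$snapped_node))) ", snapped" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Snap points to their nearest network node
#'
#' Assigns each point the Euclidean-nearest node of the network; ties are
#' broken deterministically by the lexicographically lowest node id.
#' Original coordinates are preserved. Snapping to nodes (rather than to the
#' nearest point on an edge) is exact and testable; on networks with short
#' blocks the snapping error is bounded by half a block diagonal.
#'
#' @param network a [road_network()].
#' @param points a [point_set()].
#' @return The point set with `snapped_node` filled in.
#' @export
snap_points <- function(network, points) {
  if (nrow(network$nodes) == 0) stop("no nodes to snap to")
  if (nrow(points) == 0) return(points)
  nx <- network$nodes$x
  ny <- network$nodes$y
  ids <- network$nodes$id
  ord <- order(ids)  # scan in id order so which.min's first-hit is the tie rule
  nx <- nx[ord]; ny <- ny[ord]; ids <- ids[ord]
  points$snapped_node <- vapply(seq_len(nrow(points)), function(i) {
    d2 <- (nx - points$x[i])^2 + (ny - points$y[i])^2
    ids[which.min(d2)]
  }, character(1))
  points
}

snapped_nodes <- function(network, points) {
  if (any(is.na(points$snapped_node)))
    points <- snap_points(network, points)
  points$snapped_node
}
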