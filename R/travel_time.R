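#' Origin-by-destination travel-time matrix
#'
#' Computes the matrix of shortest travel times (seconds) between two point
#' sets under one transport mode, replacing the external routing-engine
#' distance matrix with an in-graph shortest-path computation. Points are
#' snapped to their nearest node first (see [snap_points()]); unreachable
#' pairs are `Inf`.
#'
#' @param network a [road_network()].
#' @param origins,destinations [point_set()] objects; rows of the matrix
#'   follow `origins` order, columns follow `destinations` order.
#' @param mode a [travel_mode()] or mode name.
#' @return An object of class `travel_time_matrix` with fields `t` (numeric
#'   matrix, seconds, dimnames = point ids), `mode`, `origins`,
#'   `destinations`.
#' @export
travel_time_matrix <- function(network, origins, destinations, mode) {
  if (!inherits(mode, "travel_mode")) mode <- travel_mode(mode)
  origins <- if (any(is.na(origins$snapped_node)))
    snap_points(network, origins) else origins
  destinations <- if (any(is.na(destinations$snapped_node)))
    snap_points(network, destinations) else destinations
  g <- mode_graph(network, mode)
  ov <- origins$snapped_node
  dv <- destinations$snapped_node
  uo <- unique(ov)
  ud <- unique(dv)
  d <- igraph::distances(g, v = uo, to = ud, mode = "out",
                         weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  t <- d[match(ov, uo), match(dv, ud), drop = FALSE]
  dimnames(t) <- list(origins$id, destinations$id)
  structure(list(t = t, mode = mode, origins = origins,
                 destinations = destinations),
            class = "travel_time_matrix")
}

#' @export
print.travel_time_matrix <- function(x, ...) {
  fin <- is.finite(x$t)
  cat(sprintf(
    "<travel_time_matrix> %d x %d, mode %s @ %g km/h\n",
    nrow(x$t), ncol(x$t), x$mode$name, x$mode$speed_kmh))
  if (any(fin))
    cat(sprintf("  finite entries: %d/%d, range [%.1f, %.1f] s\n",
                sum(fin), length(fin), min(x$t[fin]), max(x$t[fin])))
  else cat("  no finite entries\n")
  invisible(x)
}

#' Write / read a travel-time matrix as CSV
#'
#' Rows are origin ids, columns destination ids, values seconds;
#' unreachable entries are written as `inf`.
#'
#' @param ttm a [travel_time_matrix()] (or bare matrix with dimnames).
#' @param path file path.
#' @return `read_ttmatrix_csv` returns a numeric matrix with `Inf` for
#'   unreachable entries.
#' @export
write_ttmatrix_csv <- function(ttm, path) {
  m <- if (inherits(ttm, "travel_time_matrix")) ttm$t else ttm
  out <- format(m, trim = TRUE, digits = 15, scientific = FALSE)
  out[is.infinite(m)] <- "inf"
  df <- data.frame(origin = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ttmatrix_csv
#' @export
read_ttmatrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "character"
  num <- suppressWarnings(apply(m, c(1, 2), function(v)
    if (v %in% c("inf", "Inf")) Inf else as.numeric(v)))
  rownames(num) <- df[[1]]
  num
}
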