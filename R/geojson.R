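# GeoJSON input/output. Networks are FeatureCollections of LineString
# features (one per street segment) with properties `length_m`, `oneway`
# and optional `maxspeed_<mode>`; point layers are FeatureCollections of
# Point features with properties `id` and `kind`. Coordinates are planar
# meters (projected); jsonlite does the (de)serialization.

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

#' Write a road network as GeoJSON
#'
#' One LineString feature per edge, endpoints in node order `u`, `v`.
#' Properties `u`/`v` record node ids so a round-trip preserves them;
#' readers without those properties recover nodes from exact coordinate
#' matches of segment endpoints.
#'
#' @param network a [road_network()].
#' @param path file path.
#' @export
write_network_geojson <- function(network, path) {
  n <- network$nodes
  speed_cols <- grep("^maxspeed_", names(network$edges), value = TRUE)
  feats <- lapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    props <- list(u = e$u, v = e$v, length_m = e$length, oneway = e$oneway)
    for (col in speed_cols)
      if (!is.na(e[[col]])) props[[col]] <- e[[col]]
    geojson_feature(
      list(type = "LineString",
           coordinates = list(c(n$x[n$id == e$u], n$y[n$id == e$u]),
                              c(n$x[n$id == e$v], n$y[n$id == e$v]))),
      props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' Read a road network from GeoJSON
#'
#' Accepts FeatureCollections of LineString features. Node ids are taken
#' from `u`/`v` properties when present; otherwise nodes are derived from
#' shared segment endpoints by exact coordinate match and assigned ids
#' `n0001`, `n0002`, ... in order of first appearance. `length_m` is
#' recomputed from the geometry when absent.
#'
#' @param path file path.
#' @return a [road_network()].
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  if (length(feats) == 0) stop("empty FeatureCollection")
  coord_key <- function(xy) paste(format(xy[[1]], digits = 12),
                                  format(xy[[2]], digits = 12))
  node_id <- character(0)   # keyed by coordinate string
  node_x <- numeric(0); node_y <- numeric(0)
  next_auto <- 0L
  get_node <- function(xy, id_hint) {
    key <- coord_key(xy)
    hit <- match(key, names(node_id))
    if (!is.na(hit)) return(node_id[[hit]])
    id <- if (!is.null(id_hint)) as.character(id_hint) else {
      next_auto <<- next_auto + 1L
      sprintf("n%04d", next_auto)
    }
    node_id[[key]] <<- id
    node_x <<- c(node_x, as.numeric(xy[[1]]))
    node_y <<- c(node_y, as.numeric(xy[[2]]))
    id
  }
  edges <- lapply(feats, function(f) {
    if (f$geometry$type != "LineString")
      stop("expected LineString features, got ", f$geometry$type)
    cc <- f$geometry$coordinates
    p <- f$properties %||% list()
    u <- get_node(cc[[1]], p$u)
    v <- get_node(cc[[length(cc)]], p$v)
    len <- p$length_m %||% sum(vapply(seq_len(length(cc) - 1), function(k) {
      sqrt((cc[[k + 1]][[1]] - cc[[k]][[1]])^2 +
             (cc[[k + 1]][[2]] - cc[[k]][[2]])^2)
    }, numeric(1)))
    row <- list(u = u, v = v, length = as.numeric(len),
                oneway = isTRUE(p$oneway))
    for (nm in grep("^maxspeed_", names(p), value = TRUE))
      row[[nm]] <- as.numeric(p[[nm]])
    row
  })
  speed_cols <- unique(unlist(lapply(edges, function(e)
    grep("^maxspeed_", names(e), value = TRUE))))
  edf <- do.call(rbind, lapply(edges, function(e) {
    for (col in speed_cols) if (is.null(e[[col]])) e[[col]] <- NA_real_
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
  nodes <- data.frame(id = unname(unlist(node_id)), x = node_x, y = node_y,
                      stringsAsFactors = FALSE)
  road_network(nodes, edf)
}

#' Write / read point layers as GeoJSON
#'
#' Point features with properties `id`, `kind` and, when snapped,
#' `snapped_node`.
#'
#' @param points a [point_set()].
#' @param path file path.
#' @export
write_points_geojson <- function(points, path) {
  feats <- lapply(seq_len(nrow(points)), function(i) {
    props <- list(id = points$id[i], kind = points$kind[i])
    if (!is.na(points$snapped_node[i]))
      props$snapped_node <- points$snapped_node[i]
    geojson_feature(list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])), props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  if (length(feats) == 0) stop("empty FeatureCollection")
  id <- vapply(feats, function(f) as.character(f$properties$id), character(1))
  x <- vapply(feats, function(f) as.numeric(f$geometry$coordinates[[1]]),
              numeric(1))
  y <- vapply(feats, function(f) as.numeric(f$geometry$coordinates[[2]]),
              numeric(1))
  kind <- vapply(feats, function(f) as.character(f$properties$kind),
                 character(1))
  snapped <- vapply(feats, function(f)
    as.character(f$properties$snapped_node %||% NA_character_), character(1))
  if (length(unique(kind)) != 1) stop("point set must have uniform kind")
  point_set(id, x, y, kind[1], snapped)
}
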