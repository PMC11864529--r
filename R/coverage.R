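#' Coverage parameters
#'
#' The service standard of the simulation: a demand point counts as covered
#' when it can be attended within `threshold_s` seconds (inclusive). The
#' default 300 s budget corresponds to a bystander walking to the nearest
#' AED and back at 2.5 min per stretch; `stretch_limit_s` records the
#' per-stretch reading for reporting (the budget itself is applied to the
#' total round trip). The ambulance arm travels one-way at the vehicular
#' mode's speed, respecting one-way streets; the bystander arm walks, which
#' never does.
#'
#' @param threshold_s coverage budget in seconds (> 0, default 300).
#' @param stretch_limit_s informational per-stretch limit (default
#'   `threshold_s / 2`).
#' @param bystander_mode [travel_mode()] for the bystander (default walk at
#'   10 km/h).
#' @param ambulance_mode [travel_mode()] for the ambulance (default 50 km/h).
#' @return A list of class `coverage_params`.
#' @export
coverage_params <- function(threshold_s = 300,
                            stretch_limit_s = threshold_s / 2,
                            bystander_mode = travel_mode("walk"),
                            ambulance_mode = travel_mode("ambulance")) {
  if (threshold_s <= 0) stop("threshold_s must be > 0")
  if (!inherits(bystander_mode, "travel_mode"))
    bystander_mode <- travel_mode(bystander_mode)
  if (!inherits(ambulance_mode, "travel_mode"))
    ambulance_mode <- travel_mode(ambulance_mode)
  structure(list(threshold_s = threshold_s, stretch_limit_s = stretch_limit_s,
                 bystander_mode = bystander_mode,
                 ambulance_mode = ambulance_mode),
            class = "coverage_params")
}

response_times <- function(demand, times, model, params) {
  stopifnot(length(times) == nrow(demand), all(times >= 0 | is.infinite(times)))
  structure(list(demand = demand, times = as.numeric(times), model = model,
                 params = params),
            class = "response_times")
}

#' @export
print.response_times <- function(x, ...) {
  fin <- is.finite(x$times)
  cat(sprintf("<response_times> model %s, %d demand point(s)\n",
              x$model, length(x$times)))
  if (any(fin))
    cat(sprintf("  median %.1f s, mean %.1f s (%d unreachable)\n",
                stats::median(x$times[fin]), mean(x$times[fin]), sum(!fin)))
  invisible(x)
}

#' Ambulance response times
#'
#' One-way vehicular travel time from the (nearest) ambulance station to
#' each demand point: `times[i] = min` over stations of the station-to-scene
#' shortest travel time. Dispatch, chute and on-scene intervals are not
#' modelled — this is the station-to-scene travel component only.
#'
#' @param network a [road_network()].
#' @param station a station [point_set()] (>= 1 station; minimum over
#'   stations is taken).
#' @param demand a demand [point_set()].
#' @param params [coverage_params()].
#' @return a `response_times` object, model `"ambulance"`.
#' @export
ambulance_response_times <- function(network, station, demand,
                                     params = coverage_params()) {
  if (nrow(station) == 0) stop("empty station set")
  ttm <- travel_time_matrix(network, station, demand, params$ambulance_mode)
  times <- apply(ttm$t, 2, min)
  response_times(ttm$destinations, times, "ambulance", params)
}

#' Bystander round-trip AED retrieval times
#'
#' Pedestrian displacement from the victim to the nearest AED and back:
#' `times[i] = min` over AED sites of the walk time there plus the walk
#' time back. Walking traversal is undirected, so the round trip equals
#' exactly twice the one-way time. With no AED sites every time is `Inf`.
#'
#' @param network a [road_network()].
#' @param demand a demand [point_set()] (non-empty).
#' @param aed_sites an AED [point_set()] (candidate kind; may be empty).
#' @param params [coverage_params()].
#' @return a `response_times` object, model `"bystander_roundtrip"`.
#' @export
bystander_roundtrip_times <- function(network, demand, aed_sites,
                                      params = coverage_params()) {
  if (nrow(demand) == 0) stop("empty demand set")
  if (nrow(aed_sites) == 0) {
    demand <- if (any(is.na(demand$snapped_node)))
      snap_points(network, demand) else demand
    return(response_times(demand, rep(Inf, nrow(demand)),
                          "bystander_roundtrip", params))
  }
  there <- travel_time_matrix(network, demand, aed_sites,
                              params$bystander_mode)
  back <- travel_time_matrix(network, aed_sites, there$origins,
                             params$bystander_mode)
  round_trip <- there$t + t(back$t)
  times <- apply(round_trip, 1, min)
  response_times(there$origins, times, "bystander_roundtrip", params)
}

#' Count demand points covered within the time budget
#'
#' Inclusive rule: a point attended at exactly the threshold counts as
#' covered.
#'
#' @param times a `response_times` object (or bare numeric vector).
#' @param params [coverage_params()]; ignored when `times` carries its own.
#' @return list with `count`, `n` and `fraction`.
#' @export
coverage_count <- function(times, params = NULL) {
  if (inherits(times, "response_times")) {
    params <- params %||% times$params
    times <- times$times
  }
  if (is.null(params)) params <- coverage_params()
  cnt <- sum(times <= params$threshold_s)
  list(count = cnt, n = length(times), fraction = cnt / length(times))
}

#' Demand-by-candidate binary coverage matrix
#'
#' `a[i, j] = 1` iff the bystander round trip between demand point `i` and
#' candidate site `j` fits the budget (`<= threshold_s`, inclusive). This
#' is the coverage relation the maximal covering location problem
#' maximizes over.
#'
#' @param network a [road_network()].
#' @param demand a demand [point_set()].
#' @param candidates a candidate [point_set()].
#' @param params [coverage_params()].
#' @return An object of class `coverage_matrix` with fields `a` (0/1
#'   integer matrix, dimnames = ids), `demand`, `candidates`, `params`.
#' @export
build_coverage_matrix <- function(network, demand, candidates,
                                  params = coverage_params()) {
  there <- travel_time_matrix(network, demand, candidates,
                              params$bystander_mode)
  back <- travel_time_matrix(network, candidates, there$origins,
                             params$bystander_mode)
  rt <- there$t + t(back$t)
  a <- matrix(as.integer(rt <= params$threshold_s), nrow = nrow(rt),
              dimnames = dimnames(there$t))
  structure(list(a = a, demand = there$origins,
                 candidates = there$destinations, params = params),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf(
    "<coverage_matrix> %d demand x %d candidates, budget %g s\n",
    nrow(x$a), ncol(x$a), x$params$threshold_s))
  cat(sprintf("  coverable demand points: %d/%d\n",
              sum(rowSums(x$a) > 0), nrow(x$a)))
  invisible(x)
}

#' Write response times as CSV
#'
#' Columns `id`, `seconds` (with `inf` for unreachable), plus the model
#' name as a column so files from both arms can be concatenated.
#'
#' @param rt a `response_times` object.
#' @param path file path.
#' @export
write_response_times_csv <- function(rt, path) {
  secs <- ifelse(is.finite(rt$times),
                 format(rt$times, trim = TRUE, digits = 15,
                        scientific = FALSE), "inf")
  df <- data.frame(id = rt$demand$id, model = rt$model, seconds = secs,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
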