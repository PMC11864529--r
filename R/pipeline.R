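#' Experiment configuration
#'
#' One config drives the whole simulated comparison: generate a city,
#' sample demand, place a station and candidate AED sites, compute
#' ambulance response times, optimize AED siting with MCLP, compute
#' bystander round-trip times, and compare the arms. Two simulations are
#' run for every demand point — one per response arm — on the identical
#' point set, in identical order.
#'
#' @param city a [city_config()].
#' @param coverage a [coverage_params()].
#' @param station_position `"corner"`, `"centroid"`, or a node id.
#' @param mclp list: `mode` (`"fixed_p"` or `"min_for_target"`), `p`
#'   (facility budget, for `fixed_p`), `target_fraction` (for
#'   `min_for_target`), `solver` (`"greedy"` or `"exact"`).
#' @param stats list: `ci_method` (`"t"`/`"bootstrap"`), `exact_limit`,
#'   `continuity`.
#' @param seed master integer seed; stage seeds are derived from it, so a
#'   config + seed pair fully determines every output.
#' @param output_dir optional directory; when set, [run_experiment()]
#'   writes all layers and reports there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(city = city_config(),
                              coverage = coverage_params(),
                              station_position = "corner",
                              mclp = list(mode = "fixed_p", p = 18,
                                          solver = "greedy"),
                              stats = list(ci_method = "t", exact_limit = 25,
                                           continuity = FALSE),
                              seed = 1, output_dir = NULL) {
  stopifnot(inherits(city, "city_config"), inherits(coverage, "coverage_params"))
  mclp$mode <- match.arg(mclp$mode %||% "fixed_p",
                         c("fixed_p", "min_for_target"))
  mclp$solver <- match.arg(mclp$solver %||% "greedy", c("greedy", "exact"))
  if (mclp$mode == "fixed_p" && is.null(mclp$p))
    stop("mclp mode fixed_p requires p")
  if (mclp$mode == "min_for_target" && is.null(mclp$target_fraction))
    stop("mclp mode min_for_target requires target_fraction")
  stats$ci_method <- match.arg(stats$ci_method %||% "t", c("t", "bootstrap"))
  stats$exact_limit <- stats$exact_limit %||% 25
  stats$continuity <- isTRUE(stats$continuity)
  structure(list(city = city, coverage = coverage,
                 station_position = station_position, mclp = mclp,
                 stats = stats, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

config_fingerprint <- function(config) {
  s <- config
  s$output_dir <- NULL
  fnv1a32(jsonlite::toJSON(unclass_recursive(s), auto_unbox = TRUE,
                           digits = NA))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' The shipped replication configuration
#'
#' Loads the packaged config emulating the study scenario: 50 demand
#' points in the central region, a 300 s budget, bystanders walking at
#' 10 km/h, ambulances at 50 km/h from a single corner station, and 18
#' MCLP-sited AEDs chosen from 80 candidates.
#'
#' @param seed master seed (default 1).
#' @param output_dir optional output directory.
#' @return an [experiment_config()].
#' @export
replication_config <- function(seed = 1, output_dir = NULL) {
  path <- system.file("extdata", "replication.yaml", package = "aedcover")
  load_experiment_config(path, seed = seed, output_dir = output_dir)
}

#' Load an experiment configuration from YAML
#'
#' Keys mirror the constructors: sections `city`, `coverage` (with
#' `threshold_s`, `bystander_speed_kmh`, `ambulance_speed_kmh`),
#' `station_position`, `mclp`, `stats`, `seed`.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @param output_dir optional output directory.
#' @return an [experiment_config()].
#' @export
load_experiment_config <- function(path, seed = NULL, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  city <- do.call(city_config, y$city %||% list())
  cov <- coverage_params(
    threshold_s = y$coverage$threshold_s %||% 300,
    bystander_mode = travel_mode("walk",
                                 y$coverage$bystander_speed_kmh %||% 10),
    ambulance_mode = travel_mode("ambulance",
                                 y$coverage$ambulance_speed_kmh %||% 50))
  experiment_config(
    city = city, coverage = cov,
    station_position = y$station_position %||% "corner",
    mclp = y$mclp %||% list(mode = "fixed_p", p = 18, solver = "greedy"),
    stats = y$stats %||% list(),
    seed = seed %||% y$seed %||% 1,
    output_dir = output_dir)
}

#' Run the full simulated comparison
#'
#' Executes the pipeline end to end: generate city, sample demand, place
#' station and candidates, compute ambulance response times and coverage,
#' build the demand-candidate coverage matrix, site AEDs by MCLP, compute
#' bystander round-trip times and coverage, run the Shapiro-Wilk check on
#' each arm and the Wilcoxon signed-rank comparison. Any stage failure
#' aborts with the stage name in the error message. Fully reproducible
#' from config + seed; when `config$output_dir` is set all layers and the
#' report are written there (see [write_experiment()]).
#'
#' @param config an [experiment_config()].
#' @return An object of class `aed_experiment`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) stop_stage(name, e))

  cc <- config$city
  cc$seed <- seed
  network <- stage("generate_city", generate_grid_city(cc))
  demand <- stage("sample_demand",
    snap_points(network, sample_demand_points(network, cc$n_demand,
                                              cc$center_fraction,
                                              seed = seed + 1L)))
  candidates <- stage("place_candidates",
    place_candidates(network, cc$n_candidates, seed = seed + 2L))
  station <- stage("place_station",
    place_station(network, config$station_position, seed = seed + 3L))

  amb <- stage("ambulance_times",
    ambulance_response_times(network, station, demand, config$coverage))
  cov_mat <- stage("coverage_matrix",
    build_coverage_matrix(network, demand, candidates, config$coverage))
  sol <- stage("mclp", {
    if (config$mclp$mode == "fixed_p") {
      prob <- mclp_problem(cov_mat, p = min(config$mclp$p, nrow(candidates)))
      if (config$mclp$solver == "exact") solve_mclp_exact(prob)
      else solve_mclp_greedy(prob)
    } else {
      min_facilities_for_target(cov_mat, config$mclp$target_fraction,
                                solver = config$mclp$solver)$solution
    }
  })
  aed_sites <- candidates[candidates$id %in% sol$selected, ]
  class(aed_sites) <- class(candidates)
  bys <- stage("bystander_times",
    bystander_roundtrip_times(network, demand, aed_sites, config$coverage))

  amb_sum <- stage("summaries",
    summarize_times(amb$times, ci_method = config$stats$ci_method,
                    seed = seed + 4L))
  bys_sum <- stage("summaries",
    summarize_times(bys$times, ci_method = config$stats$ci_method,
                    seed = seed + 5L))

  finite <- is.finite(amb$times) & is.finite(bys$times)
  n_excluded <- sum(!finite)
  comparison <- stage("wilcoxon", wilcoxon_signed_rank(
    paired_comparison(amb$times[finite], bys$times[finite],
                      labels = c("ambulance", "bystander_roundtrip")),
    exact_limit = config$stats$exact_limit,
    continuity = config$stats$continuity))
  normality <- stage("shapiro_wilk", list(
    ambulance = shapiro_wilk(amb$times[finite]),
    bystander = shapiro_wilk(bys$times[finite])))

  report <- structure(list(
    network = network, demand = demand, candidates = candidates,
    station = station,
    ambulance = list(times = amb, summary = amb_sum,
                     coverage = coverage_count(amb)),
    bystander = list(times = bys, summary = bys_sum,
                     coverage = coverage_count(bys)),
    coverage_matrix = cov_mat, mclp_solution = sol,
    normality = normality, comparison = comparison,
    n_excluded_pairs = n_excluded,
    provenance = list(seed = seed, config = config,
                      config_hash = config_fingerprint(config),
                      package_version = as.character(
                        utils::packageVersion("aedcover")))),
    class = "aed_experiment")
  if (!is.null(config$output_dir))
    write_experiment(report, config$output_dir)
  report
}

#' @export
print.aed_experiment <- function(x, ...) {
  cat("<aed_experiment>", sprintf("seed %d, config %s\n",
      x$provenance$seed, x$provenance$config_hash))
  th <- x$ambulance$times$params$threshold_s
  cat(sprintf("  ambulance: %d/%d covered within %g s; ",
              x$ambulance$coverage$count, x$ambulance$coverage$n, th))
  cat(sprintf("mean %.0f s, median %.0f s\n",
              x$ambulance$summary$mean, x$ambulance$summary$median))
  cat(sprintf("  bystander: %d/%d covered within %g s; ",
              x$bystander$coverage$count, x$bystander$coverage$n, th))
  cat(sprintf("mean %.0f s, median %.0f s (%d AED sites)\n",
              x$bystander$summary$mean, x$bystander$summary$median,
              length(x$mclp_solution$selected)))
  cat(sprintf("  Wilcoxon signed-rank: z = %.3f, p = %.3g (%s)\n",
              x$comparison$z, x$comparison$p, x$comparison$method))
  invisible(x)
}

#' Long-format export of both response arms
#'
#' One row per (demand point, arm): columns `demand_id`, `arm`, `seconds`.
#' Pairing is preserved — joining the two arms on `demand_id` reconstructs
#' the paired differences exactly.
#'
#' @param report an `aed_experiment`.
#' @param path optional CSV path; when given, written with a provenance
#'   comment line.
#' @return the data.frame, invisibly when `path` is given.
#' @export
export_violin_data <- function(report, path = NULL) {
  df <- rbind(
    data.frame(demand_id = report$demand$id, arm = "ambulance",
               seconds = report$ambulance$times$times,
               stringsAsFactors = FALSE),
    data.frame(demand_id = report$demand$id, arm = "bystander",
               seconds = report$bystander$times$times,
               stringsAsFactors = FALSE))
  if (is.null(path)) return(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(report), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(df)
}

provenance_line <- function(report) {
  sprintf("# aedcover seed=%d config=%s version=%s",
          report$provenance$seed, report$provenance$config_hash,
          report$provenance$package_version)
}

#' Write every experiment artifact to a directory
#'
#' GeoJSON layers (network, demand, candidates, station, selected AED
#' sites), CSVs (paired response times in long format, the coverage
#' matrix) and a structured text report. Every file carries the seed and
#' config fingerprint; outputs are byte-identical across repeated runs of
#' the same config + seed.
#'
#' @param report an `aed_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_network_geojson(report$network, fp("network.geojson"))
  write_points_geojson(report$demand, fp("demand.geojson"))
  write_points_geojson(report$candidates, fp("candidates.geojson"))
  write_points_geojson(report$station, fp("station.geojson"))
  sel <- report$candidates[report$candidates$id %in%
                             report$mclp_solution$selected, ]
  class(sel) <- class(report$candidates)
  write_points_geojson(sel, fp("selected_aeds.geojson"))
  export_violin_data(report, fp("response_times.csv"))
  cm <- report$coverage_matrix
  con <- file(fp("coverage_matrix.csv"), "w")
  writeLines(provenance_line(report), con)
  utils::write.table(
    data.frame(demand_id = rownames(cm$a), cm$a, check.names = FALSE),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  writeLines(format_experiment_report(report), fp("report.txt"))
  invisible(dir)
}

format_experiment_report <- function(x) {
  th <- x$ambulance$times$params$threshold_s
  fmt_arm <- function(name, arm) c(
    sprintf("%s_covered: %d", name, arm$coverage$count),
    sprintf("%s_n: %d", name, arm$coverage$n),
    sprintf("%s_fraction: %.6f", name, arm$coverage$fraction),
    sprintf("%s_mean_s: %.6f", name, arm$summary$mean),
    sprintf("%s_median_s: %.6f", name, arm$summary$median),
    sprintf("%s_sd_s: %.6f", name, arm$summary$sd),
    sprintf("%s_ci_low_s: %.6f", name, arm$summary$ci_low),
    sprintf("%s_ci_high_s: %.6f", name, arm$summary$ci_high))
  c(provenance_line(x),
    sprintf("threshold_s: %g", th),
    fmt_arm("ambulance", x$ambulance),
    fmt_arm("bystander", x$bystander),
    sprintf("mclp_method: %s", x$mclp_solution$method),
    sprintf("mclp_sites: %d", length(x$mclp_solution$selected)),
    sprintf("mclp_objective: %g", x$mclp_solution$objective),
    sprintf("mclp_selected: %s",
            paste(x$mclp_solution$selected, collapse = ",")),
    sprintf("shapiro_ambulance_W: %.6f", x$normality$ambulance$w_statistic),
    sprintf("shapiro_ambulance_p: %.6g", x$normality$ambulance$p),
    sprintf("shapiro_bystander_W: %.6f", x$normality$bystander$w_statistic),
    sprintf("shapiro_bystander_p: %.6g", x$normality$bystander$p),
    sprintf("wilcoxon_w_plus: %g", x$comparison$w_plus),
    sprintf("wilcoxon_w_minus: %g", x$comparison$w_minus),
    sprintf("wilcoxon_z: %.6f", x$comparison$z),
    sprintf("wilcoxon_p: %.6g", x$comparison$p),
    sprintf("wilcoxon_method: %s", x$comparison$method),
    sprintf("excluded_pairs: %d", x$n_excluded_pairs))
}
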