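line_net <- function(spacing = 500, n = 10) {
  # straight street: nodes every `spacing` m
  road_network(
    data.frame(id = sprintf("n%02d", 1:n), x = (0:(n - 1)) * spacing, y = 0),
    data.frame(u = sprintf("n%02d", 1:(n - 1)), v = sprintf("n%02d", 2:n),
               length = spacing))
}

test_that("coverage parameter defaults encode the 300 s budget", {
  p <- coverage_params()
  expect_equal(p$threshold_s, 300)
  expect_equal(2 * p$stretch_limit_s, p$threshold_s)
  expect_equal(p$bystander_mode$speed_kmh, 10)
  expect_equal(p$ambulance_mode$speed_kmh, 50)
  expect_error(coverage_params(threshold_s = 0), "threshold_s")
})

test_that("ambulance times are one-way station-to-scene minima", {
  net <- line_net()
  station <- snap_points(net, point_set("s1", 0, 0, "station"))
  demand <- snap_points(net, point_set(c("d1", "d2"), c(0, 4500), c(0, 0),
                                       "demand"))
  rt <- ambulance_response_times(net, station, demand)
  expect_equal(rt$times[1], 0)                      # co-located
  expect_equal(rt$times[2], 4.5 / 50 * 3600)        # 4.5 km at 50 km/h = 324 s
  expect_error(ambulance_response_times(net, demand[0, ], demand),
               "empty station")
})

test_that("several stations: each demand point gets the nearest", {
  net <- line_net()
  stations <- snap_points(net, point_set(c("s1", "s2"), c(0, 4500), c(0, 0),
                                         "station"))
  demand <- snap_points(net, point_set(c("d1", "d2"), c(500, 4000), c(0, 0),
                                       "demand"))
  rt <- ambulance_response_times(net, stations, demand)
  expect_equal(rt$times, c(0.5, 0.5) / 50 * 3600)
})

test_that("bystander round trip is exactly twice the one-way walk time", {
  net <- tiny_city()
  demand <- snap_points(net, sample_demand_points(net, 10, seed = 1))
  aeds <- place_candidates(net, 4, seed = 2)
  rt <- bystander_roundtrip_times(net, demand, aeds)
  oneway <- travel_time_matrix(net, demand, aeds, "walk")$t
  expect_equal(rt$times, unname(2 * apply(oneway, 1, min)))
})

test_that("no AED sites means every demand point is unreachable", {
  net <- line_net()
  demand <- snap_points(net, point_set("d1", 0, 0, "demand"))
  rt <- bystander_roundtrip_times(net, demand, demand[0, ])
  expect_true(all(is.infinite(rt$times)))
  aed_here <- snap_points(net, point_set("c1", 0, 0, "candidate"))
  expect_equal(bystander_roundtrip_times(net, demand, aed_here)$times, 0)
})

test_that("coverage counting is inclusive at the boundary", {
  res <- coverage_count(c(300, 300.1, 299.9), coverage_params())
  expect_equal(res$count, 2)
  expect_equal(res$fraction, 2 / 3)
  expect_equal(coverage_count(rep(Inf, 5), coverage_params())$count, 0)
})

test_that("a 150 s one-way walk is covered at the 300 s round-trip budget", {
  # ~416.667 m at 10 km/h = 150 s each stretch (length chosen so the
  # float product is exactly 150, pinning the inclusive boundary)
  L <- 416.66666666666663
  net <- road_network(
    data.frame(id = c("a", "b"), x = c(0, L), y = 0),
    data.frame(u = "a", v = "b", length = L))
  demand <- snap_points(net, point_set("d1", 0, 0, "demand"))
  aed <- snap_points(net, point_set("c1", L, 0, "candidate"))
  rt <- bystander_roundtrip_times(net, demand, aed)
  expect_equal(rt$times, 300)
  expect_equal(coverage_count(rt)$count, 1)
})

test_that("coverage matrix equals entrywise round-trip recomputation", {
  net <- tiny_city()
  demand <- snap_points(net, sample_demand_points(net, 15, seed = 3))
  cands <- place_candidates(net, 10, seed = 4)
  cm <- build_coverage_matrix(net, demand, cands)
  oneway <- travel_time_matrix(net, demand, cands, "walk")$t
  expect_equal(unname(cm$a), unname(matrix(as.integer(2 * oneway <= 300),
                                           nrow = 15)))
  # candidate co-located with a demand point covers it
  at_demand <- point_set("c1", demand$x[1], demand$y[1], "candidate",
                         snapped_node = demand$snapped_node[1])
  cm2 <- build_coverage_matrix(net, demand, at_demand)
  expect_equal(cm2$a[1, 1], 1L)
})

test_that("a candidate beyond the 417 m walking reach covers nothing", {
  net <- line_net(spacing = 500, n = 10)
  demand <- snap_points(net, point_set(c("d1", "d2"), c(0, 500), c(0, 0),
                                       "demand"))
  far <- snap_points(net, point_set("c1", 4500, 0, "candidate"))
  cm <- build_coverage_matrix(net, demand, far)
  expect_true(all(cm$a == 0L))
})

test_that("adding an AED never worsens times; raising the budget never loses points", {
  net <- tiny_city()
  demand <- snap_points(net, sample_demand_points(net, 12, seed = 5))
  a1 <- place_candidates(net, 3, seed = 6)
  t1 <- bystander_roundtrip_times(net, demand, a1)$times
  a2 <- rbind(a1, point_set("c999", net$nodes$x[1], net$nodes$y[1],
                            "candidate", snapped_node = net$nodes$id[1]))
  class(a2) <- class(a1)
  t2 <- bystander_roundtrip_times(net, demand, a2)$times
  expect_true(all(t2 <= t1 + 1e-9))
  expect_gte(coverage_count(t2, coverage_params())$count,
             coverage_count(t1, coverage_params())$count)
  for (th in c(60, 120, 240, 480)) {
    lo <- coverage_count(t1, coverage_params(threshold_s = th))$count
    hi <- coverage_count(t1, coverage_params(threshold_s = th + 60))$count
    expect_lte(lo, hi)
  }
})

test_that("ambulances respect one-way streets while bystanders never do", {
  net <- road_network(
    data.frame(id = c("a", "b"), x = c(0, 400), y = 0),
    data.frame(u = "b", v = "a", length = 400, oneway = TRUE))
  station <- snap_points(net, point_set("s1", 0, 0, "station"))
  demand <- snap_points(net, point_set("d1", 400, 0, "demand"))
  amb <- ambulance_response_times(net, station, demand)
  expect_true(is.infinite(amb$times))          # a -> b blocked for vehicles
  aed_at_station <- point_set("c1", 0, 0, "candidate", snapped_node = "a")
  bys <- bystander_roundtrip_times(net, demand, aed_at_station)
  expect_equal(bys$times, 2 * 0.4 / 10 * 3600) # walkable both ways
})
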