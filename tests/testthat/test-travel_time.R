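test_that("network construction enforces its invariants", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 500), y = c(0, 0))
  expect_error(road_network(nodes, data.frame(u = "a", v = "b", length = 0)),
               "length")
  expect_error(road_network(nodes, data.frame(u = "a", v = "z", length = 1)),
               "not declared")
  expect_error(road_network(rbind(nodes, nodes),
                            data.frame(u = "a", v = "b", length = 1)),
               "unique")
  expect_error(travel_mode("helicopter"), "unknown travel mode")
  expect_error(travel_mode("walk", -1), "positive")
})

test_that("default mode speeds are the standardized study values", {
  expect_equal(travel_mode("walk")$speed_kmh, 10)
  expect_equal(travel_mode("ambulance")$speed_kmh, 50)
  expect_gt(travel_mode("bicycle")$speed_kmh, 0)
  expect_gt(travel_mode("car")$speed_kmh, 0)
})

two_node_net <- function(oneway = FALSE) {
  road_network(data.frame(id = c("a", "b"), x = c(0, 500), y = c(0, 0)),
               data.frame(u = "a", v = "b", length = 500, oneway = oneway))
}

test_that("single-edge travel times match hand arithmetic", {
  net <- two_node_net()
  expect_equal(shortest_travel_time(net, "a", "b", "walk"), 180)      # 0.5 km / 10 km/h
  expect_equal(shortest_travel_time(net, "a", "b", "ambulance"), 36)  # 0.5 km / 50 km/h
  expect_equal(shortest_travel_time(net, "a", "a", "walk"), 0)
})

test_that("one-way edges block vehicles but never pedestrians", {
  net <- two_node_net(oneway = TRUE)
  expect_equal(shortest_travel_time(net, "b", "a", "car"), Inf)
  expect_equal(shortest_travel_time(net, "a", "b", "car"), 45)
  expect_equal(shortest_travel_time(net, "b", "a", "walk"), 180)
})

test_that("per-edge speed overrides take precedence over the mode default", {
  net <- road_network(
    data.frame(id = c("a", "b"), x = c(0, 1000), y = c(0, 0)),
    data.frame(u = "a", v = "b", length = 1000, oneway = FALSE,
               maxspeed_car = 20, maxspeed_walk = NA))
  expect_equal(shortest_travel_time(net, "a", "b", "car"), 180)  # 1 km / 20 km/h
  expect_equal(shortest_travel_time(net, "a", "b", "walk"), 360) # default 10
})

test_that("snapping is nearest-node with lowest-id tie break", {
  net <- road_network(data.frame(id = c("n1", "n2"), x = c(0, 100), y = c(0, 0)),
                      data.frame(u = "n1", v = "n2", length = 100))
  pts <- point_set(c("p1", "p2"), c(0, 50), c(0, 0), "demand")
  sn <- snap_points(net, pts)
  expect_equal(sn$snapped_node, c("n1", "n1"))  # exact hit; equidistant tie
  expect_equal(sn$x, pts$x)                     # coordinates preserved
  empty <- road_network(data.frame(id = character(), x = numeric(),
                                   y = numeric()),
                        data.frame(u = character(), v = character(),
                                   length = numeric()))
  expect_error(snap_points(empty, pts), "no nodes to snap to")
})

test_that("snapping agrees with an exhaustive nearest-node scan", {
  net <- random_network(n = 30, seed = 11)
  set.seed(42)
  pts <- point_set(sprintf("p%02d", 1:20), runif(20, 0, 1000),
                   runif(20, 0, 1000), "demand")
  sn <- snap_points(net, pts)
  for (i in 1:20) {
    d <- sqrt((net$nodes$x - pts$x[i])^2 + (net$nodes$y - pts$y[i])^2)
    expect_equal(sn$snapped_node[i], net$nodes$id[which.min(d)])
  }
})

test_that("shortest paths equal the Floyd-Warshall oracle on random graphs", {
  for (seed in 1:5) {
    net <- random_network(n = 30, seed = seed)
    for (mode in c("walk", "car", "ambulance")) {
      D <- fw_all_pairs(net, mode)
      pts <- point_set(paste0("q", seq_len(nrow(net$nodes))),
                       net$nodes$x, net$nodes$y, "demand",
                       snapped_node = net$nodes$id)
      ttm <- travel_time_matrix(net, pts, pts, mode)
      expect_equal(unname(ttm$t), unname(D), tolerance = 1e-9)
    }
  }
})

test_that("matrix entries equal per-pair shortest_travel_time calls", {
  net <- random_network(n = 15, seed = 3)
  set.seed(5)
  org <- snap_points(net, point_set(sprintf("o%d", 1:5), runif(5, 0, 1000),
                                    runif(5, 0, 1000), "demand"))
  dst <- snap_points(net, point_set(sprintf("t%d", 1:8), runif(8, 0, 1000),
                                    runif(8, 0, 1000), "candidate"))
  ttm <- travel_time_matrix(net, org, dst, "car")
  for (i in 1:5) for (j in 1:8)
    expect_equal(ttm$t[i, j],
                 shortest_travel_time(net, org$snapped_node[i],
                                      dst$snapped_node[j], "car"))
})

test_that("degenerate matrices behave: 1x1 zero and disconnected Inf column", {
  net <- road_network(
    data.frame(id = c("a", "b", "c"), x = c(0, 100, 5000), y = 0),
    data.frame(u = "a", v = "b", length = 100))
  p1 <- snap_points(net, point_set("p", 0, 0, "demand"))
  expect_equal(unname(travel_time_matrix(net, p1, p1, "walk")$t),
               matrix(0))
  far <- point_set("f", 5000, 0, "candidate", snapped_node = "c")
  both <- snap_points(net, point_set(c("p", "q"), c(0, 100), c(0, 0), "demand"))
  expect_true(all(is.infinite(travel_time_matrix(net, both, far, "walk")$t)))
})

test_that("walk matrices are symmetric and times scale inversely with speed", {
  net <- random_network(n = 25, seed = 9)
  pts <- point_set(paste0("q", seq_len(25)), net$nodes$x, net$nodes$y,
                   "demand", snapped_node = net$nodes$id)
  w1 <- travel_time_matrix(net, pts, pts, travel_mode("walk", 10))$t
  expect_equal(w1, t(w1))
  w2 <- travel_time_matrix(net, pts, pts, travel_mode("walk", 20))$t
  fin <- is.finite(w1)
  expect_equal(w1[fin] / 2, w2[fin], tolerance = 1e-9)
  expect_true(all(is.infinite(w2[!fin])))
})

test_that("adding an edge never increases any travel time", {
  net <- random_network(n = 20, m = 30, seed = 13)
  pts <- point_set(paste0("q", 1:20), net$nodes$x, net$nodes$y, "demand",
                   snapped_node = net$nodes$id)
  before <- travel_time_matrix(net, pts, pts, "car")$t
  extra <- data.frame(u = "n001", v = "n015",
                      length = sqrt((net$nodes$x[1] - net$nodes$x[15])^2 +
                                      (net$nodes$y[1] - net$nodes$y[15])^2),
                      oneway = FALSE)
  net2 <- road_network(net$nodes, rbind(net$edges, extra))
  after <- travel_time_matrix(net2, pts, pts, "car")$t
  expect_true(all(after <= before + 1e-9))
})

test_that("triangle inequality holds among snapped nodes within one mode", {
  net <- random_network(n = 12, seed = 21)
  pts <- point_set(paste0("q", 1:12), net$nodes$x, net$nodes$y, "demand",
                   snapped_node = net$nodes$id)
  D <- travel_time_matrix(net, pts, pts, "car")$t
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    if (is.finite(D[i, k]) && is.finite(D[k, j]))
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})
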