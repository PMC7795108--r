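test_that("edge times follow the class speed table", {
  # 80 km of national road at 80 km/h is one hour
  seg <- road_segment(rbind(c(0, 0), c(80000, 0)), "national")
  net <- build_network(list(seg))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$time_min, 60)
  # class -> speed defaults
  expect_equal(unname(road_speeds[c("national", "provincial", "county",
                                    "township", "special", "village",
                                    "rail_highspeed", "rail_ordinary")]),
               c(80, 70, 50, 25, 20, 15, 200, 120))
  expect_error(road_segment(rbind(c(0, 0), c(0, 0)), "county"),
               "zero-length")
})

test_that("rail edges are present iff include_rail", {
  segs <- list(road_segment(rbind(c(0, 0), c(1000, 0)), "county"),
               road_segment(rbind(c(0, 100), c(1000, 100)),
                            "rail_ordinary"))
  with_rail <- build_network(segs, include_rail = TRUE)
  without <- build_network(segs, include_rail = FALSE)
  expect_true(any(with_rail$edges$is_rail))
  expect_false(any(without$edges$is_rail))
})

test_that("crossing segments share a node with four incident edges", {
  segs <- list(road_segment(rbind(c(-1000, 0), c(1000, 0)), "county"),
               road_segment(rbind(c(0, -1000), c(0, 1000)), "county"))
  net <- build_network(segs)
  # geometric oracle: the crossing is at the origin
  atorigin <- which(abs(net$nodes[, 1]) < 1e-6 &
                      abs(net$nodes[, 2]) < 1e-6)
  expect_length(atorigin, 1)
  incident <- sum(net$edges$from == atorigin | net$edges$to == atorigin)
  expect_equal(incident, 4)
  expect_equal(nrow(net$edges), 4)
})

test_that("access legs follow the walk/feeder two-speed rule", {
  net <- build_network(list(road_segment(rbind(c(0, 0), c(10000, 0)),
                                         "county")))
  # 1000 m (within 1250 m) walked at 5 km/h -> 12 min
  leg <- access_leg(c(5000, 1000), net, metric = "time")
  expect_equal(leg$cost, 12)
  expect_equal(leg$dist, 1000)
  # 2500 m (beyond 1250 m) at the 25 km/h feeder speed -> 6 min
  expect_equal(access_leg(c(5000, 2500), net, metric = "time")$cost, 6)
  # on the road: zero
  expect_equal(access_leg(c(5000, 0), net, metric = "time")$cost, 0)
  # space metric: raw meters
  expect_equal(access_leg(c(5000, 2500), net, metric = "space")$cost, 2500)
})

test_that("od_cost matches hand values on simple configurations", {
  net <- build_network(list(road_segment(rbind(c(0, 0), c(10000, 0)),
                                         "county")))
  # same edge, 4 km apart at 50 km/h -> 4.8 min
  expect_equal(od_cost(c(2000, 0), c(6000, 0), net, metric = "time"), 4.8)
  # identity in both metrics
  expect_equal(od_cost(c(3000, 500), c(3000, 500), net, metric = "time"),
               0)
  expect_equal(od_cost(c(3000, 500), c(3000, 500), net, metric = "space"),
               0)
  # direct candidate eliminates the network detour: points 150 m apart,
  # each 100 m off the road -> 0.15 km walked at 5 km/h = 1.8 min
  segs2 <- list(road_segment(rbind(c(0, 0), c(100, 0)), "village"),
                road_segment(rbind(c(10000, 0), c(10100, 0)), "village"))
  net2 <- build_network(segs2)
  o <- c(50, 100); d <- c(200, 100)
  expect_equal(od_cost(o, d, net2, metric = "time"), 1.8)
  # the plain node-cost result is far worse (disconnected here -> direct)
  expect_equal(sqrt(sum((o - d)^2)), 150)
})

test_that("cost matrix on the fixture equals exhaustive path enumeration", {
  fx <- fixture_minimal()
  p <- access_params()
  for (metric in c("time", "space")) {
    cm <- cost_matrix(fx$cells, fx$facilities, fx$network, p, metric)
    for (i in seq_len(nrow(fx$cells)))
      for (k in seq_len(nrow(fx$facilities))) {
        expected <- oracle_od_cost(
          c(fx$cells$x[i], fx$cells$y[i]),
          c(fx$facilities$x[k], fx$facilities$y[k]),
          fx$network, p, metric)
        expect_equal(cm$cost[i, k], expected, tolerance = 1e-10,
                     label = paste("cell", i, "facility", k, metric))
      }
  }
})

test_that("adding a facility appends a column without changing others", {
  fx <- fixture_minimal()
  cm1 <- cost_matrix(fx$cells, fx$facilities, fx$network, metric = "time")
  fac2 <- rbind(fx$facilities,
                data.frame(id = "f5", x = 1500, y = 4500,
                           level = "primary", staff = 5,
                           capacity_weight = 1, city_id = 1L))
  cm2 <- cost_matrix(fx$cells, fac2, fx$network, metric = "time")
  expect_equal(cm2$cost[, colnames(cm1$cost)], cm1$cost)
  expect_equal(ncol(cm2$cost), ncol(cm1$cost) + 1)
})

test_that("the space metric never uses speeds", {
  fx <- fixture_minimal()
  fast <- lapply(fx$segments, function(s)
    road_segment(s$coords, s$road_class, s$speed_kmh * 2))
  net_fast <- build_network(fast, include_rail = FALSE)
  cm <- cost_matrix(fx$cells, fx$facilities, fx$network, metric = "space")
  cm_fast <- cost_matrix(fx$cells, fx$facilities, net_fast,
                         metric = "space")
  expect_equal(cm$cost, cm_fast$cost)
  # but the time metric does change
  cm_t <- cost_matrix(fx$cells, fx$facilities, fx$network, metric = "time")
  cm_tf <- cost_matrix(fx$cells, fx$facilities, net_fast, metric = "time")
  expect_true(any(cm_tf$cost < cm_t$cost))
})

test_that("improved rule never exceeds plain node-cost; time cost is
          bounded below by distance at top network speed", {
  r <- generate_region(small_config(seed = 4))
  p <- access_params()
  cmin <- cost_matrix(r$cells, r$facilities, r$network, p, "time", "min")
  cnode <- cost_matrix(r$cells, r$facilities, r$network, p, "time", "node")
  expect_true(all(cmin$cost <= cnode$cost + 1e-9))
  dd <- sqrt(outer(r$cells$x, r$facilities$x, "-")^2 +
               outer(r$cells$y, r$facilities$y, "-")^2)
  vmax <- max(road_speeds) * 1000 / 60  # m per min
  expect_true(all(cmin$cost >= dd / vmax - 1e-9))
})

test_that("triangle inequality holds up to the intermediate access legs", {
  fx <- fixture_minimal()
  p <- access_params()
  # provable for the node-cost route (concatenating the two legs through b
  # is itself a candidate route); the direct short-circuit of the improved
  # rule can only lower the left-hand side further
  pts <- cbind(fx$cells$x, fx$cells$y)
  for (a in c(1, 3, 7)) for (b in c(2, 5)) for (cc in c(6, 9)) {
    ac_node <- od_cost(pts[a, ], pts[cc, ], fx$network, p, "time", "node")
    ac_min <- od_cost(pts[a, ], pts[cc, ], fx$network, p, "time", "min")
    ab <- od_cost(pts[a, ], pts[b, ], fx$network, p, "time", "node")
    bc <- od_cost(pts[b, ], pts[cc, ], fx$network, p, "time", "node")
    legb <- access_leg(pts[b, ], fx$network, p, "time")$cost
    expect_lte(ac_node, ab + bc + 2 * legb + 1e-9)
    expect_lte(ac_min, ac_node + 1e-12)
  }
})

test_that("enabling rail never increases a time cost", {
  fx <- fixture_minimal()
  no_rail <- cost_matrix(fx$cells, fx$facilities, fx$network,
                         metric = "time")
  rail <- cost_matrix(fx$cells, fx$facilities, fx$network_rail,
                      metric = "time")
  expect_true(all(rail$cost <= no_rail$cost + 1e-9))
  r <- generate_region(small_config(seed = 9))
  nr <- cost_matrix(r$cells, r$facilities, r$network, metric = "time")
  wr <- cost_matrix(r$cells, r$facilities, r$network_rail, metric = "time")
  expect_true(all(wr$cost <= nr$cost + 1e-9))
})

test_that("the literal conditional rule matches its stated definition", {
  fx <- fixture_minimal()
  p <- access_params()
  cc <- cost_matrix(fx$cells, fx$facilities, fx$network, p, "time",
                    "conditional")
  for (i in seq_len(nrow(fx$cells)))
    for (k in seq_len(nrow(fx$facilities))) {
      expected <- oracle_od_cost(
        c(fx$cells$x[i], fx$cells$y[i]),
        c(fx$facilities$x[k], fx$facilities$y[k]),
        fx$network, p, "time", rule = "conditional")
      expect_equal(cc$cost[i, k], expected, tolerance = 1e-10)
    }
})

test_that("cost matrices round-trip through CSV with metadata", {
  fx <- fixture_minimal()
  cm <- cost_matrix(fx$cells, fx$facilities, fx$network, metric = "time")
  path <- file.path(withr::local_tempdir(), "costs.csv")
  write_cost_matrix(cm, path)
  back <- read_cost_matrix(path)
  expect_equal(back$cost, cm$cost)
  expect_equal(back$metric, cm$metric)
  expect_equal(unclass(back$params), unclass(cm$params))
})
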