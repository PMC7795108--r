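test_that("nearest-cost surface is the row minimum over the subset", {
  m <- rbind(c(30, 12, 45), c(5, 80, 9))
  cm <- fake_costs(m)
  s <- nearest_cost(cm)
  expect_equal(unname(s$values), c(12, 5))
  # single facility: identity
  expect_equal(unname(nearest_cost(fake_costs(m[, 2, drop = FALSE]))$values),
               c(12, 80))
  # adding a cheaper facility lowers the minimum (oracle: recompute min)
  m2 <- cbind(m, c(5, 100))
  expect_equal(unname(nearest_cost(fake_costs(m2))$values),
               apply(m2, 1, min))
  expect_error(nearest_cost(cm, character(0)), "non-empty")
  expect_equal(nearest_cost(fake_costs(m, "space"))$label, "Pri_S")
})

test_that("supply-demand ratio matches hand evaluation", {
  # two cells of 100 people at decay weights 1 and 0.5 (d = 1, 2 with
  # beta 1, eps 1): R = 10 / (100*1 + 100*0.5) = 10/150
  cm <- fake_costs(matrix(c(1, 2), ncol = 1))
  cells <- data.frame(id = c("1", "2"), population = c(100, 100))
  fac <- data.frame(id = "f1", staff = 10, capacity_weight = 1)
  p <- fca_params("time", d0 = 10, beta = 1, eps = 1)
  expect_equal(supply_demand_ratio(fac, cm, cells, p), 10 / 150)
  # beta = 0: pure supply over in-range demand
  p0 <- fca_params("time", d0 = 10, beta = 0, eps = 1)
  expect_equal(supply_demand_ratio(fac, cm, cells, p0), 10 / 200)
  # empty catchment: ratio 0 with a message
  pshort <- fca_params("time", d0 = 0.5, beta = 1, eps = 1)
  expect_message(r0 <- supply_demand_ratio(fac, cm, cells, pshort),
                 "no demand")
  expect_equal(r0, 0)
})

test_that("2SFCA surface matches Eqs hand evaluation and conserves supply", {
  cm <- fake_costs(matrix(c(1, 2), ncol = 1))
  cells <- data.frame(id = c("1", "2"), population = c(100, 100))
  fac <- data.frame(id = "f1", staff = 10, capacity_weight = 1)
  p <- fca_params("time", d0 = 10, beta = 1, eps = 1)
  s <- two_step_fca(cm, cells, fac, p)
  expect_equal(unname(s$values), c(10 / 150 * 1, 10 / 150 * 0.5))
  # conservation: total delivered accessibility equals total supply
  expect_equal(sum(cells$population * s$values), 10)
  # strict threshold: a cell exactly at d0 is excluded
  cm2 <- fake_costs(matrix(c(1, 10), ncol = 1))
  s2 <- two_step_fca(cm2, cells, fac, p)
  expect_equal(unname(s2$values)[2], 0)
})

test_that("2SFCA agrees with the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    nI <- sample(3:12, 1); nJ <- sample(1:5, 1)
    cost <- matrix(runif(nI * nJ, 0.2, 30), nI, nJ)
    D <- sample(0:500, nI, replace = TRUE)
    S <- runif(nJ, 5, 200); P <- sample(c(1, 2), nJ, replace = TRUE)
    d0 <- runif(1, 5, 40); beta <- runif(1, 0, 2); eps <- 1
    cells <- data.frame(id = as.character(seq_len(nI)), population = D)
    fac <- data.frame(id = paste0("f", seq_len(nJ)), staff = S,
                      capacity_weight = P)
    p <- fca_params("time", d0 = d0, beta = beta, eps = eps)
    s <- suppressMessages(two_step_fca(fake_costs(cost), cells, fac, p))
    o <- oracle_2sfca(cost, D, S, P, d0, beta, eps)
    expect_equal(unname(s$values), o$A, tolerance = 1e-12)
  }
})

test_that("all three engines are linear in supply", {
  fx <- fixture_minimal()
  cm <- cost_matrix(fx$cells, fx$facilities, fx$network, metric = "time")
  cmr <- cost_matrix(fx$cells, fx$facilities, fx$network_rail,
                     metric = "time")
  fac <- fx$facilities
  fac2 <- fac; fac2$staff <- fac2$staff * 3
  p <- fca_params("time")
  sec <- fac[fac$level != "primary", ]
  sec2 <- fac2[fac2$level != "primary", ]
  expect_equal(two_step_fca(cm, fx$cells, sec2, p)$values,
               3 * two_step_fca(cm, fx$cells, sec, p)$values)
  ter <- fac[fac$level == "tertiary", ]
  ter2 <- fac2[fac2$level == "tertiary", ]
  expect_equal(
    suppressMessages(tertiary_access(cmr, fx$cells, ter2, 2, p))$values,
    3 * suppressMessages(tertiary_access(cmr, fx$cells, ter, 2, p))$values)
})

test_that("tertiary model matches term-by-term hand evaluation", {
  fx <- fixture_minimal()
  cmr <- cost_matrix(fx$cells, fx$facilities, fx$network_rail,
                     metric = "time")
  ter <- fx$facilities[fx$facilities$level == "tertiary", ]
  p <- fca_params("time", beta_own = 1.5, beta_capital = 1, eps = 1)
  s <- suppressMessages(
    tertiary_access(cmr, fx$cells, ter, fx$capital_city, p))
  # hand evaluation: single hospital f4 in capital city 2.
  d <- cmr$cost[, "f4"]
  D <- fx$cells$population
  own_cells <- fx$cells$city_id == 2
  w_own <- pmax(d, 1)^(-1.5)
  R_own <- ter$staff * 1 / sum(D[own_cells] * w_own[own_cells])
  A_own <- ifelse(own_cells, R_own * w_own, 0)
  w_cap <- pmax(d, 1)^(-1)
  R_cap <- ter$staff * 2 / sum(D * w_cap)
  A_cap <- R_cap * w_cap
  expect_equal(unname(s$values), unname(A_own + A_cap), tolerance = 1e-12)
  # city 1 has no tertiary hospital: its cells carry the capital term only
  expect_equal(unname(s$values[!own_cells]), unname(A_cap[!own_cells]))
  # capital hospitals contribute twice for capital residents, and the
  # switch suppresses the own-city share
  s_sup <- suppressMessages(
    tertiary_access(cmr, fx$cells, ter, fx$capital_city, p,
                    suppress_capital_own = TRUE))
  expect_equal(unname(s_sup$values), unname(A_cap), tolerance = 1e-12)
  expect_true(all(s$values[own_cells] > s_sup$values[own_cells]))
})

test_that("tertiary accessibility decays monotonically from a single
          capital hospital under uniform demand", {
  cells <- data.frame(id = as.character(1:5),
                      population = rep(100, 5), city_id = rep(1L, 5))
  cost <- matrix(c(1, 3, 7, 12, 40), ncol = 1,
                 dimnames = list(cells$id, "h1"))
  fac <- data.frame(id = "h1", staff = 100, city_id = 1L)
  s <- tertiary_access(fake_costs(cost), cells, fac, 1L,
                       fca_params("time"))
  expect_equal(order(s$values, decreasing = TRUE), 1:5)
})

test_that("adding facilities never worsens nearest cost; enlarging d0
          never lowers mean 2SFCA accessibility", {
  r <- generate_region(small_config(seed = 6))
  cm <- cost_matrix(r$cells, r$facilities, r$network, metric = "time")
  pri_all <- nearest_cost(cm)
  sub <- r$facilities$id[r$facilities$level == "primary"]
  pri_sub <- nearest_cost(cm, sub)
  expect_true(all(pri_all$values <= pri_sub$values + 1e-12))
  sec <- r$facilities[r$facilities$level != "primary", ]
  D <- r$cells$population
  means <- vapply(c(60, 90, 120, 150), function(d0) {
    s <- suppressMessages(two_step_fca(cm, r$cells, sec,
                                       fca_params("time", d0 = d0)))
    sum(D * s$values) / sum(D)
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-12))
})

test_that("zero-population cells still receive accessibility values", {
  cm <- fake_costs(matrix(c(1, 2, 3), ncol = 1))
  cells <- data.frame(id = as.character(1:3), population = c(100, 0, 50))
  fac <- data.frame(id = "f1", staff = 10, capacity_weight = 1)
  s <- two_step_fca(cm, cells, fac, fca_params("time", d0 = 10, eps = 1))
  expect_true(s$values[2] > 0)  # receives access, contributes no demand
  expect_equal(sum(cells$population * s$values), 10)
})
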