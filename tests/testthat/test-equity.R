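make_surface <- function(values, label = "Sec_T") {
  structure(list(label = label,
                 values = setNames(values,
                                   as.character(seq_along(values))),
                 units = "x", params = NULL),
            class = "accessibility_surface")
}

test_that("reciprocal min-max normalization of cost surfaces", {
  s <- make_surface(c(10, 20, 40), "Pri_T")
  n <- invert_normalize(s)
  # 1/x = {0.1, 0.05, 0.025} -> normalized {1, 1/3, 0}
  expect_equal(unname(n$values), c(1, 1 / 3, 0))
  # endpoints: min cost -> 1, max cost -> 0; ranking exactly inverted
  set.seed(1)
  x <- runif(50, 1, 100)
  nn <- invert_normalize(make_surface(x, "Pri_S"))
  expect_equal(unname(nn$values[which.min(x)]), 1)
  expect_equal(unname(nn$values[which.max(x)]), 0)
  expect_equal(order(nn$values), rev(order(x)))
  # index surfaces pass through untouched
  idx <- make_surface(c(1, 2, 3), "Ter_T")
  expect_identical(invert_normalize(idx), idx)
  expect_message(z <- invert_normalize(make_surface(c(5, 5, 5), "Pri_T")),
                 "constant")
  expect_equal(unname(z$values), c(0, 0, 0))
})

test_that("Lorenz curve and Gini match their defining properties", {
  # equal values: perfect equality
  expect_equal(lorenz_gini(rep(3, 10), rep(7, 10))$gini, 0)
  # two equal-population units with values (0, v): G = 0.5
  expect_equal(lorenz_gini(c(0, 5), c(100, 100))$gini, 0.5)
  lr <- lorenz_gini(c(0, 5), c(100, 100))
  expect_equal(lr$points$pop_share, c(0, 0.5, 1))
  expect_equal(lr$points$access_share, c(0, 0, 1))
  expect_error(lorenz_gini(c(0, 0), c(1, 1)), "zero")
})

test_that("trapezoid Gini equals the mean-absolute-difference formula", {
  set.seed(9)
  for (rep in 1:30) {
    n <- sample(2:50, 1)
    v <- runif(n, 0, 10)
    p <- sample(0:100, n, replace = TRUE)
    if (sum(p) == 0 || sum(p * v) == 0) next
    g1 <- lorenz_gini(v, p)$gini
    expect_equal(g1, oracle_gini_mad(v, p), tolerance = 1e-10)
  }
})

test_that("Gini is scale- and replication-invariant, curve below the
          diagonal", {
  set.seed(13)
  v <- runif(20, 0.1, 5); p <- sample(1:50, 20, replace = TRUE)
  g <- lorenz_gini(v, p)
  expect_equal(lorenz_gini(v * 7, p)$gini, g$gini, tolerance = 1e-12)
  # splitting every unit into two identical halves changes nothing
  expect_equal(lorenz_gini(rep(v, 2), rep(p / 2, 2))$gini, g$gini,
               tolerance = 1e-12)
  expect_true(all(g$points$access_share <= g$points$pop_share + 1e-12))
  expect_true(all(diff(g$points$access_share) >= -1e-12))
})

test_that("county aggregation is the population-weighted mean", {
  cells <- data.frame(id = 1:3, population = c(100, 300, 50),
                      county_id = c(1, 1, 2))
  s <- make_surface(c(4, 8, 6))
  agg <- aggregate_to_county(s, cells)
  expect_equal(unname(agg["1"]), (100 * 4 + 300 * 8) / 400)  # 7.0
  expect_equal(unname(agg["2"]), 6)  # single-cell county: identity
  # uniform surface: every county equals the constant
  expect_equal(unname(aggregate_to_county(make_surface(rep(2, 3)), cells)),
               c(2, 2))
  # zero-population county excluded with warning
  cells0 <- data.frame(id = 1:3, population = c(100, 300, 0),
                       county_id = c(1, 1, 2))
  expect_warning(a0 <- aggregate_to_county(s, cells0), "zero-population")
  expect_equal(names(a0), "1")
})

test_that("group correlation matches the closed form and flags
          significance", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(group_correlation(setNames(x, letters[1:5]),
                                 setNames(2 * x + 1, letters[1:5]))$r, 1)
  # closed-form check on a small printed-style table
  a <- c(23.9, 18.88, 27.14, 24.13, 30.2)
  b <- c(0.32, 0.28, 0.41, 0.37, 0.45)
  gc <- group_correlation(setNames(a, 1:5), setNames(b, 1:5))
  r_closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(gc$r, r_closed, tolerance = 1e-12)
  expect_true(gc$stars %in% c("", "*", "**"))
  expect_error(group_correlation(setNames(rep(1, 5), 1:5),
                                 setNames(x, 1:5)), "constant")
  expect_error(group_correlation(setNames(x[1:2], 1:2),
                                 setNames(x[1:2], 1:2)), "3 counties")
})

test_that("independent group ratios are rarely called significant", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed + 500)
    cv <- setNames(runif(30), 1:30)
    gr <- setNames(runif(30), 1:30)
    if (group_correlation(cv, gr)$p < 0.05) hits <- hits + 1
  }
  expect_gte(20 - hits, 18)
})

test_that("composition ratios behave at the proportional and segregated
          extremes", {
  cells <- data.frame(id = as.character(1:10),
                      population = rep(100, 10))
  s <- make_surface(1:10)
  # group proportional to population: every bin equals the global share
  prop <- rep(30, 10)
  qc <- quantile_composition(s, cells, prop)
  expect_equal(qc$group_share, rep(0.3, nrow(qc)))
  expect_equal(qc$group_share + qc$complement_share, rep(1, nrow(qc)))
  # group entirely in the lowest-value cells
  seg <- c(100, 100, rep(0, 8))
  qs <- quantile_composition(s, cells, seg)
  expect_equal(qs$group_share[1], 1)
  expect_equal(qs$group_share[qs$bin == "top10%"], 0)
  # bins must partition [0, 100]
  expect_error(quantile_composition(s, cells, prop, bins = c(10, 50, 100)),
               "partition")
})

test_that("cell-count and population-weighted binning both cover all
          population", {
  set.seed(31)
  cells <- data.frame(id = as.character(1:40),
                      population = sample(50:500, 40))
  grp <- rbinom(40, cells$population, 0.4)
  s <- make_surface(runif(40))
  for (cc in c(TRUE, FALSE)) {
    q <- quantile_composition(s, cells, grp, cell_count = cc)
    ok <- !is.na(q$group_share)
    expect_true(all(q$group_share[ok] >= 0 & q$group_share[ok] <= 1))
    expect_equal(q$group_share[ok] + q$complement_share[ok],
                 rep(1, sum(ok)))
  }
})

test_that("equity report wires surfaces, subdivisions and groups
          together", {
  r <- generate_region(small_config(seed = 8))
  s <- accessibility_surfaces(r)
  labs <- c("Pri_T", "Pri_S", "Sec_T", "Sec_S", "Ter_T", "Ter_S")
  eq <- suppressMessages(equity_report(s[labs], r))
  expect_setequal(unique(eq$gini$surface), labs)
  expect_true(all(eq$gini$gini >= 0 & eq$gini$gini < 1))
  expect_equal(nrow(eq$correlations), 12)
  expect_true(all(abs(eq$correlations$r) <= 1))
  # Pri gini rows used the normalized surface: recompute one directly
  g <- lorenz_gini(invert_normalize(s$Pri_T)$values[
    as.character(r$cells$id)], r$cells$population)$gini
  expect_equal(eq$gini$gini[eq$gini$region == "region" &
                              eq$gini$surface == "Pri_T"], g)
})
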