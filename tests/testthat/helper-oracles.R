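# Independent brute-force oracles used across the suite. These re-derive
# every quantity from first principles (exhaustive enumeration, explicit
# double sums, closed forms) and never call the code paths they check.

# --- exhaustive shortest-path enumeration ---------------------------------

# All simple paths between two vertices of a small edge list, by DFS.
# edges: data.frame(from, to, w). Returns the minimum total weight (Inf if
# no path); from == to gives 0.
enum_shortest <- function(edges, from, to) {
  if (from == to) return(0)
  best <- Inf
  visit <- function(v, seen, acc) {
    if (acc >= best) return()
    if (v == to) { best <<- acc; return() }
    for (e in seq_len(nrow(edges))) {
      nxt <- if (edges$from[e] == v) edges$to[e] else
        if (edges$to[e] == v) edges$from[e] else next
      if (nxt %in% seen) next
      visit(nxt, c(seen, nxt), acc + edges$w[e])
    }
  }
  visit(from, from, 0)
  best
}

# Two-speed access-leg cost, restated independently (minutes or meters).
oracle_leg <- function(dist_m, params, metric) {
  if (metric == "space") return(dist_m)
  if (dist_m <= params$d_threshold) dist_m / (params$walk_speed * 1000 / 60)
  else dist_m / (params$feeder_speed * 1000 / 60)
}

# Exhaustive-enumeration od cost between two points under the improved
# min(network, direct) rule. Snap locations (edge index + parameter) are
# taken from access_leg (the projection is shared); the path through the
# network, the candidate combination and the leg costs are recomputed
# from scratch here.
oracle_od_cost <- function(origin, dest, network, params, metric,
                           rule = "min") {
  wcol <- if (metric == "space") "length_m" else "time_min"
  ed <- data.frame(from = network$edges$from, to = network$edges$to,
                   w = network$edges[[wcol]])
  so <- medaccess::access_leg(origin, network, params, metric)
  sd <- medaccess::access_leg(dest, network, params, metric)
  eo <- network$edges[so$edge, ]; edd <- network$edges[sd$edge, ]
  # candidates from the snap point toward either end of its host edge
  starts <- rbind(
    data.frame(v = eo$from, part = so$t * ed$w[so$edge]),
    data.frame(v = eo$to, part = (1 - so$t) * ed$w[so$edge]))
  ends <- rbind(
    data.frame(v = edd$from, part = sd$t * ed$w[sd$edge]),
    data.frame(v = edd$to, part = (1 - sd$t) * ed$w[sd$edge]))
  net_path <- Inf
  for (i in 1:2) for (j in 1:2) {
    sp <- enum_shortest(ed, starts$v[i], ends$v[j])
    net_path <- min(net_path, starts$part[i] + sp + ends$part[j])
  }
  if (so$edge == sd$edge)
    net_path <- min(net_path, abs(so$t - sd$t) * ed$w[so$edge])
  network_cand <- oracle_leg(so$dist, params, metric) + net_path +
    oracle_leg(sd$dist, params, metric)
  ddist <- sqrt(sum((origin - dest)^2))
  direct_cand <- oracle_leg(ddist, params, metric)
  switch(rule,
         min = min(network_cand, direct_cand),
         node = network_cand,
         conditional = if (direct_cand < oracle_leg(so$dist, params,
                                                    metric) +
                           oracle_leg(sd$dist, params, metric))
           direct_cand else network_cand)
}

# --- Moran's I by explicit double sum -------------------------------------

oracle_moran <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
    s0 <- s0 + W[i, j]
  }
  n * num / (s0 * sum((x - xb)^2))
}

# --- Gini by the population-weighted mean-absolute-difference formula -----

oracle_gini_mad <- function(values, populations) {
  keep <- populations > 0
  v <- values[keep]; p <- populations[keep]
  P <- sum(p)
  mu <- sum(p * v) / P
  s <- 0
  for (i in seq_along(v)) for (j in seq_along(v))
    s <- s + p[i] * p[j] * abs(v[i] - v[j])
  s / (2 * P^2 * mu)
}

# --- hand evaluation of the 2SFCA equations -------------------------------

# R_j and A_i for arbitrary small instances; strict d < d0, decay
# max(d, eps)^-beta.
oracle_2sfca <- function(cost, D, S, P, d0, beta, eps) {
  nJ <- ncol(cost)
  R <- numeric(nJ)
  for (j in seq_len(nJ)) {
    den <- 0
    for (k in seq_len(nrow(cost)))
      if (cost[k, j] < d0)
        den <- den + D[k] * max(cost[k, j], eps)^(-beta)
    R[j] <- if (den > 0) S[j] * P[j] / den else 0
  }
  A <- numeric(nrow(cost))
  for (i in seq_len(nrow(cost)))
    for (j in seq_len(nJ))
      if (cost[i, j] < d0)
        A[i] <- A[i] + R[j] * max(cost[i, j], eps)^(-beta)
  list(R = R, A = A)
}

# --- small builders -------------------------------------------------------

# wrap a plain matrix as a travel_cost_matrix (for toy analytic cases)
fake_costs <- function(m, metric = "time") {
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  structure(list(cost = m, metric = metric, rail_used = FALSE,
                 params = medaccess::access_params(), rule = "min",
                 n_disconnected = 0), class = "travel_cost_matrix")
}

# a small fast region config for property tests
small_config <- function(seed = 1, ...) {
  args <- list(extent_km = 40, cell_km = 5, n_cities = 2,
               facility_counts = c(primary = 10, secondary = 3,
                                   tertiary = 2),
               population_total = 50000, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(medaccess::region_config, args)
}
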