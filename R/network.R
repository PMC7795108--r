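#' Default design speeds by road class
#'
#' Average travel speeds (km/h) assigned to each transport class when a
#' segment does not carry an explicit speed: national roads 80, provincial
#' 70, county 50, township 25, special-purpose 20, village 15, high-speed
#' rail 200, ordinary rail 120.
#'
#' @format Named numeric vector, km/h.
#' @export
road_speeds <- c(
  national = 80, provincial = 70, county = 50, township = 25,
  special = 20, village = 15, rail_highspeed = 200, rail_ordinary = 120
)

.rail_classes <- c("rail_highspeed", "rail_ordinary")

#' Create a typed road or rail segment
#'
#' @param coords Two-column numeric matrix of planar coordinates (meters);
#'   one row per vertex of the polyline (at least two rows).
#' @param road_class One of `names(road_speeds)`.
#' @param speed_kmh Optional speed override, km/h; defaults to the class
#'   speed from [road_speeds].
#' @return An object of class `road_segment`.
#' @export
road_segment <- function(coords, road_class, speed_kmh = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2 || nrow(coords) < 2)
    stop("coords must be a >=2-row, 2-column matrix of planar meters")
  road_class <- match.arg(road_class, names(road_speeds))
  if (is.null(speed_kmh)) speed_kmh <- unname(road_speeds[road_class])
  if (speed_kmh <= 0) stop("speed_kmh must be positive")
  len <- sum(sqrt(rowSums((coords[-1, , drop = FALSE] -
                             coords[-nrow(coords), , drop = FALSE])^2)))
  if (len <= 0) stop("zero-length road segment rejected")
  structure(list(coords = coords, road_class = road_class,
                 speed_kmh = speed_kmh,
                 is_rail = road_class %in% .rail_classes),
            class = "road_segment")
}

#' Build a transport network graph from typed segments
#'
#' Segments are exploded into straight pieces, noded at every pairwise
#' crossing (so crossing roads share a junction vertex), and assembled into
#' an undirected graph. Every edge carries its length in meters and its
#' traversal time in minutes, `time_min = length_m / (speed_kmh * 1000/60)`.
#'
#' @param segments List of [road_segment] objects.
#' @param include_rail Logical; if `FALSE`, rail segments are dropped before
#'   the graph is built (the road-only network).
#' @return An object of class `transport_network` with elements `nodes`
#'   (matrix of vertex coordinates), `edges` (data frame with `from`, `to`,
#'   `length_m`, `time_min`, `road_class`, `is_rail`) and `include_rail`.
#' @export
build_network <- function(segments, include_rail = TRUE) {
  if (inherits(segments, "road_segment")) segments <- list(segments)
  if (length(segments) == 0) stop("segments must be non-empty")
  if (!all(vapply(segments, inherits, logical(1), "road_segment")))
    stop("all segments must be road_segment objects")
  if (!include_rail)
    segments <- Filter(function(s) !s$is_rail, segments)
  if (length(segments) == 0)
    stop("no non-rail segments to build a network from")

  # explode polylines into straight pieces
  pieces <- list()
  for (s in segments) {
    cc <- s$coords
    for (i in seq_len(nrow(cc) - 1)) {
      a <- cc[i, ]; b <- cc[i + 1, ]
      if (.dist2(a, b) <= 0) stop("zero-length piece in road segment")
      pieces[[length(pieces) + 1]] <-
        list(a = a, b = b, road_class = s$road_class,
             speed_kmh = s$speed_kmh, is_rail = s$is_rail)
    }
  }

  # node: collect interior crossing points per piece as parameters t
  np <- length(pieces)
  splits <- vector("list", np)
  if (np > 1) {
    for (i in seq_len(np - 1)) {
      pi <- pieces[[i]]
      for (j in seq(i + 1, np)) {
        pj <- pieces[[j]]
        x <- .segment_intersection(pi$a, pi$b, pj$a, pj$b)
        if (is.null(x)) next
        li <- .dist2(pi$a, pi$b); lj <- .dist2(pj$a, pj$b)
        ti <- .dist2(pi$a, x) / li
        tj <- .dist2(pj$a, x) / lj
        if (ti > 1e-9 && ti < 1 - 1e-9) splits[[i]] <- c(splits[[i]], ti)
        if (tj > 1e-9 && tj < 1 - 1e-9) splits[[j]] <- c(splits[[j]], tj)
      }
    }
  }

  # split pieces at crossings and collect final straight edges
  coords <- list(); keys <- character(0)
  vid <- function(xy) {
    k <- paste(round(xy[1], 3), round(xy[2], 3), sep = "_")
    i <- match(k, keys)
    if (is.na(i)) {
      coords[[length(coords) + 1]] <<- xy
      keys[length(keys) + 1] <<- k
      i <- length(keys)
    }
    i
  }
  ef <- et <- integer(0); el <- numeric(0)
  ecl <- character(0); erail <- logical(0); espd <- numeric(0)
  for (i in seq_len(np)) {
    p <- pieces[[i]]
    ts <- sort(unique(c(0, splits[[i]], 1)))
    pts <- lapply(ts, function(t) p$a + t * (p$b - p$a))
    for (k in seq_len(length(pts) - 1)) {
      v1 <- vid(pts[[k]]); v2 <- vid(pts[[k + 1]])
      if (v1 == v2) next
      ef <- c(ef, v1); et <- c(et, v2)
      el <- c(el, .dist2(pts[[k]], pts[[k + 1]]))
      ecl <- c(ecl, p$road_class); erail <- c(erail, p$is_rail)
      espd <- c(espd, p$speed_kmh)
    }
  }
  nodes <- do.call(rbind, coords)
  colnames(nodes) <- c("x", "y")
  edges <- data.frame(from = ef, to = et, length_m = el,
                      time_min = el / (espd * 1000 / 60),
                      road_class = ecl, speed_kmh = espd,
                      is_rail = erail, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, include_rail = include_rail,
                 segments = segments),
            class = "transport_network")
}

#' @export
print.transport_network <- function(x, ...) {
  cat("<transport_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges", sep = "")
  if (any(x$edges$is_rail)) cat(" (incl. rail)")
  cat("\n  classes:", paste(sort(unique(x$edges$road_class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Access-leg parameters for off-network points
#'
#' Off-network demand points reach the road network by walking when the snap
#' distance is within `d_threshold` (the distance walkable in 15 min at
#' `walk_speed`), and by a low-class feeder road speed beyond it.
#'
#' @param d_threshold Walk/feeder switch distance in meters (default 1250).
#' @param walk_speed Walking speed, km/h (default 5).
#' @param feeder_speed Speed assumed beyond the walking range, km/h
#'   (default 25).
#' @return An object of class `access_params`.
#' @export
access_params <- function(d_threshold = 1250, walk_speed = 5,
                          feeder_speed = 25) {
  stopifnot(d_threshold > 0, walk_speed > 0, feeder_speed > 0)
  structure(list(d_threshold = d_threshold, walk_speed = walk_speed,
                 feeder_speed = feeder_speed), class = "access_params")
}

# cost of covering dist_m off-network under the two-speed rule (minutes) or
# as raw meters for the space metric
.leg_cost <- function(dist_m, params, metric) {
  if (metric == "space") return(dist_m)
  speed <- ifelse(dist_m <= params$d_threshold,
                  params$walk_speed, params$feeder_speed)
  dist_m / (speed * 1000 / 60)
}

# snap points (n x 2 matrix) to the nearest non-rail edge of the network;
# returns data.frame(edge, t, x, y, dist)
.snap_points <- function(pts, network) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  road <- which(!network$edges$is_rail)
  if (length(road) == 0) stop("network has no road edges to snap to")
  A <- network$nodes[network$edges$from[road], , drop = FALSE]
  B <- network$nodes[network$edges$to[road], , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  out <- data.frame(edge = integer(nrow(pts)), t = numeric(nrow(pts)),
                    x = numeric(nrow(pts)), y = numeric(nrow(pts)),
                    dist = numeric(nrow(pts)))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    t <- (sweep(A, 2, p, function(a, b) b - a)[, 1] * AB[, 1] +
          sweep(A, 2, p, function(a, b) b - a)[, 2] * AB[, 2]) / len2
    t[len2 == 0] <- 0
    t <- pmin(pmax(t, 0), 1)
    qx <- A[, 1] + t * AB[, 1]
    qy <- A[, 2] + t * AB[, 2]
    d2 <- (qx - p[1])^2 + (qy - p[2])^2
    k <- which.min(d2)
    out$edge[i] <- road[k]; out$t[i] <- t[k]
    out$x[i] <- qx[k]; out$y[i] <- qy[k]
    out$dist[i] <- sqrt(d2[k])
  }
  out
}

#' Snap a point to the network and cost its access leg
#'
#' Finds the nearest location on any non-rail edge and returns the snap
#' location together with the access-leg cost: under the time metric the
#' straight snap distance is covered at `walk_speed` when within
#' `d_threshold` and at `feeder_speed` otherwise; under the space metric the
#' leg cost is the raw snap distance in meters.
#'
#' @param point Length-2 numeric, planar meters.
#' @param network A `transport_network`.
#' @param params An [access_params] object.
#' @param metric `"time"` (minutes) or `"space"` (meters).
#' @return List with `snap` (coordinates on the network), `edge`, `t`,
#'   `dist` (meters) and `cost` (minutes or meters).
#' @export
access_leg <- function(point, network, params = access_params(),
                       metric = c("time", "space")) {
  metric <- match.arg(metric)
  s <- .snap_points(matrix(point, ncol = 2), network)
  list(snap = c(s$x[1], s$y[1]), edge = s$edge[1], t = s$t[1],
       dist = s$dist[1], cost = .leg_cost(s$dist[1], params, metric))
}

# Build an igraph over the network augmented with virtual vertices at the
# given snap locations, so shortest paths may start/end mid-edge. Returns
# list(graph, vnames = vertex name per snap row).
.augmented_graph <- function(network, snaps, metric) {
  wcol <- if (metric == "space") "length_m" else "time_min"
  ed <- network$edges
  n0 <- nrow(network$nodes)
  vn <- character(nrow(snaps))
  # virtual vertices keyed by (edge, t); reuse endpoints when t ~ 0/1
  virt_name <- character(0); virt_edge <- integer(0); virt_t <- numeric(0)
  for (i in seq_len(nrow(snaps))) {
    e <- snaps$edge[i]; t <- snaps$t[i]
    if (t < 1e-9) { vn[i] <- as.character(ed$from[e]); next }
    if (t > 1 - 1e-9) { vn[i] <- as.character(ed$to[e]); next }
    hit <- which(virt_edge == e & virt_t == t)
    if (length(hit) == 0) {
      virt_name <- c(virt_name, paste0("v", e, "_", format(t, digits = 17)))
      virt_edge <- c(virt_edge, e); virt_t <- c(virt_t, t)
      hit <- length(virt_name)
    }
    vn[i] <- virt_name[hit[1]]
  }
  # assemble edge list, splitting edges that host virtual vertices
  ef <- character(0); et <- character(0); ew <- numeric(0)
  for (e in seq_len(nrow(ed))) {
    w <- ed[[wcol]][e]
    hk <- which(virt_edge == e)
    if (length(hk) == 0) {
      ef <- c(ef, as.character(ed$from[e]))
      et <- c(et, as.character(ed$to[e]))
      ew <- c(ew, w)
    } else {
      ts <- virt_t[hk]
      o <- order(ts)
      vs <- c(as.character(ed$from[e]), virt_name[hk][o],
              as.character(ed$to[e]))
      tt <- c(0, ts[o], 1)
      for (k in seq_len(length(vs) - 1)) {
        ef <- c(ef, vs[k]); et <- c(et, vs[k + 1])
        ew <- c(ew, w * (tt[k + 1] - tt[k]))
      }
    }
  }
  verts <- unique(c(as.character(seq_len(n0)), ef, et))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = verts))
  list(graph = g, vnames = vn)
}

#' Origin-destination travel cost under the improved node-cost rule
#'
#' The network candidate is the access leg from the origin to its snap
#' point, plus the shortest-path cost along the network, plus the access leg
#' at the destination. The direct candidate is the straight-line
#' origin-destination distance costed by the same two-speed walk/feeder rule
#' (time metric) or taken as raw meters (space metric). Under
#' `rule = "min"` (default) the smaller of the two is returned, which
#' removes the spurious detours that arise where low-class roads were
#' dropped from the digitized network; `rule = "conditional"` reproduces the
#' literal switch (direct distance used only when it costs less than the sum
#' of the two access legs); `rule = "node"` is the plain node-cost result
#' with no direct candidate. Disconnected pairs fall back to the direct
#' candidate.
#'
#' @param origin,dest Length-2 numeric points, planar meters.
#' @inheritParams access_leg
#' @param rule Candidate-combination rule, see Details.
#' @return A single non-negative cost (minutes or meters).
#' @export
od_cost <- function(origin, dest, network, params = access_params(),
                    metric = c("time", "space"),
                    rule = c("min", "conditional", "node")) {
  metric <- match.arg(metric); rule <- match.arg(rule)
  m <- cost_matrix(data.frame(id = "o", x = origin[1], y = origin[2]),
                   data.frame(id = "d", x = dest[1], y = dest[2]),
                   network, params, metric, rule)
  unname(m$cost[1, 1])
}

#' Cell-to-facility travel cost matrix
#'
#' Computes [od_cost] for every (demand cell, facility) pair in one pass:
#' all points are snapped to the road edges, the graph is augmented with the
#' snap vertices, and a single multi-source shortest-path call supplies the
#' network candidates.
#'
#' @param cells Data frame with columns `id`, `x`, `y` (cell centroids).
#' @param facilities Data frame with columns `id`, `x`, `y`.
#' @inheritParams od_cost
#' @return An object of class `travel_cost_matrix`: list with `cost`
#'   (matrix, rows = cells, cols = facilities), `metric`, `rail_used`,
#'   `params`, `rule`, and `n_disconnected` (pairs that fell back to the
#'   direct candidate for lack of a network path).
#' @export
cost_matrix <- function(cells, facilities, network,
                        params = access_params(),
                        metric = c("time", "space"),
                        rule = c("min", "conditional", "node")) {
  metric <- match.arg(metric); rule <- match.arg(rule)
  stopifnot(nrow(cells) > 0, nrow(facilities) > 0)
  cp <- cbind(cells$x, cells$y)
  fp <- cbind(facilities$x, facilities$y)
  sc <- .snap_points(cp, network)
  sf <- .snap_points(fp, network)
  ag <- .augmented_graph(network, rbind(sc, sf), metric)
  nC <- nrow(cells)
  vc <- ag$vnames[seq_len(nC)]
  vf <- ag$vnames[nC + seq_len(nrow(facilities))]
  uc <- unique(vc); uf <- unique(vf)
  Du <- igraph::distances(ag$graph, v = uc, to = uf,
                          weights = igraph::E(ag$graph)$weight)
  D <- Du[match(vc, uc), match(vf, uf), drop = FALSE]
  legc <- .leg_cost(sc$dist, params, metric)
  legf <- .leg_cost(sf$dist, params, metric)
  netw <- D + outer(legc, legf, "+")
  ddist <- sqrt(outer(cp[, 1], fp[, 1], "-")^2 +
                outer(cp[, 2], fp[, 2], "-")^2)
  direct <- if (metric == "space") ddist else
    matrix(.leg_cost(as.vector(ddist), params, metric), nrow = nC)
  disconnected <- !is.finite(netw)
  cost <- switch(rule,
    min = pmin(netw, direct),
    conditional = {
      use_direct <- direct < outer(legc, legf, "+")
      ifelse(use_direct, direct, netw)
    },
    node = netw)
  cost[disconnected] <- direct[disconnected]
  dimnames(cost) <- list(as.character(cells$id),
                         as.character(facilities$id))
  if (any(disconnected))
    message(sum(disconnected),
            " disconnected origin-destination pairs used the direct candidate")
  structure(list(cost = cost, metric = metric,
                 rail_used = any(network$edges$is_rail),
                 params = params, rule = rule,
                 n_disconnected = sum(disconnected)),
            class = "travel_cost_matrix")
}

#' @export
print.travel_cost_matrix <- function(x, ...) {
  cat("<travel_cost_matrix> ", nrow(x$cost), " cells x ", ncol(x$cost),
      " facilities; metric=", x$metric,
      if (x$rail_used) " (rail)", "; rule=", x$rule, "\n", sep = "")
  cat("  cost range: ", format(min(x$cost), digits = 4), " - ",
      format(max(x$cost), digits = 4),
      if (x$metric == "time") " min" else " m", "\n", sep = "")
  invisible(x)
}

#' Write / read a travel cost matrix as CSV plus a JSON sidecar
#'
#' The matrix is written as CSV (rows = cell ids, columns = facility ids);
#' metric, rule, rail flag and access parameters go to `<path>.meta.json`.
#'
#' @param x A `travel_cost_matrix`.
#' @param path CSV file path.
#' @return `write_cost_matrix` returns `path` invisibly; `read_cost_matrix`
#'   returns the reconstructed `travel_cost_matrix`.
#' @export
write_cost_matrix <- function(x, path) {
  m <- format(x$cost, digits = 17, trim = TRUE, scientific = FALSE)
  df <- data.frame(cell_id = rownames(x$cost), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("cell_id", colnames(x$cost))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(metric = x$metric, rail_used = x$rail_used, rule = x$rule,
               params = unclass(x$params),
               n_disconnected = x$n_disconnected)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cost_matrix
#' @export
read_cost_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(cell_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(cost = m, metric = meta$metric, rail_used = meta$rail_used,
                 params = do.call(access_params, meta$params),
                 rule = meta$rule, n_disconnected = meta$n_disconnected),
            class = "travel_cost_matrix")
}
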