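#' Configuration for a synthetic study region
#'
#' Describes a square province-like study area: a regular demand grid with
#' per-cell total, aging and agricultural population, a small set of urban
#' cores (one of which is the provincial capital), a three-level facility
#' table, and a typed road/rail network. Defaults emulate, at desk scale,
#' a gridded provincial study area (5 km cells, population concentrated in
#' cores with a dispersed rural remainder, agricultural share higher in
#' rural cells, aging share higher in core cells, tertiary hospitals only
#' in cores).
#'
#' @param extent_km Side length of the square region, km.
#' @param cell_km Grid cell size, km; must divide `extent_km`.
#' @param n_cities Number of urban cores.
#' @param capital_index Which core (1-based) is the provincial capital.
#' @param facility_counts Named integer vector with entries `primary`,
#'   `secondary`, `tertiary`.
#' @param population_total Total population, persons.
#' @param rural_fraction Share of population outside the cores, in \[0,1\].
#' @param aging_core_ratio,aging_rural_ratio Expected aging (65+) share in
#'   core / rural cells.
#' @param agricultural_core_ratio,agricultural_rural_ratio Expected
#'   agricultural-population share in core / rural cells.
#' @param road_density Length-2 numeric `c(core, branch)`: `core` = extra
#'   provincial-class links between cores beyond the national-class spanning
#'   tree; `branch` = spacing (in grid lines) of the rural township/village
#'   road lattice (1 = every centroid line, 2 = every other, ...).
#' @param staff_meanlog Named numeric, log-scale location of the lognormal
#'   staff-count distribution per level.
#' @param staff_sdlog Lognormal scale parameter for staff counts.
#' @param seed RNG seed; regions are bit-reproducible given (config, seed).
#' @return An object of class `region_config`.
#' @export
region_config <- function(extent_km = 150, cell_km = 5, n_cities = 5,
                          capital_index = 1,
                          facility_counts = c(primary = 230,
                                              secondary = 30,
                                              tertiary = 9),
                          population_total = 4e6, rural_fraction = 0.4,
                          aging_core_ratio = 0.12, aging_rural_ratio = 0.09,
                          agricultural_core_ratio = 0.15,
                          agricultural_rural_ratio = 0.70,
                          road_density = c(core = 1, branch = 2),
                          staff_meanlog = c(primary = log(30),
                                            secondary = log(150),
                                            tertiary = log(800)),
                          staff_sdlog = 0.4,
                          seed = 1L) {
  cfg <- list(extent_km = extent_km, cell_km = cell_km, n_cities = n_cities,
              capital_index = capital_index,
              facility_counts = facility_counts,
              population_total = population_total,
              rural_fraction = rural_fraction,
              aging_core_ratio = aging_core_ratio,
              aging_rural_ratio = aging_rural_ratio,
              agricultural_core_ratio = agricultural_core_ratio,
              agricultural_rural_ratio = agricultural_rural_ratio,
              road_density = road_density,
              staff_meanlog = staff_meanlog, staff_sdlog = staff_sdlog,
              seed = as.integer(seed))
  validate_region_config(cfg)
  structure(cfg, class = "region_config")
}

#' @rdname region_config
#' @param config A config list to validate.
#' @export
validate_region_config <- function(config) {
  with(config, {
    if (extent_km <= 0 || cell_km <= 0)
      stop("extent_km and cell_km must be positive")
    if (abs(extent_km / cell_km - round(extent_km / cell_km)) > 1e-9)
      stop("cell_km must divide extent_km")
    n_side <- round(extent_km / cell_km)
    if (n_cities < 1) stop("n_cities must be >= 1")
    if (n_cities > n_side^2)
      stop("infeasible config: more urban cores than grid cells")
    if (capital_index < 1 || capital_index > n_cities)
      stop("capital_index must be in 1..n_cities")
    if (!all(c("primary", "secondary", "tertiary") %in%
             names(facility_counts)))
      stop("facility_counts needs primary, secondary, tertiary entries")
    if (any(facility_counts < 1)) stop("all facility counts must be >= 1")
    ratios <- c(rural_fraction, aging_core_ratio, aging_rural_ratio,
                agricultural_core_ratio, agricultural_rural_ratio)
    if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
    if (population_total < 1) stop("population_total must be >= 1")
    if (length(road_density) != 2 || any(road_density < 1))
      stop("road_density must be c(core, branch) with entries >= 1")
  })
  invisible(config)
}

# largest-remainder allocation of `total` units proportional to weights;
# exact conservation, deterministic ties by index
.allocate_integer <- function(total, weights) {
  if (total == 0) return(integer(length(weights)))
  w <- weights / sum(weights)
  raw <- w * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, seq_along(raw), decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic study region
#'
#' Builds a `study_region` from a [region_config]: urban cores sampled at
#' least two cells apart, population split between a decaying kernel around
#' each core and a uniform low-intensity rural field, binomially drawn
#' aging/agricultural strata with core- and rural-specific shares, a road
#' network made of a national-class spanning tree over the cores, optional
#' extra provincial links, a rural township/village lattice, county
#' connectors from each core, and one ordinary-rail line chaining the cores
#' through the capital. Facilities: tertiary hospitals only in core cells
#' (the first in the capital), secondary in core cells, primary everywhere
#' with density proportional to population. Deterministic given the config
#' (which includes the seed).
#'
#' @param config A [region_config].
#' @return An object of class `study_region`: list with `config`, `cells`
#'   (data frame: `id`, `row`, `col`, `x`, `y`, `population`, `aging`,
#'   `agricultural`, `county_id`, `city_id`, `is_core`), `facilities`
#'   (data frame: `id`, `x`, `y`, `level`, `staff`, `capacity_weight`,
#'   `city_id`), `segments` (typed road/rail polylines), `network`
#'   (road-only [build_network] graph), `network_rail` (with rail),
#'   `subdivisions` (named character, city id -> subdivision label),
#'   `capital_city` (city id of the capital).
#' @export
generate_region <- function(config) {
  validate_region_config(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  cell_m <- config$cell_km * 1000
  n_side <- round(config$extent_km / config$cell_km)
  n_cells <- n_side^2
  # row-major cell ids from the southwest corner
  cells <- expand.grid(col = seq_len(n_side), row = seq_len(n_side))
  cells <- cells[, c("row", "col")]
  cells$id <- seq_len(n_cells)
  cells$x <- (cells$col - 0.5) * cell_m
  cells$y <- (cells$row - 0.5) * cell_m

  # --- cores: sampled without replacement, pairwise Chebyshev distance >= 2
  core_cells <- integer(0)
  cand <- sample.int(n_cells)
  for (i in cand) {
    if (length(core_cells) == config$n_cities) break
    ok <- all(pmax(abs(cells$row[i] - cells$row[core_cells]),
                   abs(cells$col[i] - cells$col[core_cells])) >= 2)
    if (length(core_cells) == 0 || ok) core_cells <- c(core_cells, i)
  }
  if (length(core_cells) < config$n_cities)
    stop("infeasible config: cannot place ", config$n_cities,
         " cores at least 2 cells apart on a ", n_side, "x", n_side, " grid")
  capital_core <- core_cells[config$capital_index]

  # city membership: nearest core centroid (ties by lower city id)
  dcore <- outer(cells$x, cells$x[core_cells], "-")^2 +
    outer(cells$y, cells$y[core_cells], "-")^2
  cells$city_id <- max.col(-dcore, ties.method = "first")
  capital_city <- which(core_cells == capital_core)

  # core cell set: Chebyshev radius 1 around any core center
  cheb <- matrix(pmax(abs(outer(cells$row, cells$row[core_cells], "-")),
                      abs(outer(cells$col, cells$col[core_cells], "-"))),
                 nrow = n_cells)
  cells$is_core <- apply(cheb, 1, min) <= 1

  # --- population: kernel around cores for the urban share, uniform rural
  core_pop_total <- round((1 - config$rural_fraction) *
                            config$population_total)
  rural_pop_total <- config$population_total - core_pop_total
  pop <- integer(n_cells)
  ci <- which(cells$is_core)
  if (length(ci)) {
    dmin <- sqrt(apply(dcore[ci, , drop = FALSE], 1, min))
    kern <- exp(-dmin / cell_m)          # decaying kernel, e-fold one cell
    pop[ci] <- .allocate_integer(core_pop_total, kern)
  }
  ri <- which(!cells$is_core)
  if (length(ri)) {
    w <- stats::runif(length(ri), 0.5, 1.5)  # dispersed low-intensity field
    pop[ri] <- .allocate_integer(rural_pop_total, w)
  } else {
    pop[ci] <- pop[ci] + .allocate_integer(rural_pop_total,
                                           rep(1, length(ci)))
  }
  cells$population <- pop
  cells$aging <- stats::rbinom(n_cells, pop,
                               ifelse(cells$is_core,
                                      config$aging_core_ratio,
                                      config$aging_rural_ratio))
  cells$agricultural <- stats::rbinom(n_cells, pop,
                                      ifelse(cells$is_core,
                                             config$agricultural_core_ratio,
                                             config$agricultural_rural_ratio))

  # counties: quadrants of each city around its core center
  cx <- cells$x[core_cells][cells$city_id]
  cy <- cells$y[core_cells][cells$city_id]
  quad <- 1L + (cells$x > cx) + 2L * (cells$y > cy)
  cells$county_id <- cells$city_id * 10L + quad

  # subdivisions: south/central/north latitude bands of the core centers
  yb <- stats::quantile(cells$y[core_cells], c(1 / 3, 2 / 3), type = 1)
  sub_of_core <- ifelse(cells$y[core_cells] <= yb[1], "south",
                        ifelse(cells$y[core_cells] <= yb[2], "central",
                               "north"))
  subdivisions <- stats::setNames(sub_of_core,
                                  as.character(seq_len(config$n_cities)))

  # --- facilities
  jitter_in_cell <- function(cell_idx) {
    cbind(cells$x[cell_idx] + stats::runif(length(cell_idx), -0.3, 0.3) *
            cell_m,
          cells$y[cell_idx] + stats::runif(length(cell_idx), -0.3, 0.3) *
            cell_m)
  }
  fc <- config$facility_counts
  # tertiary: capital core first, then remaining cores round-robin
  tcells <- c(core_cells[config$capital_index],
              rep(core_cells[-config$capital_index],
                  length.out = max(0, fc[["tertiary"]] - 1)))
  tcells <- tcells[seq_len(fc[["tertiary"]])]
  # secondary: core cells, probability proportional to population
  core_set <- which(cells$is_core)
  scells <- sample(core_set, fc[["secondary"]], replace = TRUE,
                   prob = pmax(cells$population[core_set], 1))
  # primary: everywhere, density proportional to population
  pcells <- sample.int(n_cells, fc[["primary"]], replace = TRUE,
                       prob = pmax(cells$population, 1))
  fcell <- c(pcells, scells, tcells)
  flevel <- rep(c("primary", "secondary", "tertiary"),
                c(fc[["primary"]], fc[["secondary"]], fc[["tertiary"]]))
  fxy <- jitter_in_cell(fcell)
  staff <- round(stats::rlnorm(length(fcell),
                               config$staff_meanlog[flevel],
                               config$staff_sdlog))
  staff <- pmax(staff, 1)
  facilities <- data.frame(
    id = paste0("f", seq_along(fcell)),
    x = fxy[, 1], y = fxy[, 2], level = flevel, staff = staff,
    capacity_weight = ifelse(flevel == "tertiary", 2, 1),
    city_id = cells$city_id[fcell], stringsAsFactors = FALSE)

  # --- road network
  segments <- .generate_roads(cells, core_cells, capital_core, config,
                              cell_m, n_side)

  region <- structure(list(
    config = config, cells = cells, facilities = facilities,
    segments = segments,
    network = build_network(segments, include_rail = FALSE),
    network_rail = build_network(segments, include_rail = TRUE),
    subdivisions = subdivisions, capital_city = capital_city),
    class = "study_region")
  region
}

# road/rail segment list for a generated region
.generate_roads <- function(cells, core_cells, capital_core, config,
                            cell_m, n_side) {
  extent_m <- n_side * cell_m
  cx <- cells$x[core_cells]; cy <- cells$y[core_cells]
  segs <- list()
  add <- function(a, b, cls) {
    if (.dist2(a, b) > 0)
      segs[[length(segs) + 1]] <<- road_segment(rbind(a, b), cls)
  }
  nc <- length(core_cells)
  # national: minimum spanning tree over core centers
  if (nc > 1) {
    dm <- as.matrix(stats::dist(cbind(cx, cy)))
    g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    for (k in seq_len(nrow(el)))
      add(c(cx[el[k, 1]], cy[el[k, 1]]), c(cx[el[k, 2]], cy[el[k, 2]]),
          "national")
    # provincial: extra closest non-tree core links
    extra <- round(config$road_density[[1]])
    if (extra > 0 && nc > 2) {
      inmst <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      pairs <- which(upper.tri(dm), arr.ind = TRUE)
      key <- paste(pairs[, 1], pairs[, 2])
      free <- which(!(key %in% inmst))
      free <- free[order(dm[pairs[free, , drop = FALSE]])]
      for (k in utils::head(free, extra))
        add(c(cx[pairs[k, 1]], cy[pairs[k, 1]]),
            c(cx[pairs[k, 2]], cy[pairs[k, 2]]), "provincial")
    }
  }
  # rural lattice: township rows + village columns every `branch` lines
  step <- max(1L, round(config$road_density[[2]]))
  rows <- seq(1L, n_side, by = step)
  cols <- seq(1L, n_side, by = step)
  for (r in rows)
    add(c(0, (r - 0.5) * cell_m), c(extent_m, (r - 0.5) * cell_m),
        "township")
  for (cc in cols)
    add(c((cc - 0.5) * cell_m, 0), c((cc - 0.5) * cell_m, extent_m),
        "village")
  # county connectors: each core center to the nearest township row
  for (i in seq_len(nc)) {
    ry <- (rows - 0.5) * cell_m
    yn <- ry[which.min(abs(ry - cy[i]))]
    if (abs(yn - cy[i]) > 1e-9) add(c(cx[i], cy[i]), c(cx[i], yn), "county")
  }
  # ordinary rail: chain the cores west->east (passes through the capital)
  if (nc > 1) {
    o <- order(cx, cy)
    coords <- cbind(cx[o], cy[o] + 0.1 * cell_m)  # offset off the roads
    segs[[length(segs) + 1]] <- road_segment(coords, "rail_ordinary")
  }
  segs
}

#' @export
print.study_region <- function(x, ...) {
  fc <- table(x$facilities$level)
  cat("<study_region> ", nrow(x$cells), " cells (",
      sqrt(nrow(x$cells)), "x", sqrt(nrow(x$cells)), ", ",
      x$config$cell_km, " km), ", x$config$n_cities, " cities (capital: ",
      x$capital_city, ")\n", sep = "")
  cat("  population ", sum(x$cells$population), "; facilities: ",
      paste(names(fc), fc, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  network: ", nrow(x$network$edges), " road edges (+",
      sum(x$network_rail$edges$is_rail), " rail)\n", sep = "")
  invisible(x)
}

#' @export
summary.study_region <- function(object, ...) {
  cells <- object$cells
  by_city <- stats::aggregate(
    cells[, c("population", "aging", "agricultural")],
    by = list(city_id = cells$city_id), FUN = sum)
  by_city$subdivision <- object$subdivisions[as.character(by_city$city_id)]
  cat("Per-city population summary:\n")
  print(by_city, row.names = FALSE)
  invisible(by_city)
}
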