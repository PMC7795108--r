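#' Minimal hand-checkable study region
#'
#' A deterministic 3x3-cell region (2 km cells) with four facilities and a
#' seven-edge network whose every cell-facility travel cost can be traced
#' by hand: one east-west county road (50 km/h) at y = 3000 m, one
#' north-south township road (25 km/h) at x = 3000 m, and one ordinary rail
#' line at y = 5000 m. Two cities; city 2 (northeast) is the capital and
#' holds the single tertiary hospital. Used throughout the test suite as
#' the oracle fixture.
#'
#' @return A `study_region`.
#' @export
fixture_minimal <- function() {
  segments <- list(
    road_segment(rbind(c(0, 3000), c(6000, 3000)), "county"),
    road_segment(rbind(c(3000, 0), c(3000, 6000)), "township"),
    road_segment(rbind(c(0, 5000), c(6000, 5000)), "rail_ordinary"))

  grid <- expand.grid(col = 1:3, row = 1:3)[, c("row", "col")]
  cells <- data.frame(
    id = 1:9, row = grid$row, col = grid$col,
    x = (grid$col - 0.5) * 2000, y = (grid$row - 0.5) * 2000)
  # city 1 = west two columns, city 2 = east column; cores at the city
  # centers (cell 5 = (3000,3000), cell 9 = (5000,5000))
  cells$city_id <- ifelse(cells$col <= 2, 1L, 2L)
  cells$is_core <- cells$id %in% c(5L, 9L)
  cells$population <- ifelse(cells$is_core, 500L, 100L)
  cells$aging <- ifelse(cells$is_core, 60L, 8L)
  cells$agricultural <- ifelse(cells$is_core, 75L, 70L)
  cells$county_id <- cells$city_id * 10L + ifelse(cells$row == 1, 1L, 2L)
  cells <- cells[, c("id", "row", "col", "x", "y", "population", "aging",
                     "agricultural", "county_id", "city_id", "is_core")]

  facilities <- data.frame(
    id = c("f1", "f2", "f3", "f4"),
    x = c(3000, 1000, 3000, 5000),
    y = c(3000, 3000, 5000, 5000),
    level = c("primary", "primary", "secondary", "tertiary"),
    staff = c(20, 10, 100, 500),
    capacity_weight = c(1, 1, 1, 2),
    city_id = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)

  config <- structure(list(
    extent_km = 6, cell_km = 2, n_cities = 2, capital_index = 2,
    facility_counts = c(primary = 2, secondary = 1, tertiary = 1),
    population_total = sum(cells$population), rural_fraction = NA,
    aging_core_ratio = NA, aging_rural_ratio = NA,
    agricultural_core_ratio = NA, agricultural_rural_ratio = NA,
    road_density = c(core = 0, branch = 0),
    staff_meanlog = NULL, staff_sdlog = NA, seed = 0L),
    class = "region_config")

  structure(list(
    config = config, cells = cells, facilities = facilities,
    segments = segments,
    network = build_network(segments, include_rail = FALSE),
    network_rail = build_network(segments, include_rail = TRUE),
    subdivisions = c(`1` = "west", `2` = "east"),
    capital_city = 2L),
    class = "study_region")
}
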