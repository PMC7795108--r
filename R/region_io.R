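# GeoJSON/CSV/YAML serialization of study regions. Coordinates are planar
# meters; cell ids are row-major from the southwest corner.

.geojson_feature <- function(geometry_type, coords, properties) {
  list(type = "Feature",
       geometry = list(type = geometry_type, coordinates = coords),
       properties = properties)
}

.write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

# data frame with x, y columns -> list of Point features
.point_features <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
    .geojson_feature("Point", c(df$x[i], df$y[i]), props)
  })
}

.write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- format(out[[nm]], digits = 17, trim = TRUE,
                          scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Serialize a study region to a directory
#'
#' Writes the network as GeoJSON LineString features (properties
#' `road_class`, `speed_kmh`, `is_rail`), cells and facilities as GeoJSON
#' Point features with mirrored CSV tables, and the configuration plus
#' city/subdivision labels as YAML. [read_region] restores the region
#' (networks are rebuilt from the segment geometry).
#'
#' @param region A `study_region`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  segs <- lapply(region$segments, function(s)
    .geojson_feature("LineString",
                     lapply(seq_len(nrow(s$coords)),
                            function(i) s$coords[i, ]),
                     list(road_class = s$road_class,
                          speed_kmh = s$speed_kmh, is_rail = s$is_rail)))
  .write_geojson(segs, file.path(dir, "network.geojson"))
  .write_geojson(.point_features(region$cells),
                 file.path(dir, "cells.geojson"))
  .write_geojson(.point_features(region$facilities),
                 file.path(dir, "facilities.geojson"))
  .write_csv_full(region$cells, file.path(dir, "cells.csv"))
  .write_csv_full(region$facilities, file.path(dir, "facilities.csv"))
  meta <- list(config = lapply(unclass(region$config), function(v)
                 if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
               subdivisions = as.list(region$subdivisions),
               capital_city = region$capital_city)
  yaml::write_yaml(meta, file.path(dir, "region.yaml"))
  invisible(dir)
}

#' @rdname write_region
#' @export
read_region <- function(dir) {
  net <- jsonlite::read_json(file.path(dir, "network.geojson"))
  segments <- lapply(net$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    road_segment(coords, f$properties$road_class,
                 f$properties$speed_kmh)
  })
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  cells$is_core <- as.logical(cells$is_core)
  facilities <- utils::read.csv(file.path(dir, "facilities.csv"),
                                colClasses = c(id = "character"))
  meta <- yaml::read_yaml(file.path(dir, "region.yaml"))
  cfg <- meta$config
  for (nm in c("facility_counts", "road_density", "staff_meanlog"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  cfg <- structure(cfg, class = "region_config")
  structure(list(
    config = cfg, cells = cells, facilities = facilities,
    segments = segments,
    network = build_network(segments, include_rail = FALSE),
    network_rail = build_network(segments, include_rail = TRUE),
    subdivisions = stats::setNames(unlist(meta$subdivisions),
                                   names(meta$subdivisions)),
    capital_city = meta$capital_city),
    class = "study_region")
}

#' Write an accessibility surface as CSV and GeoJSON
#'
#' @param surface An `accessibility_surface`.
#' @param cells The region's cell table (for coordinates in the GeoJSON).
#' @param path CSV path; a `.geojson` sibling is written alongside when
#'   `cells` is supplied.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, cells = NULL) {
  df <- data.frame(cell_id = names(surface$values),
                   value = unname(surface$values))
  .write_csv_full(df, path)
  meta <- list(label = surface$label, units = surface$units,
               params = if (!is.null(surface$params))
                 unclass(surface$params))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cells)) {
    df2 <- data.frame(id = cells$id, x = cells$x, y = cells$y,
                      value = unname(surface$values))
    .write_geojson(.point_features(df2),
                   sub("\\.csv$", ".geojson", path))
  }
  invisible(path)
}
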