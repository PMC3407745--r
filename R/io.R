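#' Write a city scene to GeoJSON and CSV files
#'
#' Roads become a GeoJSON FeatureCollection of LineStrings with a
#' `vehicles_per_day` property; census blocks a FeatureCollection of
#' Polygons with `residents`, `area`, `altitude`, `green_adjacent`
#' properties; scene metadata (extent, centre) goes to a JSON sidecar.
#'
#' @param city a `city_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_city_scene <- function(city, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  road_features <- lapply(seq_len(nrow(city$roads)), function(i) {
    r <- city$roads[i, ]
    list(type = "Feature",
         properties = list(id = r$id, vehicles_per_day = r$vehicles_per_day),
         geometry = list(type = "LineString",
                         coordinates = list(c(r$x1, r$y1), c(r$x2, r$y2))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = road_features),
    file.path(dir, "roads.geojson"), auto_unbox = TRUE, digits = NA)

  block_features <- lapply(seq_len(nrow(city$blocks)), function(i) {
    b <- city$blocks[i, ]
    poly <- city$block_polygons[[i]]
    ring <- lapply(c(seq_along(poly$x), 1), function(j) c(poly$x[j], poly$y[j]))
    list(type = "Feature",
         properties = list(id = b$id, residents = b$residents, area = b$area,
                           altitude = b$altitude,
                           green_adjacent = b$green_adjacent),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = block_features),
    file.path(dir, "blocks.geojson"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(extent = city$extent, centre = city$centre),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a city scene back from GeoJSON and CSV files
#'
#' Inverse of [write_city_scene()]. The altitude field of a scene read
#' from disk is reconstructed by nearest-block-centroid lookup of the
#' stored block altitudes.
#'
#' @param dir directory written by [write_city_scene()].
#' @return A `city_scene`.
#' @export
read_city_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"))
  rj <- jsonlite::read_json(file.path(dir, "roads.geojson"))
  roads <- do.call(rbind, lapply(rj$features, function(f) {
    cc <- f$geometry$coordinates
    data.frame(x1 = cc[[1]][[1]], y1 = cc[[1]][[2]],
               x2 = cc[[2]][[1]], y2 = cc[[2]][[2]],
               vehicles_per_day = f$properties$vehicles_per_day,
               id = f$properties$id)
  }))
  bj <- jsonlite::read_json(file.path(dir, "blocks.geojson"))
  blocks <- do.call(rbind, lapply(bj$features, function(f) {
    data.frame(id = f$properties$id, residents = f$properties$residents,
               area = f$properties$area, altitude = f$properties$altitude,
               green_adjacent = isTRUE(f$properties$green_adjacent))
  }))
  block_polygons <- lapply(bj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    k <- length(ring) - 1  # last vertex repeats the first
    list(x = vapply(ring[seq_len(k)], function(v) v[[1]], numeric(1)),
         y = vapply(ring[seq_len(k)], function(v) v[[2]], numeric(1)))
  })
  blocks$cx <- vapply(block_polygons, function(p) mean(p$x), numeric(1))
  blocks$cy <- vapply(block_polygons, function(p) mean(p$y), numeric(1))
  altitude_field <- local({
    cx <- blocks$cx; cy <- blocks$cy; alt <- blocks$altitude
    function(x, y) {
      vapply(seq_along(x), function(i) {
        alt[which.min((cx - x[i])^2 + (cy - y[i])^2)]
      }, numeric(1))
    }
  })
  structure(
    list(extent = meta$extent, centre = unlist(meta$centre), roads = roads,
         blocks = blocks[, c("id", "cx", "cy", "residents", "area",
                             "altitude", "green_adjacent")],
         block_polygons = block_polygons, altitude_field = altitude_field,
         config = NULL, seed = NULL),
    class = "city_scene")
}

#' Write a measurement set to CSV files
#'
#' @param ms a `measurement_set`.
#' @param dir output directory.
#' @param prefix file name prefix (e.g. the campaign label).
#' @return `dir`, invisibly.
#' @export
write_measurements <- function(ms, dir, prefix = paste0("campaign", ms$campaign)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- ms$records
  rec$campaign <- ms$campaign
  rec$sampler <- ms$sampler
  utils::write.csv(rec, file.path(dir, paste0(prefix, "_measurements.csv")),
                   row.names = FALSE)
  utils::write.csv(ms$sites, file.path(dir, paste0(prefix, "_sites.csv")),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a measurement set from CSV files
#'
#' @param dir,prefix as in [write_measurements()].
#' @return A `measurement_set`.
#' @export
read_measurements <- function(dir, prefix) {
  rec <- utils::read.csv(file.path(dir, paste0(prefix, "_measurements.csv")))
  sites <- utils::read.csv(file.path(dir, paste0(prefix, "_sites.csv")))
  structure(list(campaign = rec$campaign[1], sampler = rec$sampler[1],
                 records = rec[, c("site_id", "period", "value")],
                 sites = sites),
            class = "measurement_set")
}

#' Write a fitted LUR model to JSON
#'
#' Stores coefficients, p-values, fit statistics and the elimination
#' trace.
#'
#' @param model a `lur` fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lur_json <- function(model, path) {
  jsonlite::write_json(list(
    campaign = model$campaign,
    selected = model$selected,
    coefficients = as.list(model$coefficients),
    p_values = as.list(model$p_values),
    r2 = model$r2, adjusted_r2 = model$adjusted_r2,
    rmse_log = model$rmse_log, n_sites = model$n_sites,
    p_remove = model$p_remove, sign_rule = model$sign_rule,
    expected_signs = as.list(model$signs),
    trace = model$trace
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
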