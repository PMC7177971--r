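#' Write unit polygons to GeoJSON
#'
#' Serialises a units table (as produced by [gen_landscape()]) to a GeoJSON
#' FeatureCollection of Polygon features with `unit_id`, `geography_class`,
#' `county_id`, and `area_km2` properties. Coordinates are planar km; no CRS
#' member is written.
#'
#' @param units data frame with a `ring` list column of closed vertex
#'   matrices plus the identifier columns above.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_geography <- function(units, path) {
  stopifnot(is.data.frame(units), "ring" %in% names(units))
  features <- lapply(seq_len(nrow(units)), function(i) {
    r <- units$ring[[i]]
    coords <- lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    list(
      type = "Feature",
      properties = list(unit_id = units$unit_id[i],
                        geography_class = units$geography_class[i],
                        county_id = units$county_id[i],
                        area_km2 = units$area_km2[i]),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read unit polygons from GeoJSON
#'
#' Inverse of [write_geography()]: reads a FeatureCollection of Polygon
#' features and returns a units data frame with a `ring` list column (outer
#' ring only; holes are not supported).
#'
#' @param path GeoJSON file path.
#' @return data frame with `unit_id`, `geography_class`, `county_id`,
#'   `area_km2`, `ring`.
#' @export
read_geography <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection: ", path)
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    data.frame(unit_id = p$unit_id,
               geography_class = p$geography_class %||% NA_character_,
               county_id = p$county_id %||% NA_character_,
               area_km2 = as.numeric(p$area_km2 %||% NA_real_),
               stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, rows)
  units$ring <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("x", "y")
    m
  })
  units
}
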