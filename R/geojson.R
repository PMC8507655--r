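# Minimal GeoJSON FeatureCollection reader/writer over jsonlite, covering the
# geometries this package produces and consumes: Polygon with a single outer
# ring, and MultiPolygon whose polygons each have a single outer ring. Rings
# with holes are rejected rather than silently mis-measured.

geojson_ring_to_part <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  # GeoJSON rings are closed; drop the repeated last vertex
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

geojson_to_geometry <- function(g, label = "feature") {
  if (is.null(g) || is.null(g$type)) {
    stop("missing geometry for ", label, call. = FALSE)
  }
  if (g$type == "Polygon") {
    if (length(g$coordinates) != 1) {
      stop("polygon with holes not supported (", label, ")", call. = FALSE)
    }
    parts <- list(geojson_ring_to_part(g$coordinates[[1]]))
  } else if (g$type == "MultiPolygon") {
    parts <- lapply(g$coordinates, function(poly) {
      if (length(poly) != 1) {
        stop("polygon with holes not supported (", label, ")", call. = FALSE)
      }
      geojson_ring_to_part(poly[[1]])
    })
  } else {
    stop("unsupported geometry type '", g$type, "' (", label, ")", call. = FALSE)
  }
  validate_geometry(parts, label)
}

part_to_ring <- function(part) {
  closed <- rbind(part, part[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

geometry_to_geojson <- function(geom) {
  if (is.matrix(geom)) geom <- list(geom)
  if (length(geom) == 1) {
    list(type = "Polygon", coordinates = list(part_to_ring(geom[[1]])))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(geom, function(p) list(part_to_ring(p))))
  }
}

read_feature_collection <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  fc$features
}

features_to_tibble <- function(features, id_field) {
  props <- lapply(features, function(f) f$properties)
  geoms <- lapply(seq_along(features), function(i) {
    label <- props[[i]][[id_field]]
    if (is.null(label)) label <- paste0("feature ", i)
    geojson_to_geometry(features[[i]]$geometry, label)
  })
  cols <- unique(unlist(lapply(props, names)))
  out <- lapply(cols, function(nm) {
    vals <- lapply(props, function(p) if (is.null(p[[nm]])) NA else p[[nm]])
    unlist(vals)
  })
  names(out) <- cols
  df <- tibble::as_tibble(out)
  df$geometry <- geoms
  df
}

write_feature_collection <- function(df, path, geometry_col = "geometry") {
  prop_cols <- setdiff(names(df), geometry_col)
  features <- lapply(seq_len(nrow(df)), function(i) {
    props <- lapply(prop_cols, function(nm) df[[nm]][[i]])
    names(props) <- prop_cols
    list(type = "Feature",
         properties = props,
         geometry = geometry_to_geojson(df[[geometry_col]][[i]]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read census tracts from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features carrying at
#' least `tract_id` and `population` properties; any property whose name
#' starts with `sub_` is treated as a demographic subgroup count.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with `tract_id`, `population`, `sub_*` count columns and
#'   a `geometry` list-column of vertex matrices.
#' @export
read_tracts_geojson <- function(path) {
  df <- features_to_tibble(read_feature_collection(path), "tract_id")
  if (!all(c("tract_id", "population") %in% names(df))) {
    stop("tract GeoJSON must carry 'tract_id' and 'population' properties",
         call. = FALSE)
  }
  df
}

#' Read water-system service areas from GeoJSON
#'
#' Expects a FeatureCollection with `pwsid` and `reported_population`
#' properties per feature.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with `pwsid`, `reported_population` and a `geometry`
#'   list-column.
#' @export
read_systems_geojson <- function(path) {
  df <- features_to_tibble(read_feature_collection(path), "pwsid")
  if (!all(c("pwsid", "reported_population") %in% names(df))) {
    stop("system GeoJSON must carry 'pwsid' and 'reported_population' properties",
         call. = FALSE)
  }
  df
}

#' Write tracts or service areas to GeoJSON
#'
#' The `geometry` list-column becomes Polygon/MultiPolygon geometries; all
#' other columns become feature properties.
#'
#' @param df A tibble with a `geometry` list-column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_geojson <- function(df, path) {
  write_feature_collection(df, path)
}
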