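#' Read and write cell boundary polygons as GeoJSON
#'
#' Polygons are exchanged as a GeoJSON `FeatureCollection` of `Polygon`
#' features, each with a `label` property.  Only simple polygons without
#' holes are supported; coordinates are global µm in the package's y-down
#' convention.  GeoJSON rings repeat the first vertex at the end; the reader
#' drops that duplicate so vertices match the implicitly-closed
#' [cell_polygon()] convention.
#'
#' @param path GeoJSON file path.
#' @return `read_polygons()`: a list of [cell_polygon()]s.
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon")
      stop("unsupported geometry type: ",
           if (is.null(geom$type)) "<none>" else geom$type,
           " (only Polygon without holes is supported)")
    if (length(geom$coordinates) != 1L)
      stop("polygons with holes are not supported")
    label <- f$properties$label
    if (is.null(label)) stop("polygon feature lacks the 'label' property")
    ring <- geom$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    n <- nrow(v)
    if (n >= 2L && all(abs(v[n, ] - v[1, ]) < 1e-12))
      v <- v[-n, , drop = FALSE]
    cell_polygon(v, label)
  })
}

#' @rdname read_polygons
#' @param polygons A list of [cell_polygon()]s.
#' @export
write_polygons <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    stopifnot(inherits(p, "cell_polygon"))
    v <- rbind(p$vertices, p$vertices[1, ])
    ring <- lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
    list(type = "Feature",
         properties = list(label = p$label),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
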