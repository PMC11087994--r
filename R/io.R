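#' Write zones to GeoJSON
#'
#' One Feature per TAZ with properties `taz_id` and `total_population`;
#' geometry is the TAZ polygon ring when present, otherwise the centroid
#' point. Coordinates are planar kilometres (synthetic cities carry no
#' geodetic projection).
#'
#' @param zones Zones tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    geom <- if (!is.null(zones$polygon) && !is.null(zones$polygon[[i]])) {
      ring <- zones$polygon[[i]]
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(k) unname(ring[k, ]))))
    } else {
      list(type = "Point", coordinates = c(zones$x[i], zones$y[i]))
    }
    list(type = "Feature",
         properties = list(taz_id = zones$taz_id[i],
                           centroid_x = zones$x[i],
                           centroid_y = zones$y[i],
                           total_population = zones$total_population[i]),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read zones from GeoJSON
#'
#' @param path GeoJSON file written by [write_zones_geojson()] (or any
#'   FeatureCollection with `taz_id`/`total_population` properties and
#'   Point or Polygon geometries in planar km).
#' @return Zones tibble.
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    if (f$geometry$type == "Polygon") {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(xy) unlist(xy)))
      colnames(ring) <- c("x", "y")
      cx <- p$centroid_x %||% mean(ring[-nrow(ring), 1])
      cy <- p$centroid_y %||% mean(ring[-nrow(ring), 2])
    } else {
      xy <- unlist(f$geometry$coordinates)
      ring <- NULL; cx <- xy[1]; cy <- xy[2]
    }
    tibble::tibble(taz_id = p$taz_id, x = cx, y = cy,
                   total_population = as.integer(p$total_population),
                   polygon = list(ring))
  })
  dplyr::bind_rows(rows)
}

#' Write the per-TAZ accessibility choropleth
#'
#' GeoJSON FeatureCollection with per-TAZ `shortest_minutes`, `covered`
#' (at the given threshold) and `color_bin` — the isochrone band the TAZ
#' falls in, at `bin`-minute intervals ("0-10", "10-20", ...).
#'
#' @param zones Zones tibble.
#' @param nearest Tibble from [nearest_service_times()].
#' @param level Congestion level to map.
#' @param path Output file.
#' @param threshold Coverage threshold minutes (default 20).
#' @param bin Isochrone bin width minutes (default 10).
#' @return `path`, invisibly.
#' @export
write_choropleth_geojson <- function(zones, nearest, level, path,
                                     threshold = 20, bin = 10) {
  sub <- nearest[nearest$level == level, ]
  sm <- sub$shortest_minutes[match(zones$taz_id, sub$origin_taz)]
  lo <- floor(sm / bin) * bin
  z <- zones
  z$shortest_minutes <- sm
  z$covered <- sm <= threshold
  z$color_bin <- sprintf("%d-%d", lo, lo + bin)
  feats <- lapply(seq_len(nrow(z)), function(i) {
    ring <- z$polygon[[i]]
    geom <- if (!is.null(ring))
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(k) unname(ring[k, ]))))
    else list(type = "Point", coordinates = c(z$x[i], z$y[i]))
    list(type = "Feature",
         properties = list(taz_id = z$taz_id[i],
                           total_population = z$total_population[i],
                           shortest_minutes = z$shortest_minutes[i],
                           covered = z$covered[i],
                           color_bin = z$color_bin[i]),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a siting solution to JSON
#'
#' @param solution A `siting_solution`.
#' @param path Output file.
#' @param gains Optional gains table from [predict_gains()].
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(solution, path, gains = NULL) {
  out <- list(n_new = solution$n_new,
              chosen_taz_ids = as.list(solution$taz_ids),
              objective = solution$objective,
              baseline = solution$baseline,
              gain = solution$gain,
              percent = solution$percent,
              level = solution$level,
              threshold = solution$threshold,
              method = solution$method)
  if (!is.null(gains)) out$per_subgroup <- gains
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
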