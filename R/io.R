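# File interchange: tracks and point tables as CSV (ISO-8601 timestamps),
# rasters as single-band TIFF with a JSON sidecar carrying georeferencing
# (values are 16-bit quantized; the sidecar stores the value range), home
# ranges as GeoJSON polygons.

#' Write / read a track as CSV
#'
#' @param track track tibble (`individual_id`, `timestamp`, `x`, `y`, and
#'   any extra columns such as `activity`, `true_state`).
#' @param path file path.
#' @return `read_track_csv` returns the track tibble with POSIXct timestamps.
#' @export
write_track_csv <- function(track, path) {
  out <- dplyr::mutate(track,
                       timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(tr, timestamp = as.POSIXct(.data$timestamp,
                                           format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

#' Write / read a raster as TIFF + JSON sidecar
#'
#' The TIFF holds 16-bit quantized values; the sidecar (`<path>.json`) holds
#' the origin, resolution, value range and category levels, so the grid
#' round-trips to within 1/65535 of its value range.
#'
#' @param r an [hs_raster].
#' @param path TIFF path (`.tif`).
#' @return `read_raster_tiff` returns the [hs_raster].
#' @export
write_raster_tiff <- function(r, path) {
  v <- raster_values(r)
  vmin <- min(v, na.rm = TRUE); vmax <- max(v, na.rm = TRUE)
  scale <- if (vmax > vmin) vmax - vmin else 1
  q <- (v - vmin) / scale
  q[is.na(q)] <- 0
  tiff::writeTIFF(q[rev(seq_len(nrow(q))), , drop = FALSE], path,
                  bits.per.sample = 16L)
  meta <- list(xmin = r$xmin, ymin = r$ymin, res = r$res,
               vmin = vmin, vmax = vmax,
               nrow = nrow(v), ncol = ncol(v),
               levels = r$levels,
               na_cells = which(is.na(v)) - 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  q <- tiff::readTIFF(path)
  v <- q[rev(seq_len(nrow(q))), , drop = FALSE] * (meta$vmax - meta$vmin) + meta$vmin
  if (length(meta$na_cells)) v[unlist(meta$na_cells) + 1L] <- NA_real_
  levels <- if (length(meta$levels)) unlist(meta$levels)
  if (!is.null(levels)) v <- round(v)
  hs_raster(v, xmin = meta$xmin, ymin = meta$ymin, res = meta$res,
            levels = levels)
}

#' Write a landscape stack as one TIFF per band
#'
#' @param landscape a `landscape_stack`.
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (band in c("canopy", "elevation", "vegclass")) {
    write_raster_tiff(landscape[[band]], file.path(dir, paste0(band, ".tif")))
  }
  invisible(dir)
}

#' Write home-range polygons as GeoJSON
#'
#' @param polys named list of `hs_polygon` (names = individual ids).
#' @param path output path.
#' @export
write_home_ranges_geojson <- function(polys, path) {
  features <- purrr::imap(polys, function(p, id) {
    xy <- polygon_coords(p)
    ring <- rbind(xy, xy[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(individual_id = id,
                        area_km2 = polygon_area(p) / 1e6),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ])))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(features)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write used/available points with a role column
#'
#' @param used,available point tibbles with `individual_id`, `x`, `y`.
#' @param path output path.
#' @export
write_points_csv <- function(used, available, path) {
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(used, role = "used"),
    dplyr::mutate(available, role = "available")
  ), path)
  invisible(path)
}

# CSV with a config-hash comment header (readable with read_csv(comment = "#"))
write_csv_stamped <- function(df, path, hash) {
  writeLines(c(paste0("# config_hash: ", hash),
               sub("\n$", "", readr::format_csv(df))), path)
  invisible(path)
}
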