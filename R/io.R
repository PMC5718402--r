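# Plain-text writers for the simulated SRDL bundle and pipeline outputs.

#' Write a table as CSV (UTC timestamps in ISO 8601)
#' @param x data.frame
#' @param path output file
#' @export
write_srdl_csv <- function(x, path) {
  for (v in names(x))
    if (inherits(x[[v]], "POSIXct"))
      x[[v]] <- format(x[[v]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_srdl_csv()], restoring timestamp columns
#' @param path file path
#' @param time_cols columns to parse as UTC timestamps
#' @export
read_srdl_csv <- function(path, time_cols = intersect(
  c("time", "start_time", "end_time", "start", "end"),
  names(utils::read.csv(path, nrows = 1)))) {
  x <- utils::read.csv(path)
  for (v in time_cols)
    x[[v]] <- as.POSIXct(x[[v]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if ("day" %in% names(x)) x$day <- as.Date(x$day)
  x
}

#' Write simulation ground truth as JSON (functions are not serialized)
#' @param truth the `truth` element of [simulate_track()]
#' @param path output file
#' @export
write_truth_json <- function(truth, path) {
  tr <- truth
  tr$latent$time <- format(tr$latent$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (nrow(tr$haulouts)) {
    tr$haulouts$start <- format(tr$haulouts$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    tr$haulouts$end <- format(tr$haulouts$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  tr$condition$day <- format(tr$condition$day)
  tr$classes <- as.list(tr$classes)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Export a trip as a GeoJSON LineString
#' @param trip data.frame with lon, lat
#' @param path output file
#' @param properties named list of feature properties
#' @export
write_trip_geojson <- function(trip, path, properties = list()) {
  gj <- list(type = "Feature", properties = properties,
             geometry = list(type = "LineString",
                             coordinates = mapply(c, trip$lon, trip$lat,
                                                  SIMPLIFY = FALSE)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
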