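# Gridded environmental fields: a lightweight lon/lat(/time) raster container
# with nearest-cell and bilinear lookup, plus synthetic field generators and a
# plain-text serialization. Real products (ETOPO-style relief, passive-
# microwave ice concentration) can be loaded into the same container from any
# source that yields axes + a value array.

#' Construct a gridded environmental field
#'
#' @param variable one of "bathymetry_m", "ice_fraction", "sst_C" (free-form
#'   names are allowed; these three are what the pipeline consumes).
#' @param lon,lat strictly increasing axis vectors (degrees).
#' @param values numeric array `length(lon) x length(lat)` or
#'   `length(lon) x length(lat) x length(time)`.
#' @param time optional `Date` vector for the third array dimension.
#' @return object of class `env_grid`
#' @export
env_grid <- function(variable, lon, lat, values, time = NULL) {
  stopifnot(all(diff(lon) > 0), all(diff(lat) > 0))
  if (is.null(time)) {
    values <- array(values, dim = c(length(lon), length(lat)))
  } else {
    stopifnot(length(time) >= 1)
    values <- array(values, dim = c(length(lon), length(lat), length(time)))
  }
  if (variable == "ice_fraction" &&
      any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("ice_fraction values must lie in [0, 1]")
  if (variable == "bathymetry_m" && any(values < 0, na.rm = TRUE))
    stop("bathymetry is stored positive-down; negative depths not allowed")
  structure(list(variable = variable, lon = lon, lat = lat,
                 time = time, values = values),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat("<env_grid>", x$variable, ":", length(x$lon), "x", length(x$lat),
      if (!is.null(x$time)) paste("x", length(x$time), "dates"), "\n")
  invisible(x)
}

#' Look up a gridded value at positions (and optionally dates)
#'
#' Nearest-cell by default; `method = "bilinear"` interpolates the four
#' surrounding cells. The time dimension, when present, is always matched to
#' the nearest available date. Out-of-bounds queries return `NA` with a
#' warning.
#'
#' @param grid an [env_grid()]
#' @param lon,lat query positions (vectors recycle)
#' @param date optional `Date` (required if the grid has a time axis)
#' @param method "nearest" or "bilinear"
#' @return numeric vector of values
#' @export
env_lookup <- function(grid, lon, lat, date = NULL,
                       method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  ti <- rep_len(1L, n)
  if (!is.null(grid$time)) {
    if (is.null(date)) stop("grid has a time axis; supply `date`")
    date <- rep_len(as.Date(date), n)
    tn <- as.numeric(grid$time)
    ti <- vapply(as.numeric(date),
                 function(d) which.min(abs(tn - d)), integer(1))
  }
  oob <- lon < min(grid$lon) | lon > max(grid$lon) |
         lat < min(grid$lat) | lat > max(grid$lat)
  if (any(oob, na.rm = TRUE))
    warning(sum(oob, na.rm = TRUE), " lookup position(s) outside grid bounds")
  out <- rep(NA_real_, n)
  ok <- which(!oob & !is.na(lon) & !is.na(lat))
  if (method == "nearest") {
    for (k in ok) {
      i <- which.min(abs(grid$lon - lon[k]))
      j <- which.min(abs(grid$lat - lat[k]))
      out[k] <- if (is.null(grid$time)) grid$values[i, j]
                else grid$values[i, j, ti[k]]
    }
  } else {
    for (k in ok) {
      i <- findInterval(lon[k], grid$lon, all.inside = TRUE)
      j <- findInterval(lat[k], grid$lat, all.inside = TRUE)
      fx <- (lon[k] - grid$lon[i]) / (grid$lon[i + 1] - grid$lon[i])
      fy <- (lat[k] - grid$lat[j]) / (grid$lat[j + 1] - grid$lat[j])
      v <- if (is.null(grid$time)) grid$values[i:(i + 1), j:(j + 1)]
           else grid$values[i:(i + 1), j:(j + 1), ti[k]]
      out[k] <- (1 - fx) * (1 - fy) * v[1, 1] + fx * (1 - fy) * v[2, 1] +
                (1 - fx) * fy * v[1, 2] + fx * fy * v[2, 2]
    }
  }
  out
}

#' Synthetic bathymetry, sea-ice and SST fields for the simulator
#'
#' Smooth analytic fields over the Northeast Atlantic study domain
#' (30W-40E, 55-85N): bathymetry with shelf-and-basin structure (~50-4000 m),
#' monthly SST with a meridional gradient and a seasonal cycle (about -2 to
#' +11 C over the domain), and ice concentration increasing toward the
#' northwest with a winter maximum.
#'
#' @param res grid resolution in degrees
#' @param months `Date` vector of monthly time steps for sst/ice
#' @return named list of three [env_grid()]s: `bathymetry`, `sst`, `ice`
#' @export
make_synthetic_env <- function(res = 0.5,
                               months = seq(as.Date("2008-01-15"),
                                            as.Date("2009-06-15"),
                                            by = "month")) {
  lon <- seq(-30, 40, by = res)
  lat <- seq(55, 85, by = res)
  lonm <- matrix(lon, length(lon), length(lat))
  latm <- matrix(lat, length(lon), length(lat), byrow = TRUE)
  bathy <- 1800 + 1200 * sin(lonm * pi / 30) * cos((latm - 55) * pi / 20) +
    600 * cos(lonm * pi / 15) - 900 * exp(-((latm - 73.86)^2 + (lonm - 13.5)^2 / 4) / 18)
  bathy <- pmax(bathy, 50)
  doy <- as.integer(format(months, "%j"))
  sst <- array(0, c(length(lon), length(lat), length(months)))
  ice <- sst
  for (k in seq_along(months)) {
    seas <- cos(2 * pi * (doy[k] - 227) / 365.25)  # warmest mid-August
    sst[, , k] <- pmax(-1.9, 9 - 0.45 * (latm - 58) +
                         1.2 * sin(lonm * pi / 40) + 2.2 * seas)
    ice[, , k] <- pmin(1, pmax(0, stats::plogis((latm - 74 - 4 * seas) / 1.5) *
                                 stats::plogis(-(lonm - 5) / 6)))
  }
  list(bathymetry = env_grid("bathymetry_m", lon, lat, bathy),
       sst = env_grid("sst_C", lon, lat, sst, time = months),
       ice = env_grid("ice_fraction", lon, lat, ice, time = months))
}

#' Write / read an env_grid as plain text
#'
#' A small self-describing text format (header lines then one row of values
#' per longitude, time slices concatenated) so synthetic rasters can ship
#' with analyses and round-trip exactly.
#'
#' @param grid an [env_grid()]
#' @param path file path
#' @export
write_env_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("variable", grid$variable),
               paste("lon", paste(format(grid$lon, digits = 12, trim = TRUE),
                                  collapse = " ")),
               paste("lat", paste(format(grid$lat, digits = 12, trim = TRUE),
                                  collapse = " ")),
               paste("time", if (is.null(grid$time)) "none"
                     else paste(format(grid$time), collapse = " "))), con)
  nt <- if (is.null(grid$time)) 1L else length(grid$time)
  for (k in seq_len(nt)) {
    v <- if (is.null(grid$time)) grid$values else grid$values[, , k]
    # one line per latitude so the reader's column-major fill (lon fastest)
    # reconstructs the array exactly
    utils::write.table(format(t(v), digits = 12, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  ln <- readLines(path)
  variable <- sub("^variable ", "", ln[1])
  toks <- function(s) {
    v <- strsplit(trimws(s), "[ \t]+")[[1]]
    v[nzchar(v)]
  }
  lon <- as.numeric(toks(sub("^lon ", "", ln[2])))
  lat <- as.numeric(toks(sub("^lat ", "", ln[3])))
  tfield <- sub("^time ", "", ln[4])
  time <- if (identical(tfield, "none")) NULL
          else as.Date(toks(tfield))
  vals <- as.numeric(unlist(strsplit(trimws(ln[-(1:4)]), "[ \t]+")))
  env_grid(variable, lon, lat, vals, time = time)
}
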