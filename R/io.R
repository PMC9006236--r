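#' Read a sample table from CSV
#'
#' One row per sample; a column named `abundance` holds the abundances and
#' every other numeric column is an environmental dimension. Optional `lat`,
#' `lon` and `date` columns carry spatiotemporal coordinates and are ignored
#' by the analysis.
#'
#' @param path CSV file path.
#' @param abundance_col Name of the abundance column.
#' @return A tibble.
#' @export
read_sample_table <- function(path, abundance_col = "abundance") {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!abundance_col %in% names(tb)) {
    stop("no '", abundance_col, "' column in ", path, call. = FALSE)
  }
  tb
}

#' Write a chromatogram to CSV (+ JSON sidecar)
#'
#' The CSV holds the standardized alpha x p matrix, row 1 = category 1 (the
#' lowest environmental values), one header column per dimension, missing
#' categories as empty cells. A JSON sidecar (`<path>.json`) records the
#' parameters, the per-dimension (min, max) used for standardization, and
#' the per-category sample counts, so the pair round-trips losslessly
#' through [read_chromatogram()].
#'
#' @param chrom A [chromatogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  readr::write_csv(tibble::as_tibble(chrom$wstar), path, na = "")
  sidecar <- list(
    params = chrom$params,
    species = chrom$species,
    n_samples = chrom$n_samples,
    env_range = chrom$env_range,
    counts = tibble::as_tibble(chrom$counts)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a chromatogram written by [write_chromatogram()]
#'
#' Restores the standardized matrix, parameters, environmental ranges and
#' category counts. The per-sample data and contributor records are not
#' serialized, so [niche_optimum()] (which needs the raw samples) is not
#' available on a re-read chromatogram; breadth and overlap are.
#'
#' @param path CSV path previously written by [write_chromatogram()].
#' @return A `chromatogram` object.
#' @export
read_chromatogram <- function(path) {
  wstar <- as.matrix(readr::read_csv(path, show_col_types = FALSE,
                                     na = c("", "NA")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts <- as.matrix(tibble::as_tibble(sidecar$counts))
  storage.mode(counts) <- "integer"
  structure(
    list(
      wstar = wstar,
      raw = NULL,
      unsmoothed = NULL,
      counts = counts,
      contributors = NULL,
      env = NULL,
      abundance = NULL,
      env_range = tibble::as_tibble(sidecar$env_range),
      params = lapply(sidecar$params, function(x) x),
      species = sidecar$species,
      n_samples = sidecar$n_samples,
      n_dropped = NA_integer_
    ),
    class = "chromatogram"
  )
}

#' Gridded environmental field
#'
#' Container for a regular latitude x longitude (x time) field of one
#' environmental variable, used to attribute an environmental value to each
#' sample by nearest-neighbour matching.
#'
#' @param values Numeric array, `lat x lon` or `lat x lon x time`; `NA` cells
#'   allowed (e.g. cloud cover).
#' @param lat,lon Strictly monotone coordinate vectors.
#' @param time Optional strictly monotone time axis (`Date` or numeric days).
#' @param var Variable name.
#' @param units Units string.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, lat, lon, time = NULL, var = "env", units = "") {
  values <- as.array(values)
  nd <- length(dim(values))
  stopifnot(nd %in% c(2, 3))
  stopifnot(dim(values)[1] == length(lat), dim(values)[2] == length(lon))
  check_monotone <- function(x, nm) {
    if (length(x) > 1 && !(all(diff(as.numeric(x)) > 0) ||
                           all(diff(as.numeric(x)) < 0))) {
      stop(nm, " coordinates must be strictly monotone", call. = FALSE)
    }
  }
  check_monotone(lat, "lat")
  check_monotone(lon, "lon")
  if (nd == 3) {
    if (is.null(time)) stop("3-d values need a time axis", call. = FALSE)
    stopifnot(dim(values)[3] == length(time))
    check_monotone(time, "time")
  }
  structure(list(values = values, lat = lat, lon = lon, time = time,
                 var = var, units = units),
            class = "env_grid")
}

#' Nearest-neighbour matching of samples to a gridded field
#'
#' Attributes to each sample the value of the grid cell whose centre is
#' nearest, looking up the nearest coordinate independently on each axis
#' (nearest latitude, nearest longitude, nearest day) — the natural
#' nearest-neighbour rule on a regular grid. A sample falling exactly midway
#' between two nodes is assigned to the lower index. Samples over missing
#' grid cells receive `NA` (and are discarded later by [chromatogram()],
#' which counts the drops).
#'
#' @param samples Data frame with columns `lat`, `lon` and, for a 3-d grid,
#'   `date` (`Date` or numeric days).
#' @param grid An [env_grid()].
#' @return The input `samples` with one new column named after `grid$var`.
#' @export
match_env_nearest <- function(samples, grid) {
  stopifnot(inherits(grid, "env_grid"), is.data.frame(samples))
  if (length(grid$lat) == 0 || length(grid$lon) == 0 ||
      length(grid$values) == 0) {
    stop("empty grid", call. = FALSE)
  }
  stopifnot(all(c("lat", "lon") %in% names(samples)))
  i <- nearest_index(samples$lat, grid$lat)
  j <- nearest_index(samples$lon, grid$lon)
  if (length(dim(grid$values)) == 3) {
    if (!"date" %in% names(samples)) {
      stop("3-d grid needs a 'date' column in samples", call. = FALSE)
    }
    t <- nearest_index(as.numeric(samples$date), as.numeric(grid$time))
    vals <- grid$values[cbind(i, j, t)]
  } else {
    vals <- grid$values[cbind(i, j)]
  }
  samples[[grid$var]] <- vals
  samples
}

# index of nearest node; ties broken toward the lower index
nearest_index <- function(x, nodes) {
  ord <- order(nodes)
  sorted <- nodes[ord]
  vapply(x, function(v) {
    dist <- abs(sorted - v)
    ord[which.min(dist)] # which.min returns the first (lower) index on ties
  }, integer(1))
}

#' Photosynthetically active radiation at depth (Beer-Lambert law)
#'
#' I_Z = I_0 * exp(-K_d * Z): surface irradiance attenuated exponentially
#' with depth at rate K_d.
#'
#' @param I0 Surface irradiance (e.g. E m^-2 day^-1); vectorized.
#' @param Kd Diffuse attenuation coefficient (m^-1, >= 0).
#' @param Z Depth (m, >= 0).
#' @return Irradiance at depth `Z`, same units as `I0`.
#' @examples
#' par_at_depth(1, Kd = 0.1, Z = 10) # exp(-1)
#' @export
par_at_depth <- function(I0, Kd, Z) {
  if (any(Kd < 0)) stop("Kd must be >= 0", call. = FALSE)
  if (any(Z < 0)) stop("Z must be >= 0", call. = FALSE)
  I0 * exp(-Kd * Z)
}
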