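#' Read and write ESRI ASCII bathymetry grids
#'
#' A `bathy_raster` holds positive water depths (metres, positive down) on
#' a regular lon/lat grid, stored rows north to south as in the ESRI ASCII
#' format (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value` header, then one row of values per line).
#'
#' @param path file path.
#' @return `read_bathymetry()` a `bathy_raster`; `write_bathymetry()` the
#'   path, invisibly.
#' @export
read_bathymetry <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count does not match ncols x nrows")
  depths <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  depths[depths == nodata] <- NA_real_
  structure(list(depths = depths, ncols = hdr$ncols, nrows = hdr$nrows,
                 xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = nodata),
            class = "bathy_raster")
}

#' @rdname read_bathymetry
#' @param raster a `bathy_raster`.
#' @export
write_bathymetry <- function(raster, path) {
  stopifnot(inherits(raster, "bathy_raster"))
  d <- raster$depths
  d[is.na(d)] <- raster$nodata
  hdr <- c(sprintf("ncols %d", raster$ncols),
           sprintf("nrows %d", raster$nrows),
           sprintf("xllcorner %.17g", raster$xll),
           sprintf("yllcorner %.17g", raster$yll),
           sprintf("cellsize %.17g", raster$cellsize),
           sprintf("NODATA_value %.17g", raster$nodata))
  rows <- apply(d, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Nearest-cell depth lookup
#'
#' Returns the depth of the grid cell containing each query point; NA (with
#' one warning) for points outside the extent, NA for NODATA cells. No
#' interpolation: the native cells are fine-grained relative to GPS noise.
#'
#' @param raster a `bathy_raster`.
#' @param lon,lat query coordinates, decimal degrees.
#' @return numeric depths in metres (positive down).
#' @export
depth_at <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "bathy_raster"), length(lon) == length(lat))
  col <- floor((lon - raster$xll) / raster$cellsize) + 1
  row_s <- floor((lat - raster$yll) / raster$cellsize) + 1  # from south
  row <- raster$nrows - row_s + 1
  ok <- !is.na(col) & !is.na(row) & col >= 1 & col <= raster$ncols &
    row >= 1 & row <= raster$nrows
  if (any(!ok & !is.na(lon)))
    warning(sum(!ok & !is.na(lon)), " point(s) outside raster extent")
  out <- rep(NA_real_, length(lon))
  out[ok] <- raster$depths[cbind(row[ok], col[ok])]
  out
}
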