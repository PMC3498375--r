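#' Bivariate kernel density surface over a track
#'
#' Product bivariate normal kernel density estimated on a regular grid of
#' cell centres covering the track's bounding box padded by one bandwidth
#' per side. Axis bandwidths follow the normal reference rule
#' `4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5)`, with the kernel standard
#' deviation a quarter of the bandwidth, matching the convention of the
#' classic R 2D KDE implementation this mirrors. The default 500 x 220
#' grid matches the availability-sampling design.
#'
#' @param points two-column matrix or data.frame of (lon, lat).
#' @param grid_shape `c(nx, ny)` grid dimensions (default `c(500, 220)`).
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; default is the
#'   padded bounding box.
#' @return object of class `density_grid`: `z` (`nx` x `ny` density
#'   matrix), cell-centre axes `x`, `y`, cell sizes `dx`, `dy`, and
#'   bandwidths `hx`, `hy`.
#' @export
kde2d_grid <- function(points, grid_shape = c(500, 220), extent = NULL) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2)
  pts <- pts[complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 2 || nrow(unique(pts)) < 2)
    stop("need at least 2 distinct points for a density surface")
  bw <- function(v) {
    s <- min(sd(v), IQR(v) / 1.34)
    if (s <= 0) s <- sd(v)
    if (s <= 0) stop("zero bandwidth: points are collinear in one axis")
    4 * 1.06 * s * n^(-1 / 5)
  }
  hx <- bw(pts[, 1]); hy <- bw(pts[, 2])
  if (is.null(extent))
    extent <- c(min(pts[, 1]) - hx, max(pts[, 1]) + hx,
                min(pts[, 2]) - hy, max(pts[, 2]) + hy)
  nx <- grid_shape[1]; ny <- grid_shape[2]
  dx <- (extent[2] - extent[1]) / nx
  dy <- (extent[4] - extent[3]) / ny
  x <- extent[1] + (seq_len(nx) - 0.5) * dx
  y <- extent[3] + (seq_len(ny) - 0.5) * dy
  ax <- matrix(dnorm(outer(x, pts[, 1], "-") / (hx / 4)) / (hx / 4),
               nx, n)
  ay <- matrix(dnorm(outer(y, pts[, 2], "-") / (hy / 4)) / (hy / 4),
               ny, n)
  z <- tcrossprod(ax, ay) / n
  structure(list(z = z, x = x, y = y, dx = dx, dy = dy, hx = hx,
                 hy = hy),
            class = "density_grid")
}

#' Apportion a sampling budget across tracks
#'
#' Largest-remainder apportionment of `total` sample points in direct
#' proportion to track lengths (numbers of locations); counts sum exactly
#' to `total`, ties on remainders broken towards earlier tracks.
#'
#' @param track_lengths numeric vector of locations per track.
#' @param total total number of samples (default 5000).
#' @return integer vector of per-track counts summing to `total`.
#' @export
allocate_sample_sizes <- function(track_lengths, total = 5000) {
  if (sum(track_lengths) <= 0) stop("total track length must be positive")
  q <- total * track_lengths / sum(track_lengths)
  n <- floor(q)
  rem <- total - sum(n)
  if (rem > 0) {
    extra <- order(q - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  as.integer(n)
}

#' Draw random locations weighted by a density surface
#'
#' Cells are drawn with replacement with probability proportional to their
#' density mass; each draw is jittered uniformly within its cell so that
#' downstream depth lookups are not quantised to cell centres.
#'
#' @param grid a `density_grid`.
#' @param n number of locations.
#' @param seed RNG seed.
#' @return data.frame `lon, lat` of `n` sampled locations.
#' @export
sample_locations <- function(grid, n, seed = 1) {
  stopifnot(inherits(grid, "density_grid"), n >= 1)
  w <- as.vector(grid$z)
  if (all(w <= 0)) stop("density surface is identically zero")
  set.seed(seed)
  cell <- sample.int(length(w), n, replace = TRUE, prob = w)
  i <- (cell - 1) %% nrow(grid$z) + 1          # x index
  j <- (cell - 1) %/% nrow(grid$z) + 1         # y index
  data.frame(lon = grid$x[i] + runif(n, -0.5, 0.5) * grid$dx,
             lat = grid$y[j] + runif(n, -0.5, 0.5) * grid$dy)
}

#' Depths at sampled locations
#'
#' Nearest-cell bathymetry lookup for a set of sampled locations; the
#' count of missing depths (outside the raster or NODATA) is reported.
#'
#' @param locations data.frame with `lon`, `lat`.
#' @param raster a `bathy_raster`.
#' @return numeric vector of depths (m), NA where missing.
#' @export
sample_depths <- function(locations, raster) {
  if (!nrow(locations)) return(numeric(0))
  d <- depth_at(raster, locations$lon, locations$lat)
  if (anyNA(d))
    message("sample_depths: ", sum(is.na(d)), " location(s) without depth")
  d
}
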