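#' Bilinear regridding to a target resolution
#'
#' Interpolates the temperature cube (and elevation, when present)
#' bilinearly at the cell centres of a regular grid at the requested
#' resolution covering the same domain. Target centres outside the source
#' cell-centre hull are masked (`NA`); there is no extrapolation. Bilinear
#' interpolation is exact on fields linear in latitude/longitude and never
#' leaves the min/max envelope of the source values.
#'
#' @param grid a [climate_grid].
#' @param resolution target resolution in degrees.
#' @return a [climate_grid] on the target grid.
#' @export
regrid_bilinear <- function(grid, resolution) {
  stopifnot(inherits(grid, "climate_grid"), resolution > 0)
  src_lat <- grid$lat; src_lon <- grid$lon
  # target centres on the lattice k*res + res/2 covering the source hull
  tgt_lat <- center_seq(min(src_lat), max(src_lat), resolution)
  tgt_lon <- center_seq(min(src_lon), max(src_lon), resolution)
  if (!length(tgt_lat) || !length(tgt_lon))
    stop("target resolution exceeds the source extent: no target centre ",
         "falls inside the source grid")
  wlat <- interp_weights(src_lat, tgt_lat)
  wlon <- interp_weights(src_lon, tgt_lon)
  ntime <- dim(grid$tas)[3]
  out <- array(NA_real_, c(length(tgt_lat), length(tgt_lon), ntime))
  for (k in seq_len(ntime))
    out[, , k] <- wlat %*% grid$tas[, , k] %*% t(wlon)
  mask_lat <- rowSums(wlat) == 0
  mask_lon <- rowSums(wlon) == 0
  if (any(mask_lat)) out[mask_lat, , ] <- NA
  if (any(mask_lon)) out[, mask_lon, ] <- NA
  elev <- NULL
  if (!is.null(grid$elevation)) {
    elev <- wlat %*% grid$elevation %*% t(wlon)
    if (any(mask_lat)) elev[mask_lat, ] <- NA
    if (any(mask_lon)) elev[, mask_lon] <- NA
  }
  climate_grid(tgt_lat, tgt_lon, grid$time, out, calendar = grid$calendar,
               elevation = elev, provenance = grid$provenance)
}

# centres of a res-grid lying within [lo, hi]
center_seq <- function(lo, hi, res) {
  k_lo <- ceiling((lo - res / 2) / res - 1e-9)
  k_hi <- floor((hi - res / 2) / res + 1e-9)
  if (k_lo > k_hi) return(numeric(0))
  seq(k_lo, k_hi) * res + res / 2
}

# sparse-in-spirit row-stochastic weight matrix for 1-d linear interpolation
interp_weights <- function(src, tgt) {
  w <- matrix(0, length(tgt), length(src))
  for (t in seq_along(tgt)) {
    x <- tgt[t]
    if (x < src[1] - 1e-9 || x > src[length(src)] + 1e-9) next  # masked
    j <- findInterval(x, src, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(src) - 1L)
    if (length(src) == 1L) { w[t, 1] <- 1; next }
    f <- (x - src[j]) / (src[j + 1] - src[j])
    w[t, j] <- 1 - f
    w[t, j + 1] <- f
  }
  w
}
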