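#' Population receptive field size from eccentricity and area
#'
#' pRF size grows approximately linearly with center eccentricity and along
#' the visual hierarchy: `sigma = 0.2 * r * roi^0.7` degrees, with `roi` = 1,
#' 2, 3 for V1, V2, V3. A floor (default 0.05 deg) keeps near-foveal pRFs
#' from collapsing to points.
#'
#' @param r pRF center eccentricity in degrees (>= 0), vectorized.
#' @param roi visual area index in `{1, 2, 3}`, vectorized.
#' @param floor_deg minimum sigma returned.
#' @return pRF sigma in degrees.
#' @export
prf_sigma <- function(r, roi, floor_deg = 0.05) {
  if (any(r < 0)) stop("eccentricity must be >= 0")
  if (!all(roi %in% c(1, 2, 3))) stop("`roi` must be 1, 2, or 3")
  pmax(0.2 * r * roi^0.7, floor_deg)
}

#' Complex-valued task response of a voxel
#'
#' Coherence and phase are folded into one complex number,
#' `c = co * (cos(ph) + i * sin(ph))`, so that averaging across voxels
#' respects phase cancellation.
#'
#' @param co coherence (>= 0), vectorized.
#' @param ph phase in radians, vectorized.
#' @return complex vector with `Mod = co`, `Arg = ph` (mod 2*pi).
#' @export
complex_response <- function(co, ph) {
  if (any(co < 0)) stop("coherence must be >= 0")
  complex(modulus = co, argument = ph)
}

#' Project voxel responses onto the visual field
#'
#' Inverted-encoding projection: for every pixel of a square grid, the
#' complex responses of all voxels are combined with gaussian pRF weights
#' `w_v(p) = exp(-||p - center_v||^2 / (2 * sigma_v^2))`. The default
#' combines them as a weighted mean (weights normalized per pixel, matching
#' the plotted "phase of the mean complex responses"); `mode = "sum"` leaves
#' the raw weighted sum. The pixel phase map is the argument and the
#' coherence map the modulus of the combined response; pixels where every
#' weight underflows are flagged empty.
#'
#' @param c_resp complex responses per voxel (see [complex_response()]).
#' @param prf_x,prf_y pRF centers in degrees.
#' @param sigma pRF sizes in degrees (see [prf_sigma()]).
#' @param grid_n pixels per side.
#' @param extent_deg half-width of the grid (degrees); pixels span
#'   `[-extent, extent]` in x and y.
#' @param mode `"mean"` (weight-normalized) or `"sum"`.
#' @return object of class `field_map`: `x`, `y` (pixel centers), `phase`
#'   and `coherence` matrices (y in rows), logical `empty`, and `mode`.
#' @export
project_field <- function(c_resp, prf_x, prf_y, sigma, grid_n = 121,
                          extent_deg = 12, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  nv <- length(c_resp)
  stopifnot(nv >= 1, length(prf_x) == nv, length(prf_y) == nv,
            length(sigma) == nv, grid_n >= 1, extent_deg > 0)
  gx <- seq(-extent_deg, extent_deg, length.out = grid_n)
  gy <- gx
  phase <- coher <- matrix(NA_real_, grid_n, grid_n)
  empty <- matrix(FALSE, grid_n, grid_n)
  inv2s2 <- 1 / (2 * sigma^2)
  for (iy in seq_len(grid_n)) {
    d2y <- (gy[iy] - prf_y)^2
    for (ix in seq_len(grid_n)) {
      w <- exp(-((gx[ix] - prf_x)^2 + d2y) * inv2s2)
      tot <- sum(w)
      if (tot < 1e-300) {
        empty[iy, ix] <- TRUE
        next
      }
      z <- sum(w * c_resp)
      if (mode == "mean") z <- z / tot
      phase[iy, ix] <- Arg(z) %% (2 * pi)
      coher[iy, ix] <- Mod(z)
    }
  }
  structure(list(x = gx, y = gy, phase = phase, coherence = coher,
                 empty = empty, mode = mode),
            class = "field_map")
}

#' Coherence-weighted centroid of a field map
#'
#' Useful summary for localizer-style maps: the coherence-weighted mean pixel
#' position, in degrees.
#'
#' @param fm a `field_map`.
#' @return named numeric `c(x, y)`.
#' @export
field_centroid <- function(fm) {
  w <- fm$coherence
  w[is.na(w)] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("field map has no coherence mass")
  c(x = sum(outer(rep(1, length(fm$y)), fm$x) * w) / tot,
    y = sum(outer(fm$y, rep(1, length(fm$x))) * w) / tot)
}
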