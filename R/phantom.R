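# Digital phantom: rasterize the ventricle into a voxel volume, carve
# parameterized perfusion defects, and degrade with point-spread blur and
# Poisson counting noise. A desk-scale stand-in for a Monte Carlo projection /
# tomographic reconstruction chain: the quantification consumes reconstructed
# short-axis images, and the dominant image-domain degradations (7 mm FWHM
# post-filter, Poisson counting statistics) are retained.

#' Perfusion defect specification
#'
#' A defect is a sector of reduced uptake: rectangles (or voxels) whose
#' circumferential angle lies within +/- `alpha/2` of the defect center and
#' whose meridian arc position falls inside a band of length `extent_mm` have
#' their uptake multiplied by `1 - severity`. Apical defects are defined by
#' meridian arc distance from the apex pole instead of angle.
#'
#' The apical-basal band placement is controlled by `placement`:
#' `"centered"` (default) centers the band on the short-axis plane through the
#' anatomical centroid, the canonical mid-ventricular wall defect, which keeps
#' the defect balanced along the long axis so that a growing defect moves the
#' perfusion vector in its own short-axis direction while leaving the z
#' component nearly unchanged; `"apex"` anchors the band at the apex pole;
#' `"base"` anchors it at the basal rim.
#'
#' @param location One of `"anterior"`, `"inferior"`, `"lateral"`, `"septal"`,
#'   `"apical"`, `"custom"`. Centers at theta = 270, 90, 0, 180 degrees
#'   respectively; `"custom"` uses `theta_center_deg`.
#' @param alpha Circumferential opening angle, degrees, in (0, 360].
#' @param extent_mm Apical-basal propagation along the meridian, mm (> 0).
#'   Default 60 mm (6 cm).
#' @param severity Fractional uptake reduction in `[0, 1]`; 1 means zero
#'   uptake inside the defect.
#' @param theta_center_deg Defect center angle for `location = "custom"`.
#' @param placement `"centered"`, `"apex"` or `"base"` (ignored for apical
#'   defects, which always grow from the apex pole).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(location = c("anterior", "inferior", "lateral",
                                     "septal", "apical", "custom"),
                        alpha = 50, extent_mm = 60, severity = 1,
                        theta_center_deg = NULL,
                        placement = c("centered", "apex", "base")) {
  location <- match.arg(location)
  placement <- match.arg(placement)
  check_number(alpha, "alpha", lower = 0, upper = 360, strict_lower = TRUE)
  check_number(extent_mm, "extent_mm", lower = 0, strict_lower = TRUE)
  check_number(severity, "severity", lower = 0, upper = 1)
  theta <- switch(location,
                  lateral = 0, inferior = 90, septal = 180, anterior = 270,
                  apical = NA_real_,
                  custom = {
                    if (is.null(theta_center_deg)) {
                      abort("`theta_center_deg` is required for a custom defect",
                            "perfvec_invalid_parameter")
                    }
                    check_number(theta_center_deg, "theta_center_deg")
                    theta_center_deg %% 360
                  })
  structure(list(location = location, alpha = as.numeric(alpha),
                 extent_mm = as.numeric(extent_mm),
                 severity = as.numeric(severity),
                 theta_center_deg = theta, placement = placement),
            class = "defect_spec")
}

#' Acquisition specification for the phantom pipeline
#'
#' @param voxel_size_mm Isotropic voxel size, mm (default 4.8).
#' @param matrix Per-axis voxel counts (length 1 or 3), or `NULL` to crop the
#'   field of view automatically to the ventricle plus `padding_mm`.
#' @param blur_fwhm_mm Full width at half maximum of the Gaussian post-filter,
#'   mm (default 7).
#' @param counts_scale Expected counts in the hottest myocardial voxel before
#'   noise (default 500, a typical clinical myocardial SPECT level).
#' @param seed Integer seed for the Poisson noise draw.
#' @param padding_mm Margin around the ventricle for the automatic field of
#'   view; keeps the blur kernel support inside the volume.
#' @param supersample Antialiasing factor of the rasterizer: each voxel value
#'   is the mean uptake over `supersample^3` sub-voxel sample points, so
#'   partial-volume voxels at the wall and defect boundaries get fractional
#'   values. 1 gives binary voxel-center membership.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(voxel_size_mm = 4.8, matrix = NULL,
                             blur_fwhm_mm = 7, counts_scale = 500,
                             seed = 1L, padding_mm = 15, supersample = 2L) {
  check_number(voxel_size_mm, "voxel_size_mm", lower = 0, strict_lower = TRUE)
  check_number(blur_fwhm_mm, "blur_fwhm_mm", lower = 0)
  check_number(counts_scale, "counts_scale", lower = 0, strict_lower = TRUE)
  check_number(padding_mm, "padding_mm", lower = 0)
  check_number(supersample, "supersample", lower = 1)
  if (!is.null(matrix)) {
    matrix <- as.integer(matrix)
    if (!length(matrix) %in% c(1L, 3L) || any(matrix < 2L)) {
      abort("`matrix` must be one or three voxel counts >= 2",
            "perfvec_invalid_parameter")
    }
    if (length(matrix) == 1L) matrix <- rep(matrix, 3L)
  }
  structure(list(voxel_size_mm = as.numeric(voxel_size_mm), matrix = matrix,
                 blur_fwhm_mm = as.numeric(blur_fwhm_mm),
                 counts_scale = as.numeric(counts_scale),
                 seed = as.integer(seed), padding_mm = as.numeric(padding_mm),
                 supersample = as.integer(supersample)),
            class = "acquisition_spec")
}

#' Voxel volume container
#'
#' A 3-D scalar image in cardiac-frame mm: `data[i, j, k]` is the value at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3-D numeric array, finite values.
#' @param spacing Per-axis voxel spacing, mm (length 1 or 3).
#' @param origin Position of the center of voxel (1, 1, 1), mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array", "perfvec_dimensionality_error")
  }
  if (any(!is.finite(data))) {
    abort("volume values must be finite", "perfvec_invalid_parameter")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be positive, length 1 or 3", "perfvec_invalid_parameter")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be a finite length-3 vector", "perfvec_invalid_parameter")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %dx%dx%d voxels, spacing (%g, %g, %g) mm, sum %.4g\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$data)))
  invisible(x)
}

# Meridian band [lo, hi] of a defect on a given resolved shape, mm of arc from
# the apex pole.
defect_band <- function(shape, defect) {
  cp <- centroid_plane_arc(shape)
  e <- defect$extent_mm
  switch(defect$placement,
         apex = c(0, min(e, cp$total)),
         base = c(max(0, cp$total - e), cp$total),
         centered = {
           lo <- min(max(0, cp$arc - e / 2), max(0, cp$total - e))
           c(lo, min(cp$total, lo + e))
         })
}

# Angular membership: circular distance from the defect center <= alpha / 2.
in_sector <- function(theta_deg, defect) {
  abs(((theta_deg - defect$theta_center_deg + 180) %% 360) - 180) <=
    defect$alpha / 2
}

# Logical defect membership for the rectangles of a parametric grid.
defect_mask <- function(grid, defect) {
  stopifnot(inherits(grid, "surface_grid"), inherits(defect, "defect_spec"))
  if (!isTRUE(grid$parametric)) {
    abort("defect geometry needs a parametric grid (built by build_lv_surface)",
          "perfvec_invalid_parameter")
  }
  d <- grid$data
  if (defect$location == "apical") {
    return(d$arc_mm <= defect$extent_mm)
  }
  band <- defect_band(grid$shape, defect)
  in_sector(d$theta_deg, defect) & d$arc_mm >= band[1] & d$arc_mm <= band[2]
}

#' Ideal (noise-free) surface weights under a defect
#'
#' Weight 1 everywhere, multiplied by `1 - severity` inside the defect. With
#' `defect = NULL` all weights are exactly 1.
#'
#' @param grid A parametric `surface_grid`.
#' @param defect A [defect_spec()] or `NULL`.
#' @return Numeric vector of per-rectangle weights.
#' @export
ideal_surface_weights <- function(grid, defect = NULL) {
  stopifnot(inherits(grid, "surface_grid"))
  w <- rep(1, nrow(grid$data))
  if (!is.null(defect)) {
    w[defect_mask(grid, defect)] <- 1 - defect$severity
  }
  w
}

#' True defect area fraction
#'
#' Fraction of the mid-surface area inside the defect sector (independent of
#' severity). Each rectangle contributes its fractional overlap with the
#' defect, in angle and in meridian arc, so the estimate is free of the
#' cell-quantization bias of the binary membership test used for weights.
#'
#' @param grid A parametric `surface_grid`.
#' @param defect A [defect_spec()] or `NULL` (fraction 0).
#' @return Scalar in `[0, 1]`.
#' @export
defect_area_fraction <- function(grid, defect = NULL) {
  if (is.null(defect)) return(0)
  stopifnot(inherits(grid, "surface_grid"), inherits(defect, "defect_spec"))
  if (!isTRUE(grid$parametric)) {
    abort("defect geometry needs a parametric grid (built by build_lv_surface)",
          "perfvec_invalid_parameter")
  }
  d <- grid$data
  shape <- grid$shape
  phi_max <- acos(-shape$base_truncation_fraction)
  dphi <- phi_max / grid$resolution$n_longitudinal
  tab <- meridian_arc_table(shape$mid_short_radius, shape$mid_long_radius,
                            phi_max)
  band_i <- round(d$phi / dphi - 0.5)           # 0-based band index
  a0 <- arc_at_phi(tab, band_i * dphi)          # cell arc span [a0, a1]
  a1 <- arc_at_phi(tab, (band_i + 1) * dphi)
  if (defect$location == "apical") {
    fs <- pmin(pmax((defect$extent_mm - a0) / (a1 - a0), 0), 1)
    ft <- 1
  } else {
    band <- defect_band(shape, defect)
    fs <- pmin(pmax((pmin(a1, band[2]) - pmax(a0, band[1])) / (a1 - a0), 0), 1)
    dth <- 360 / grid$resolution$n_circumferential
    dd <- abs(((d$theta_deg - defect$theta_center_deg + 180) %% 360) - 180)
    ft <- if (defect$alpha >= 360 - dth / 2) 1 else {
      pmin(pmax((defect$alpha / 2 + dth / 2 - dd) / dth, 0), 1)
    }
  }
  sum(d$area * ft * fs) / sum(d$area)
}

# Pointwise uptake of the phantom: 1 inside the myocardial shell, scaled by
# 1 - severity inside the defect sector, 0 elsewhere. X, Y, Z are arrays of
# cardiac-frame mm coordinates.
uptake_field <- function(X, Y, Z, shape, defect, tab) {
  rs <- shape$mid_short_radius
  rl <- shape$mid_long_radius
  t2 <- shape$wall_thickness / 2
  rho2 <- X^2 + Y^2
  q_endo <- rho2 / (rs - t2)^2 + Z^2 / (rl - t2)^2
  q_epi <- rho2 / (rs + t2)^2 + Z^2 / (rl + t2)^2
  z_base <- -shape$base_truncation_fraction * rl
  u <- array(0, dim = dim(X))
  myo <- q_endo >= 1 & q_epi <= 1 & Z >= z_base
  u[myo] <- 1
  if (!is.null(defect) && defect$severity > 0) {
    phi_max <- acos(-shape$base_truncation_fraction)
    # Meridian position of each point from its normalized (rho, z) angle.
    phi_vox <- atan2(sqrt(rho2) / rs, Z / rl)
    s_vox <- array(arc_at_phi(tab, pmin(pmax(phi_vox, 0), phi_max)),
                   dim = dim(X))
    if (defect$location == "apical") {
      hit <- myo & s_vox <= defect$extent_mm
    } else {
      band <- defect_band(shape, defect)
      th_vox <- (atan2(Y, X) * 180 / pi) %% 360
      hit <- myo & in_sector(th_vox, defect) &
        s_vox >= band[1] & s_vox <= band[2]
    }
    u[hit] <- 1 - defect$severity
  }
  u
}

#' Rasterize the ventricle into a voxel volume
#'
#' Uptake is 1 between the endocardial and epicardial ellipsoids (mid surface
#' shrunk/grown by half the wall thickness on each semi-axis) on the apical
#' side of the basal plane, scaled by `1 - severity` inside the defect sector,
#' and 0 elsewhere. Each voxel receives the mean uptake over
#' `acq$supersample^3` sub-voxel points, so boundary voxels carry fractional
#' (partial-volume) values; `supersample = 1` gives binary voxel-center
#' membership. No blur or noise is applied here.
#'
#' @param shape An [lv_shape()] (cavity-volume constraint honored).
#' @param defect A [defect_spec()] or `NULL`.
#' @param acq An [acquisition_spec()]; controls voxel size, field of view and
#'   rasterizer antialiasing.
#' @return A [voxel_volume()] centered on the ellipsoid center.
#' @export
render_volume <- function(shape = lv_shape(), defect = NULL,
                          acq = acquisition_spec()) {
  stopifnot(inherits(shape, "lv_shape"), inherits(acq, "acquisition_spec"))
  if (!is.null(defect)) stopifnot(inherits(defect, "defect_spec"))
  shape <- resolve_shape(shape)
  rs <- shape$mid_short_radius
  rl <- shape$mid_long_radius
  t2 <- shape$wall_thickness / 2
  v <- acq$voxel_size_mm
  need <- c(rs + t2, rs + t2, rl + t2) + acq$padding_mm
  if (is.null(acq$matrix)) {
    n <- 2L * as.integer(ceiling(need / v)) + 1L
  } else {
    n <- acq$matrix
    if (any((n - 1) * v / 2 < c(rs + t2, rs + t2, rl + t2))) {
      abort("voxel grid too small to contain the ventricle",
            "perfvec_field_of_view")
    }
  }
  # Voxel centers symmetric about the ellipsoid center (origin of the frame).
  coords <- lapply(n, function(ni) (seq_len(ni) - (ni + 1) / 2) * v)
  X <- array(coords[[1]], dim = n)
  Y <- array(rep(coords[[2]], each = n[1]), dim = n)
  Z <- array(rep(coords[[3]], each = n[1] * n[2]), dim = n)
  tab <- meridian_arc_table(rs, rl, acos(-shape$base_truncation_fraction))

  ss <- acq$supersample
  if (ss == 1L) {
    vol <- uptake_field(X, Y, Z, shape, defect, tab)
  } else {
    # Symmetric sub-voxel offsets, e.g. (-v/4, +v/4) for supersample 2.
    off <- ((seq_len(ss) - 0.5) / ss - 0.5) * v
    vol <- array(0, dim = n)
    for (ox in off) for (oy in off) for (oz in off) {
      vol <- vol + uptake_field(X + ox, Y + oy, Z + oz, shape, defect, tab)
    }
    vol <- vol / ss^3
  }
  voxel_volume(vol, spacing = v,
               origin = c(coords[[1]][1], coords[[2]][1], coords[[3]][1]))
}

#' Isotropic Gaussian post-filter
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` mm,
#' converted to voxels per axis. The discrete kernel is sampled at voxel
#' offsets out to 4 sigma and normalized to unit sum; boundaries are
#' zero-padded, so total counts are conserved exactly for activity further
#' than the kernel radius from the volume edge.
#'
#' @param vol A [voxel_volume()].
#' @param fwhm_mm Full width at half maximum, mm (>= 0; 0 returns the input).
#' @return The blurred [voxel_volume()].
#' @export
apply_gaussian_blur <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm < 0) {
    abort("`fwhm_mm` must be a single non-negative number",
          "perfvec_invalid_parameter")
  }
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- vol$data
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / vol$spacing[axis]
    r <- as.integer(ceiling(4 * sigma_vox))
    k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
    k <- k / sum(k)
    out <- conv_axis(out, k, axis)
  }
  voxel_volume(out, spacing = vol$spacing, origin = vol$origin)
}

# 1-D convolution along one axis of a 3-D array, zero-padded, via a banded
# matrix product.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    j <- seq_len(n)
    i <- j + off
    ok <- i >= 1L & i <= n
    K[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  p <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, p), nrow = n)
  res <- array(K %*% m, dim = d[p])
  aperm(res, order(p))
}

#' Add Poisson counting noise
#'
#' Rescales the volume so its hottest voxel has expectation `counts_scale`,
#' replaces each voxel by an independent Poisson draw with that mean, and
#' returns the integer-count volume. The same seed gives identical output; the
#' caller's RNG state is untouched.
#'
#' @param vol A non-negative [voxel_volume()].
#' @param counts_scale Expected counts in the hottest voxel (> 0).
#' @param seed Integer seed.
#' @return A [voxel_volume()] of integer counts.
#' @export
add_poisson_noise <- function(vol, counts_scale, seed) {
  stopifnot(inherits(vol, "voxel_volume"))
  check_number(counts_scale, "counts_scale", lower = 0, strict_lower = TRUE)
  if (any(vol$data < 0)) {
    abort("volume must be non-negative before adding Poisson noise",
          "perfvec_invalid_parameter")
  }
  mx <- max(vol$data)
  if (mx == 0) {
    return(voxel_volume(array(0, dim(vol$data)), vol$spacing, vol$origin))
  }
  lambda <- vol$data * (counts_scale / mx)
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  voxel_volume(array(as.numeric(counts), dim(vol$data)), vol$spacing,
               vol$origin)
}

#' Simulate one SPECT-like study
#'
#' Composes the phantom pipeline: rasterize, blur with the acquisition's
#' post-filter, optionally add Poisson noise; and builds the matching
#' ground-truth surface grid (weights not yet sampled).
#'
#' @param shape An [lv_shape()].
#' @param defect A [defect_spec()] or `NULL`.
#' @param acq An [acquisition_spec()].
#' @param res A [grid_resolution()] for the returned surface.
#' @param noise Add Poisson noise with `acq$counts_scale` and `acq$seed`?
#' @return List with elements `volume` (degraded [voxel_volume()]) and
#'   `surface` (the `surface_grid`, unit weights).
#' @export
simulate_study <- function(shape = lv_shape(), defect = NULL,
                           acq = acquisition_spec(), res = grid_resolution(),
                           noise = TRUE) {
  shape <- resolve_shape(shape)
  vol <- render_volume(shape, defect, acq)
  vol <- apply_gaussian_blur(vol, acq$blur_fwhm_mm)
  if (noise) vol <- add_poisson_noise(vol, acq$counts_scale, acq$seed)
  list(volume = vol, surface = build_lv_surface(shape, res))
}
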