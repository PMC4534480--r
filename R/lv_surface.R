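# Parametric mid-myocardial surface: a truncated prolate ellipsoid sampled as a
# grid of rectangles, each carrying a center position, an area and an intensity
# weight. The surface is the carrier of every centroid computation in the
# package.

#' Left-ventricular shape specification
#'
#' Describes the mid-myocardial surface as a prolate ellipsoid of revolution
#' (equal short semi-axes in x and y, long semi-axis along z) truncated by a
#' basal plane. The apex pole is included; the base is open. When
#' `target_cavity_volume` is given, both radii are rescaled by a common factor
#' (wall thickness held fixed) so that the endocardial cavity volume matches it;
#' the default reproduces an end-diastolic cavity volume of 148 mL, a typical
#' standard-male ventricle.
#'
#' @param mid_short_radius Short (equatorial) semi-axis of the mid surface, mm.
#' @param mid_long_radius Long (apex-directed) semi-axis, mm.
#' @param base_truncation_fraction Fraction of the long radius, on the basal
#'   side of center, at which the basal plane cuts the ellipsoid. Must lie in
#'   (0, 1].
#' @param wall_thickness Myocardial wall thickness, mm. Used by the voxel
#'   rasterizer ([render_volume()]) and by the cavity-volume solver; the mid
#'   surface itself is infinitely thin.
#' @param target_cavity_volume Endocardial cavity volume to solve for, mL, or
#'   `NULL` to use the radii as given.
#' @return An object of class `lv_shape`.
#' @seealso [build_lv_surface()], [cavity_volume()], [solve_cavity_volume()]
#' @export
lv_shape <- function(mid_short_radius = 25, mid_long_radius = 45,
                     base_truncation_fraction = 0.35, wall_thickness = 10,
                     target_cavity_volume = 148) {
  check_number(mid_short_radius, "mid_short_radius", lower = 0,
               strict_lower = TRUE, class = "perfvec_invalid_shape")
  check_number(mid_long_radius, "mid_long_radius", lower = 0,
               strict_lower = TRUE, class = "perfvec_invalid_shape")
  check_number(wall_thickness, "wall_thickness", lower = 0,
               strict_lower = TRUE, class = "perfvec_invalid_shape")
  check_number(base_truncation_fraction, "base_truncation_fraction",
               lower = 0, upper = 1, strict_lower = TRUE,
               class = "perfvec_invalid_shape")
  if (!is.null(target_cavity_volume)) {
    check_number(target_cavity_volume, "target_cavity_volume", lower = 0,
                 strict_lower = TRUE, class = "perfvec_invalid_shape")
  }
  structure(list(mid_short_radius = as.numeric(mid_short_radius),
                 mid_long_radius = as.numeric(mid_long_radius),
                 base_truncation_fraction = as.numeric(base_truncation_fraction),
                 wall_thickness = as.numeric(wall_thickness),
                 target_cavity_volume = target_cavity_volume),
            class = "lv_shape")
}

#' Surface grid resolution
#'
#' @param n_longitudinal Number of bands from apex pole to base (>= 4).
#' @param n_circumferential Number of sectors around the long axis (>= 8,
#'   even). Evenness guarantees the exact mirror pairing of rectangles about
#'   the x-z and y-z planes.
#' @return An object of class `grid_resolution`.
#' @export
grid_resolution <- function(n_longitudinal = 32, n_circumferential = 64) {
  check_number(n_longitudinal, "n_longitudinal", lower = 4)
  check_number(n_circumferential, "n_circumferential", lower = 8)
  if (n_circumferential %% 2 != 0) {
    abort("`n_circumferential` must be even (mirror symmetry of the grid)",
          "perfvec_invalid_parameter")
  }
  structure(list(n_longitudinal = as.integer(n_longitudinal),
                 n_circumferential = as.integer(n_circumferential)),
            class = "grid_resolution")
}

#' Cardiac coordinate frame
#'
#' Axis conventions used throughout: +x septal-to-lateral, +y
#' anterior-to-inferior, +z basal-to-apical (right-handed: x cross y = z).
#' With these signs the perfusion vector, which points away from a defect,
#' acquires a positive y component for an anterior defect and a negative x
#' component for a lateral defect. The circumferential angle theta is measured
#' in the x-y plane from +x (lateral) toward +y (inferior), so inferior sits at
#' 90 deg, septal at 180 deg and anterior at 270 deg.
#'
#' @param origin Reference point of the frame, mm.
#' @return An object of class `cardiac_frame`.
#' @export
cardiac_frame <- function(origin = c(0, 0, 0)) {
  structure(list(x = "septal-lateral (+x lateral)",
                 y = "anterior-inferior (+y inferior)",
                 z = "basal-apical (+z apical)",
                 handedness = "right",
                 origin = as.numeric(origin)),
            class = "cardiac_frame")
}

# Meridian metric of the ellipse (rs sin(phi), rl cos(phi)): arc length per
# unit polar angle phi (phi = 0 at the apex pole).
meridian_metric <- function(phi, rs, rl) {
  sqrt(rl^2 * sin(phi)^2 + rs^2 * cos(phi)^2)
}

# Dense lookup table of meridian arc length s(phi) from the apex pole.
meridian_arc_table <- function(rs, rl, phi_max, n = 4097L) {
  phi <- seq(0, phi_max, length.out = n)
  h <- meridian_metric(phi, rs, rl)
  s <- c(0, cumsum((h[-1L] + h[-n]) / 2 * diff(phi)))
  list(phi = phi, s = s, total = s[n])
}

arc_at_phi <- function(tab, phi) {
  stats::approx(tab$phi, tab$s, xout = phi, rule = 2)$y
}

phi_at_arc <- function(tab, s) {
  stats::approx(tab$s, tab$phi, xout = s, rule = 2)$y
}

#' Endocardial cavity volume of a shape
#'
#' Closed-form volume of the endocardial ellipsoid (mid surface shrunk by half
#' the wall thickness on each semi-axis) truncated at the basal plane of the
#' mid surface.
#'
#' @param shape An [lv_shape()].
#' @return Cavity volume in mL.
#' @export
cavity_volume <- function(shape) {
  stopifnot(inherits(shape, "lv_shape"))
  a <- shape$mid_short_radius - shape$wall_thickness / 2
  cc <- shape$mid_long_radius - shape$wall_thickness / 2
  if (a <= 0 || cc <= 0) {
    abort("wall thickness exceeds a mid-surface radius: no endocardial cavity",
          "perfvec_invalid_shape")
  }
  z0 <- max(-shape$base_truncation_fraction * shape$mid_long_radius, -cc)
  v_mm3 <- pi * a^2 * ((cc - z0) - (cc^3 - z0^3) / (3 * cc^2))
  v_mm3 / 1000
}

#' Rescale a shape to a target cavity volume
#'
#' Finds the common scale factor on both mid-surface radii (wall thickness and
#' truncation fraction fixed) whose endocardial cavity volume equals
#' `target` mL.
#'
#' @param shape An [lv_shape()].
#' @param target Target cavity volume in mL; defaults to the shape's own
#'   `target_cavity_volume`.
#' @return The rescaled `lv_shape`, with `target_cavity_volume` preserved.
#' @export
solve_cavity_volume <- function(shape, target = shape$target_cavity_volume) {
  stopifnot(inherits(shape, "lv_shape"))
  if (is.null(target)) return(shape)
  check_number(target, "target", lower = 0, strict_lower = TRUE,
               class = "perfvec_invalid_shape")
  scaled <- function(s) {
    sh <- shape
    sh$mid_short_radius <- shape$mid_short_radius * s
    sh$mid_long_radius <- shape$mid_long_radius * s
    sh
  }
  lo <- (shape$wall_thickness / 2) /
    min(shape$mid_short_radius, shape$mid_long_radius) * (1 + 1e-6) + 1e-9
  hi <- max(10, lo * 2)
  root <- stats::uniroot(function(s) cavity_volume(scaled(s)) - target,
                         interval = c(lo, hi), tol = 1e-12)
  out <- scaled(root$root)
  out$target_cavity_volume <- target
  out
}

# Apply the cavity-volume constraint if present. Idempotent.
resolve_shape <- function(shape) {
  if (is.null(shape$target_cavity_volume)) return(shape)
  solve_cavity_volume(shape)
}

#' Build the mid-myocardial surface grid
#'
#' Samples the truncated prolate ellipsoid as `n_longitudinal` bands of polar
#' angle (apex pole first) times `n_circumferential` sectors, one rectangle per
#' cell. Each rectangle carries its center position in the cardiac frame, its
#' area (local metric product: circumferential arc spacing times meridional arc
#' spacing at the cell center), a weight initialized to 1, and the intrinsic
#' surface coordinates (circumferential angle, polar angle, meridian arc length
#' from the apex) plus the analytic outward unit normal used by the intensity
#' sampler.
#'
#' @param shape An [lv_shape()]; if it carries a `target_cavity_volume` the
#'   radii are first rescaled to honor it.
#' @param res A [grid_resolution()].
#' @return An object of class `surface_grid`: a list with elements `data` (one
#'   row per rectangle: `index`, `x`, `y`, `z`, `area`, `weight`, `theta_deg`,
#'   `phi`, `arc_mm`, `nx`, `ny`, `nz`), `shape` (the resolved shape),
#'   `resolution`, `frame`, `arc_total` (total meridian arc apex to base, mm)
#'   and `parametric` (`TRUE` for grids built here, `FALSE` for grids read from
#'   CSV, which lack the intrinsic coordinates).
#' @examples
#' g <- build_lv_surface()
#' nrow(g$data)                  # 32 x 64 rectangles
#' anatomical_centroid(g)        # on the long axis: x = y = 0
#' @export
build_lv_surface <- function(shape = lv_shape(), res = grid_resolution()) {
  stopifnot(inherits(shape, "lv_shape"), inherits(res, "grid_resolution"))
  shape <- resolve_shape(shape)
  rs <- shape$mid_short_radius
  rl <- shape$mid_long_radius
  phi_max <- acos(-shape$base_truncation_fraction)
  np <- res$n_longitudinal
  nc <- res$n_circumferential
  dphi <- phi_max / np
  dth <- 2 * pi / nc
  phi_c <- (seq_len(np) - 0.5) * dphi
  th_c <- (seq_len(nc) - 0.5) * dth
  tab <- meridian_arc_table(rs, rl, phi_max)

  phi <- rep(phi_c, each = nc)
  th <- rep(th_c, times = np)
  sp <- sin(phi)
  cp <- cos(phi)
  x <- rs * sp * cos(th)
  y <- rs * sp * sin(th)
  z <- rl * cp
  h <- meridian_metric(phi, rs, rl)
  area <- (rs * sp * dth) * (h * dphi)
  # Outward normal of the ellipsoid, analytic from the implicit gradient.
  gx <- sp * cos(th) / rs
  gy <- sp * sin(th) / rs
  gz <- cp / rl
  gn <- sqrt(gx^2 + gy^2 + gz^2)

  data <- data.frame(index = seq_len(np * nc) - 1L,
                     x = x, y = y, z = z,
                     area = area, weight = 1,
                     theta_deg = (th * 180 / pi) %% 360,
                     phi = phi,
                     arc_mm = arc_at_phi(tab, phi),
                     nx = gx / gn, ny = gy / gn, nz = gz / gn)
  structure(list(data = data, shape = shape, resolution = res,
                 frame = cardiac_frame(), arc_total = tab$total,
                 parametric = TRUE),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  d <- x$data
  cat(sprintf("<surface_grid> %d rectangles", nrow(d)))
  if (isTRUE(x$parametric)) {
    cat(sprintf(" (%d bands x %d sectors)", x$resolution$n_longitudinal,
                x$resolution$n_circumferential))
  }
  cat(sprintf("\n  total area %.1f mm^2, meridian arc %s mm\n",
              sum(d$area),
              if (is.null(x$arc_total)) "?" else sprintf("%.1f", x$arc_total)))
  invisible(x)
}

#' Rigidly transform a surface grid
#'
#' Maps rectangle centers (and normals, when present) by a rotation followed by
#' a translation. Areas, weights and the intrinsic surface coordinates are
#' unchanged; rigid motions preserve them.
#'
#' @param grid A `surface_grid`.
#' @param rotation 3x3 orthonormal matrix (checked to 1e-8).
#' @param translation Length-3 translation, mm.
#' @return The transformed `surface_grid`.
#' @export
transform_grid <- function(grid, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(grid, "surface_grid"))
  rotation <- as.matrix(rotation)
  if (!is.numeric(rotation) || !identical(dim(rotation), c(3L, 3L)) ||
      any(!is.finite(rotation))) {
    abort("`rotation` must be a finite 3x3 matrix", "perfvec_invalid_transform")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("`rotation` is not orthonormal (within 1e-8)",
          "perfvec_invalid_transform")
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    abort("`translation` must be a finite length-3 vector",
          "perfvec_invalid_transform")
  }
  d <- grid$data
  xyz <- cbind(d$x, d$y, d$z) %*% t(rotation)
  d$x <- xyz[, 1L] + translation[1L]
  d$y <- xyz[, 2L] + translation[2L]
  d$z <- xyz[, 3L] + translation[3L]
  if (all(c("nx", "ny", "nz") %in% names(d))) {
    nrm <- cbind(d$nx, d$ny, d$nz) %*% t(rotation)
    d$nx <- nrm[, 1L]
    d$ny <- nrm[, 2L]
    d$nz <- nrm[, 3L]
  }
  grid$data <- d
  grid$frame$origin <- as.numeric(rotation %*% grid$frame$origin + translation)
  grid
}

#' Validate a surface grid
#'
#' Reports (never raises) violations of the grid invariants: positive finite
#' areas, finite center positions, finite non-negative weights.
#'
#' @param grid A `surface_grid`.
#' @return A data frame with columns `index` and `rule`, one row per violation;
#'   zero rows when the grid is valid.
#' @export
validate_grid <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  d <- grid$data
  idx <- integer(0)
  rule <- character(0)
  add <- function(which, what) {
    idx <<- c(idx, d$index[which])
    rule <<- c(rule, rep(what, length(which)))
  }
  add(which(!is.finite(d$area) | d$area <= 0), "non-positive area")
  add(which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z)),
      "non-finite position")
  add(which(!is.finite(d$weight)), "non-finite weight")
  add(which(is.finite(d$weight) & d$weight < 0), "negative weight")
  data.frame(index = idx, rule = rule, stringsAsFactors = FALSE)
}

#' Replace the weights of a surface grid
#'
#' @param grid A `surface_grid`.
#' @param weights Numeric vector, one finite non-negative value per rectangle.
#' @return The grid with its `weight` column replaced.
#' @export
set_weights <- function(grid, weights) {
  stopifnot(inherits(grid, "surface_grid"))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(grid$data)) {
    abort(sprintf("expected %d weights, got %d", nrow(grid$data),
                  length(weights)), "perfvec_shape_error")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("weights must be finite and non-negative", "perfvec_invalid_parameter")
  }
  grid$data$weight <- weights
  grid
}

# Meridian arc position of the short-axis plane through the anatomical
# (area-weighted) centroid of a shape's mid surface. Quadrature in phi.
centroid_plane_arc <- function(shape, n = 2048L) {
  shape <- resolve_shape(shape)
  rs <- shape$mid_short_radius
  rl <- shape$mid_long_radius
  phi_max <- acos(-shape$base_truncation_fraction)
  phi <- seq(0, phi_max, length.out = n)
  w <- rs * sin(phi) * meridian_metric(phi, rs, rl)   # area density per dphi
  zbar <- sum(w * rl * cos(phi)) / sum(w)
  phi_bar <- acos(min(1, max(-1, zbar / rl)))
  tab <- meridian_arc_table(rs, rl, phi_max)
  list(arc = arc_at_phi(tab, phi_bar), total = tab$total, tab = tab)
}
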