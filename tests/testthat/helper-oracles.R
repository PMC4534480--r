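# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, exhaustive enumeration, quadrature.

# Brute-force triple-sum weighted centroid over a data frame of rectangles.
oracle_centroid <- function(df, w) {
  sx <- sy <- sz <- sw <- 0
  for (i in seq_len(nrow(df))) {
    aw <- df$area[i] * w[i]
    sx <- sx + df$x[i] * aw
    sy <- sy + df$y[i] * aw
    sz <- sz + df$z[i] * aw
    sw <- sw + aw
  }
  c(sx, sy, sz) / sw
}

# Random small surface_grid-shaped object with positive areas and weights.
random_grid <- function(n) {
  data <- data.frame(index = seq_len(n) - 1L,
                     x = runif(n, -50, 50), y = runif(n, -50, 50),
                     z = runif(n, -50, 50),
                     area = runif(n, 0.1, 5), weight = runif(n, 0.01, 3))
  structure(list(data = data, frame = cardiac_frame(), parametric = FALSE),
            class = "surface_grid")
}

# Exhaustive-enumeration two-sided Mann-Whitney p value (tie-free samples).
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(ix) sum(seq_len(na + nb)[ix]) -
                   na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# Quadrature area of the truncated prolate ellipsoid mid surface.
oracle_surface_area <- function(shape) {
  shape <- solve_cavity_volume(shape)
  rs <- shape$mid_short_radius
  rl <- shape$mid_long_radius
  f <- function(phi) 2 * pi * rs * sin(phi) *
    sqrt(rl^2 * sin(phi)^2 + rs^2 * cos(phi)^2)
  integrate(f, 0, acos(-shape$base_truncation_fraction),
            rel.tol = 1e-10)$value
}

# Numerical-integration endocardial cavity volume (mL): stack of elliptical
# cross sections above the basal plane.
oracle_cavity_volume <- function(shape) {
  shape_r <- solve_cavity_volume(shape)
  a <- shape_r$mid_short_radius - shape_r$wall_thickness / 2
  cc <- shape_r$mid_long_radius - shape_r$wall_thickness / 2
  z0 <- max(-shape_r$base_truncation_fraction * shape_r$mid_long_radius, -cc)
  f <- function(z) pi * a^2 * (1 - z^2 / cc^2)
  integrate(f, z0, cc, rel.tol = 1e-10)$value / 1000
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Shared default phantom pieces (built once per test file load).
default_shape <- solve_cavity_volume(lv_shape())
default_grid <- build_lv_surface(default_shape)

noiseless_volume <- function(defect = NULL, acq = acquisition_spec()) {
  apply_gaussian_blur(render_volume(default_shape, defect, acq),
                      acq$blur_fwhm_mm)
}

noiseless_vector <- function(defect = NULL, acq = acquisition_spec()) {
  compute_perfusion_vector(default_grid,
                           sample_weights(noiseless_volume(defect, acq),
                                          default_grid))
}
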