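test_that("ideal surface weights implement the sector predicate", {
  g <- default_grid
  expect_equal(ideal_surface_weights(g, NULL), rep(1, nrow(g$data)))

  # full-circumference, full-length, full-severity defect wipes all weight
  full <- defect_spec("anterior", alpha = 360, extent_mm = 1000, severity = 1,
                      placement = "apex")
  w <- ideal_surface_weights(g, full)
  expect_true(all(w == 0))
  expect_error(compute_perfusion_vector(g, w),
               class = "perfvec_degenerate_weights")

  # anterior 90 deg, severity 0.5: anterior center reduced, inferior wall not
  half <- defect_spec("anterior", alpha = 90, severity = 0.5)
  w2 <- ideal_surface_weights(g, half)
  d <- g$data
  band <- perfvec:::defect_band(g$shape, half)
  mid_arc <- mean(band)
  at_center <- which.min(abs(d$theta_deg - 270) + abs(d$arc_mm - mid_arc))
  at_inferior <- which.min(abs(d$theta_deg - 90) + abs(d$arc_mm - mid_arc))
  expect_equal(w2[at_center], 0.5)
  expect_equal(w2[at_inferior], 1)
})

test_that("defect area fraction matches the analytic sector fraction", {
  g <- default_grid
  sh <- g$shape
  # independent fine-grid area density along the meridian
  phi_max <- acos(-sh$base_truncation_fraction)
  phi_f <- seq(0, phi_max, length.out = 20001)
  h_f <- sqrt(sh$mid_long_radius^2 * sin(phi_f)^2 +
                sh$mid_short_radius^2 * cos(phi_f)^2)
  arc_f <- c(0, cumsum((h_f[-1] + h_f[-length(h_f)]) / 2 * diff(phi_f)))
  dens <- sh$mid_short_radius * sin(phi_f) * h_f
  for (alpha in c(30, 70, 120)) {
    def <- defect_spec("anterior", alpha = alpha)
    band <- perfvec:::defect_band(sh, def)
    long_frac <- sum(dens[arc_f >= band[1] & arc_f <= band[2]]) / sum(dens)
    expect_equal(defect_area_fraction(g, def), alpha / 360 * long_frac,
                 tolerance = 0.02)
  }
})

test_that("rasterized volume matches a brute-force membership scan", {
  acq <- acquisition_spec(voxel_size_mm = 6, supersample = 1)
  vol <- render_volume(default_shape, NULL, acq)
  sh <- default_shape
  t2 <- sh$wall_thickness / 2
  n_oracle <- 0L
  d <- dim(vol$data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    q_en <- (p[1]^2 + p[2]^2) / (sh$mid_short_radius - t2)^2 +
      p[3]^2 / (sh$mid_long_radius - t2)^2
    q_ep <- (p[1]^2 + p[2]^2) / (sh$mid_short_radius + t2)^2 +
      p[3]^2 / (sh$mid_long_radius + t2)^2
    if (q_en >= 1 && q_ep <= 1 &&
        p[3] >= -sh$base_truncation_fraction * sh$mid_long_radius) {
      n_oracle <- n_oracle + 1L
    }
  }
  expect_equal(sum(vol$data > 0), n_oracle)
})

test_that("severity-1 defect voxels are exactly zero and uptake integral converges", {
  def <- defect_spec("anterior", alpha = 60, severity = 1)
  acq1 <- acquisition_spec(voxel_size_mm = 4.8, supersample = 1)
  vol1 <- render_volume(default_shape, def, acq1)
  # binary rasterization: voxels are either 0 or full uptake, and the defect
  # sector removes support relative to the defect-free render
  vol0 <- render_volume(default_shape, NULL, acq1)
  expect_true(all(vol1$data %in% c(0, 1)))
  expect_gt(sum(vol0$data) - sum(vol1$data), 0)

  tot1 <- sum(vol1$data) * prod(vol1$spacing)
  acq2 <- acquisition_spec(voxel_size_mm = 2.4, supersample = 1)
  vol2 <- render_volume(default_shape, def, acq2)
  tot2 <- sum(vol2$data) * prod(vol2$spacing)
  expect_equal(tot1, tot2, tolerance = 0.02)

  expect_error(render_volume(default_shape, NULL,
                             acquisition_spec(matrix = 8)),
               class = "perfvec_field_of_view")
})

test_that("Gaussian blur matches the closed-form kernel and conserves counts", {
  acq <- acquisition_spec()
  n <- 21L
  arr <- array(0, c(n, n, n))
  arr[11, 11, 11] <- 1
  vol <- voxel_volume(arr, spacing = 4.8, origin = c(0, 0, 0))

  expect_identical(apply_gaussian_blur(vol, 0)$data, vol$data)

  out <- apply_gaussian_blur(vol, 7)$data
  sigma_vox <- 7 / (2 * sqrt(2 * log(2))) / 4.8
  r <- ceiling(4 * sigma_vox)
  k1 <- dnorm(seq(-r, r), sd = sigma_vox)
  k1 <- k1 / sum(k1)
  idx <- seq(11 - r, 11 + r)
  want <- outer(outer(k1, k1), k1)
  got <- out[idx, idx, idx]
  expect_lt(max(abs(got - want)) / max(want), 1e-6)
  expect_equal(sum(out), 1, tolerance = 1e-3)

  blurred <- apply_gaussian_blur(noiseless_volume(), 7)
  expect_equal(sum(blurred$data) / sum(noiseless_volume()$data), 1,
               tolerance = 1e-3)
  expect_error(apply_gaussian_blur(vol, -1),
               class = "perfvec_invalid_parameter")
})

test_that("Poisson noise is seeded, integer and moment-correct", {
  zero <- voxel_volume(array(0, c(4, 4, 4)), 4.8)
  expect_true(all(add_poisson_noise(zero, 100, 1)$data == 0))

  vol <- noiseless_volume()
  n1 <- add_poisson_noise(vol, 500, 42)
  n2 <- add_poisson_noise(vol, 500, 42)
  expect_identical(n1$data, n2$data)
  expect_true(all(n1$data == round(n1$data)))
  expect_false(identical(add_poisson_noise(vol, 500, 43)$data, n1$data))

  unif <- voxel_volume(array(1, c(50, 50, 40)), 1)  # 1e5 voxels
  noisy <- add_poisson_noise(unif, 1e4, 7)
  expect_equal(mean(noisy$data), 1e4, tolerance = 0.01)
  expect_gt(var(as.numeric(noisy$data)) / mean(noisy$data), 0.97)
  expect_lt(var(as.numeric(noisy$data)) / mean(noisy$data), 1.03)
  expect_error(add_poisson_noise(unif, 0, 1),
               class = "perfvec_invalid_parameter")
})

test_that("simulate_study composes the pipeline deterministically", {
  s1 <- simulate_study(acq = acquisition_spec(seed = 9L))
  s2 <- simulate_study(acq = acquisition_spec(seed = 9L))
  expect_identical(s1$volume$data, s2$volume$data)

  w <- sample_weights(s1$volume, s1$surface)
  mid <- s1$surface$data$arc_mm > s1$surface$arc_total / 3 &
    s1$surface$data$arc_mm < 2 * s1$surface$arc_total / 3
  expect_lt(sd(w[mid]) / mean(w[mid]), 0.05)

  p70 <- noiseless_vector(defect_spec("anterior", alpha = 70))
  p10 <- noiseless_vector(defect_spec("anterior", alpha = 10))
  expect_gt(abs(p70$P[["y"]]), abs(p10$P[["y"]]))
})

test_that("noisy normal magnitudes stay below the noiseless 30-degree defect", {
  vol <- noiseless_volume()
  mags <- vapply(1:100, function(s) {
    nv <- add_poisson_noise(vol, 500, s)
    compute_perfusion_vector(default_grid,
                             sample_weights(nv, default_grid))$magnitude
  }, numeric(1))
  p30 <- noiseless_vector(defect_spec("anterior", alpha = 30))$magnitude
  expect_lt(median(mags), p30)
  expect_lt(max(mags), p30)   # zero distribution overlap
})

test_that("noiseless perfusion vector is stable under voxel-size halving", {
  def <- defect_spec("anterior", alpha = 50)
  p1 <- noiseless_vector(def, acquisition_spec(voxel_size_mm = 4.8))
  p2 <- noiseless_vector(def, acquisition_spec(voxel_size_mm = 2.4))
  expect_lt(sqrt(sum((p1$P - p2$P)^2)), 0.2)
})

test_that("synthetic cohorts are reproducible and carry the expected structure", {
  spec <- cohort_spec(n_normal = 10, n_per_defect_group = 0, seed = 3)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 10L)
  expect_true(all(co$group == "normal"))
  expect_true(all(co$true_extent_fraction == 0))

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(spec), f1)
  write_cohort_csv(generate_cohort(spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(generate_cohort(cohort_spec(n_normal = 0,
                                           n_per_defect_group = 0)),
               class = "perfvec_empty_table")

  small <- generate_cohort(cohort_spec(n_normal = 4, n_per_defect_group = 2,
                                       seed = 5))
  expect_equal(nrow(small), 12L)
  expect_setequal(unique(small$group),
                  c("normal", "apical", "inferior", "anterior", "lateral"))
  expect_true(all(small$condition[small$group == "normal"] == "normal"))
  expect_true(all(small$true_extent_fraction[small$group != "normal"] > 0))
  expect_true(all(small$vec_diff_mag >= 0))
})
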