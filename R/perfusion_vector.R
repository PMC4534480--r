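# Core statistic: area- and intensity-weighted centroids of the mid-myocardial
# surface and their difference, the perfusion vector.

#' Weighted centroid of a surface grid
#'
#' Computes the intensity-weighted center of gravity
#' \deqn{C = \left(\frac{\sum x_i A_i W_i}{\sum A_i W_i},
#'                \frac{\sum y_i A_i W_i}{\sum A_i W_i},
#'                \frac{\sum z_i A_i W_i}{\sum A_i W_i}\right)}
#' over the rectangles of the grid. With all weights equal to 1 this reduces to
#' the geometric (anatomical) centroid.
#'
#' @param grid A `surface_grid`.
#' @param weights Per-rectangle intensities; defaults to the grid's own
#'   `weight` column. Must be finite, non-negative, with `sum(A * W) > 0`.
#' @param kind Label stored on the result, `"perfusion"` or `"anatomical"`.
#' @return An object of class `centroid`: list with `point` (named x/y/z, mm)
#'   and `kind`.
#' @export
weighted_centroid <- function(grid, weights = NULL, kind = "perfusion") {
  stopifnot(inherits(grid, "surface_grid"))
  d <- grid$data
  if (nrow(d) == 0L) {
    abort("grid has no rectangles", "perfvec_degenerate_grid")
  }
  if (is.null(weights)) weights <- d$weight
  weights <- as.numeric(weights)
  if (length(weights) != nrow(d)) {
    abort(sprintf("expected %d weights, got %d", nrow(d), length(weights)),
          "perfvec_shape_error")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("weights must be finite and non-negative", "perfvec_invalid_parameter")
  }
  aw <- d$area * weights
  tot <- sum(aw)
  if (!is.finite(tot) || tot <= 0) {
    abort("sum(area * weight) is not positive: degenerate weights",
          "perfvec_degenerate_weights")
  }
  point <- c(x = sum(d$x * aw), y = sum(d$y * aw), z = sum(d$z * aw)) / tot
  structure(list(point = point, kind = kind), class = "centroid")
}

#' Anatomical centroid of a surface grid
#'
#' The geometric centroid: [weighted_centroid()] with unit weights.
#'
#' @param grid A `surface_grid`.
#' @return A `centroid` of kind `"anatomical"`.
#' @export
anatomical_centroid <- function(grid) {
  weighted_centroid(grid, weights = rep(1, nrow(grid$data)),
                    kind = "anatomical")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("<centroid:%s> (%.4f, %.4f, %.4f) mm\n", x$kind,
              x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Compute the perfusion vector of a weighted surface
#'
#' The perfusion vector is `P = C_P - C_A`, the displacement of the
#' perfusion-weighted center of gravity `C_P` from the anatomical centroid
#' `C_A`. Uniform perfusion gives `P = 0`; a localized defect pulls `C_P` away
#' from the defect, so `P` points away from it, with a magnitude growing with
#' defect severity and extent.
#'
#' @param grid A `surface_grid` whose `weight` column holds measured
#'   intensities (or `weights` given explicitly).
#' @param weights Optional per-rectangle intensities overriding the grid's.
#' @param phase `"stress"`, `"rest"` or `"unspecified"`; carried through to
#'   stress/rest difference metrics.
#' @return An object of class `perfusion_result`: list with centroids `C_A` and
#'   `C_P`, the vector `P` (named x/y/z components, mm), its Euclidean
#'   `magnitude` (mm), `phase` and the cardiac `frame`.
#' @examples
#' g <- build_lv_surface()
#' compute_perfusion_vector(g)   # uniform weights: zero vector
#' @export
compute_perfusion_vector <- function(grid, weights = NULL,
                                     phase = c("unspecified", "stress", "rest")) {
  phase <- match.arg(phase)
  c_a <- anatomical_centroid(grid)
  c_p <- weighted_centroid(grid, weights = weights, kind = "perfusion")
  p <- c_p$point - c_a$point
  structure(list(C_A = c_a, C_P = c_p, P = p,
                 magnitude = sqrt(sum(p^2)),
                 phase = phase, frame = grid$frame),
            class = "perfusion_result")
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf("<perfusion_result:%s>\n", x$phase))
  cat(sprintf("  C_A (%.3f, %.3f, %.3f) mm\n", x$C_A$point[1], x$C_A$point[2],
              x$C_A$point[3]))
  cat(sprintf("  C_P (%.3f, %.3f, %.3f) mm\n", x$C_P$point[1], x$C_P$point[2],
              x$C_P$point[3]))
  cat(sprintf("  P   (%.3f, %.3f, %.3f) mm, |P| = %.3f mm\n",
              x$P[1], x$P[2], x$P[3], x$magnitude))
  invisible(x)
}

#' Stress/rest difference metrics
#'
#' Two readings of the stress-rest difference: the difference of the vector
#' magnitudes `|P_stress| - |P_rest|` (may be negative; the headline ischemia
#' metric) and the magnitude of the vector difference `|P_stress - P_rest|`
#' (always non-negative).
#'
#' @param stress,rest `perfusion_result` objects computed in the same cardiac
#'   frame.
#' @return An object of class `difference_result`: list with
#'   `magnitude_difference` and `vector_difference_magnitude`, both mm.
#' @export
difference_metrics <- function(stress, rest) {
  stopifnot(inherits(stress, "perfusion_result"),
            inherits(rest, "perfusion_result"))
  if (!identical(stress$frame, rest$frame)) {
    abort("stress and rest results are not in the same cardiac frame",
          "perfvec_frame_error")
  }
  dv <- stress$P - rest$P
  structure(list(magnitude_difference = stress$magnitude - rest$magnitude,
                 vector_difference_magnitude = sqrt(sum(dv^2))),
            class = "difference_result")
}

#' @export
print.difference_result <- function(x, ...) {
  cat(sprintf("<difference_result> |Ps|-|Pr| = %.3f mm, |Ps-Pr| = %.3f mm\n",
              x$magnitude_difference, x$vector_difference_magnitude))
  invisible(x)
}
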