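# Synthetic stress/rest cohort generator: the desk-scale analogue of a
# 40-normal / 80-abnormal patient study. Each synthetic patient runs through
# the full phantom pipeline (render, blur, Poisson noise, normal-profile
# sampling) at stress and rest.

#' Cohort specification
#'
#' Defaults emulate the validation cohort layout: 40 normal studies plus four
#' defect-location groups of 20 (80 abnormal). Abnormal patients draw a defect
#' opening angle, severity and condition; "ischemia" patients have their rest
#' severity reduced to `severity * rest_ratio` (reversible defect), while
#' "infarction" patients keep the same severity at rest (fixed defect).
#'
#' @param n_normal Number of defect-free studies (default 40).
#' @param n_per_defect_group Studies per defect location (default 20).
#' @param locations Defect location groups.
#' @param alpha_range Uniform range of the opening angle, degrees.
#' @param severity_range Uniform range of stress severity.
#' @param extent_mm Apical-basal defect propagation, mm.
#' @param rest_ratio_range Uniform range of the rest/stress severity ratio for
#'   ischemia-like patients.
#' @param prob_ischemia Probability an abnormal patient is ischemia-like
#'   rather than infarct-like.
#' @param shape,res,acq,sampling Phantom and sampling parameters shared by all
#'   studies.
#' @param seed Master seed; every draw (defect parameters and per-study noise
#'   seeds) derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 40, n_per_defect_group = 20,
                        locations = c("apical", "inferior", "anterior",
                                      "lateral"),
                        alpha_range = c(20, 70), severity_range = c(0.5, 1),
                        extent_mm = 60, rest_ratio_range = c(0.1, 0.4),
                        prob_ischemia = 0.5,
                        shape = lv_shape(), res = grid_resolution(),
                        acq = acquisition_spec(), sampling = sampling_spec(),
                        seed = 1L) {
  check_number(n_normal, "n_normal", lower = 0)
  check_number(n_per_defect_group, "n_per_defect_group", lower = 0)
  check_number(prob_ischemia, "prob_ischemia", lower = 0, upper = 1)
  check_number(extent_mm, "extent_mm", lower = 0, strict_lower = TRUE)
  stopifnot(length(alpha_range) == 2L, length(severity_range) == 2L,
            length(rest_ratio_range) == 2L)
  locations <- match.arg(locations, several.ok = TRUE)
  structure(list(n_normal = as.integer(n_normal),
                 n_per_defect_group = as.integer(n_per_defect_group),
                 locations = locations,
                 alpha_range = as.numeric(alpha_range),
                 severity_range = as.numeric(severity_range),
                 extent_mm = as.numeric(extent_mm),
                 rest_ratio_range = as.numeric(rest_ratio_range),
                 prob_ischemia = as.numeric(prob_ischemia),
                 shape = shape, res = res, acq = acq, sampling = sampling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# One phantom study at given defect and noise seed -> perfusion_result.
run_study <- function(shape, grid, defect, acq, sampling, noise_seed, phase) {
  vol <- render_volume(shape, defect, acq)
  vol <- apply_gaussian_blur(vol, acq$blur_fwhm_mm)
  vol <- add_poisson_noise(vol, acq$counts_scale, noise_seed)
  w <- sample_weights(vol, grid, sampling)
  compute_perfusion_vector(grid, weights = w, phase = phase)
}

#' Generate a synthetic stress/rest cohort
#'
#' Draws defect parameters per patient, simulates paired stress and rest
#' studies through the full phantom pipeline, samples weights, and records the
#' perfusion vectors, difference metrics and the true defect area fraction.
#' Fully reproducible from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `cohort_table`, one row per patient:
#'   `study_id`, `group` (defect location or `"normal"`), `condition`
#'   (`"normal"`, `"ischemia"`, `"infarction"`), stress and rest vector
#'   components and magnitudes (mm), `diff_mag` (`|P_s| - |P_r|`),
#'   `vec_diff_mag` (`|P_s - P_r|`), `true_extent_fraction`, `alpha_deg`,
#'   `severity`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("normal", spec$n_normal),
              rep(spec$locations, each = spec$n_per_defect_group))
  if (length(groups) == 0L) {
    abort("cohort has zero patients", "perfvec_empty_table")
  }
  shape <- resolve_shape(spec$shape)
  grid <- build_lv_surface(shape, spec$res)

  with_seed(spec$seed, {
    rows <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      grp <- groups[i]
      noise_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
      if (grp == "normal") {
        condition <- "normal"
        alpha <- NA_real_
        severity <- NA_real_
        d_stress <- d_rest <- NULL
        frac <- 0
      } else {
        condition <- if (stats::runif(1) < spec$prob_ischemia) "ischemia"
                     else "infarction"
        alpha <- stats::runif(1, spec$alpha_range[1], spec$alpha_range[2])
        severity <- stats::runif(1, spec$severity_range[1],
                                 spec$severity_range[2])
        rest_sev <- if (condition == "ischemia") {
          severity * stats::runif(1, spec$rest_ratio_range[1],
                                  spec$rest_ratio_range[2])
        } else severity
        d_stress <- defect_spec(grp, alpha = alpha,
                                extent_mm = spec$extent_mm,
                                severity = severity)
        d_rest <- defect_spec(grp, alpha = alpha, extent_mm = spec$extent_mm,
                              severity = rest_sev)
        frac <- defect_area_fraction(grid, d_stress)
      }
      ps <- run_study(shape, grid, d_stress, spec$acq, spec$sampling,
                      noise_seeds[1], "stress")
      pr <- run_study(shape, grid, d_rest, spec$acq, spec$sampling,
                      noise_seeds[2], "rest")
      dm <- difference_metrics(ps, pr)
      rows[[i]] <- data.frame(
        study_id = sprintf("S%03d", i), group = grp, condition = condition,
        stress_px = ps$P[["x"]], stress_py = ps$P[["y"]],
        stress_pz = ps$P[["z"]], stress_mag = ps$magnitude,
        rest_px = pr$P[["x"]], rest_py = pr$P[["y"]],
        rest_pz = pr$P[["z"]], rest_mag = pr$magnitude,
        diff_mag = dm$magnitude_difference,
        vec_diff_mag = dm$vector_difference_magnitude,
        true_extent_fraction = frac,
        alpha_deg = alpha, severity = severity,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "seed") <- spec$seed
    out
  })
}

cohort_columns <- c("study_id", "group", "condition",
                    "stress_px", "stress_py", "stress_pz", "stress_mag",
                    "rest_px", "rest_py", "rest_pz", "rest_mag",
                    "diff_mag", "vec_diff_mag", "true_extent_fraction",
                    "alpha_deg", "severity")

#' Write / read a cohort table as CSV
#'
#' Numeric cells are written with 9 significant digits; identical tables give
#' byte-identical files.
#'
#' @param cohort A `cohort_table` (or compatible data frame).
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing)) {
    abort(paste("cohort table lacks columns:", paste(missing, collapse = ", ")),
          "perfvec_schema_error")
  }
  out <- cohort[cohort_columns]
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                          sprintf("%.9g", out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort table not found: %s", path), "perfvec_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing)) {
    abort(paste("cohort CSV lacks columns:", paste(missing, collapse = ", ")),
          "perfvec_schema_error")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}
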