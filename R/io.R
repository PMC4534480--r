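# Readers and writers: surface-grid CSV, NIfTI-1 volumes, result/report JSON.
# All interchange coordinates are cardiac-frame millimetres.

surface_columns <- c("index", "x_mm", "y_mm", "z_mm", "area_mm2", "weight")

#' Write a surface grid to CSV
#'
#' Columns `index,x_mm,y_mm,z_mm,area_mm2,weight`, one row per rectangle,
#' numeric cells at 9 significant digits. The intrinsic surface coordinates
#' and normals are not part of the interchange format; a grid read back from
#' CSV supports the centroid computations but not defect geometry or normal
#' sampling.
#'
#' @param grid A `surface_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(grid, path) {
  stopifnot(inherits(grid, "surface_grid"))
  d <- grid$data
  out <- data.frame(index = d$index,
                    x_mm = sprintf("%.9g", d$x),
                    y_mm = sprintf("%.9g", d$y),
                    z_mm = sprintf("%.9g", d$z),
                    area_mm2 = sprintf("%.9g", d$area),
                    weight = sprintf("%.9g", d$weight))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a surface grid from CSV
#'
#' Strict schema: exactly the columns written by [write_surface_csv()], a
#' contiguous 0-based index, and numeric cells throughout. Malformed input is
#' rejected, never coerced.
#'
#' @param path Input file path.
#' @return A `surface_grid` with `parametric = FALSE`.
#' @export
read_surface_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("surface CSV not found: %s", path), "perfvec_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(surface_columns, names(raw))
  extra <- setdiff(names(raw), surface_columns)
  if (length(missing) || length(extra)) {
    abort(sprintf("surface CSV schema mismatch%s%s",
                  if (length(missing)) paste0("; missing: ",
                                              paste(missing, collapse = ", "))
                  else "",
                  if (length(extra)) paste0("; unexpected: ",
                                            paste(extra, collapse = ", "))
                  else ""),
          "perfvec_schema_error")
  }
  if (nrow(raw) == 0L) {
    abort("surface CSV contains a header but no rectangles",
          "perfvec_empty_grid")
  }
  num <- lapply(surface_columns, function(nm) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]))
    if (length(bad) || anyNA(raw[[nm]])) {
      row <- if (length(bad)) bad[1] else which(is.na(raw[[nm]]))[1]
      abort(sprintf("non-numeric value in column '%s', row %d", nm, row),
            "perfvec_parse_error")
    }
    v
  })
  names(num) <- surface_columns
  if (!identical(as.integer(num$index), seq_len(nrow(raw)) - 1L)) {
    abort("`index` must be contiguous from 0", "perfvec_schema_error")
  }
  data <- data.frame(index = as.integer(num$index),
                     x = num$x_mm, y = num$y_mm, z = num$z_mm,
                     area = num$area_mm2, weight = num$weight)
  structure(list(data = data, shape = NULL, resolution = NULL,
                 frame = cardiac_frame(), arc_total = NULL,
                 parametric = FALSE),
            class = "surface_grid")
}

#' Write / read a voxel volume as NIfTI-1
#'
#' Voxel spacing goes into the header `pixdim`; the volume origin into the
#' sform affine. Values and spacing round-trip exactly for integer-count
#' volumes.
#'
#' @param vol A [voxel_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("volume not found: %s", path), "perfvec_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("expected a 3-D volume, got %d dimensions", length(d)),
          "perfvec_dimensionality_error")
  }
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L || any(!is.finite(spacing[1:3])) ||
      any(spacing[1:3] <= 0)) {
    abort("volume header carries no usable voxel spacing",
          "perfvec_header_error")
  }
  aff <- RNifti::xform(img)
  origin <- aff[1:3, 4]
  voxel_volume(array(as.numeric(img), dim = d), spacing = spacing[1:3],
               origin = origin)
}

#' Write a perfusion result as JSON
#'
#' `{phase, C_A:[x,y,z], C_P:[x,y,z], P:[x,y,z], magnitude}`, mm units.
#'
#' @param result A `perfusion_result`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "perfusion_result"))
  obj <- list(phase = result$phase,
              C_A = unname(result$C_A$point),
              C_P = unname(result$C_P$point),
              P = unname(result$P),
              magnitude = result$magnitude)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Write a group-comparison report as JSON
#'
#' @param report A `group_comparison`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "group_comparison"))
  obj <- list(metric = report$metric, reference = report$reference,
              kruskal = list(H = report$kruskal$H,
                             p_value = report$kruskal$p_value,
                             df = report$kruskal$df),
              n_comparisons = report$n_comparisons,
              bonferroni_threshold = report$bonferroni_threshold,
              omnibus_significant = report$omnibus_significant,
              pairwise = report$pairwise)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
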