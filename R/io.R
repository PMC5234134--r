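#' @name sinomar_io
#' @title Reading and writing images, sinograms, masks, and geometry
#'
#' @description
#' Images and sinograms are stored either as 32-bit TIFF with an affine
#' offset/scale declared in a YAML sidecar (\code{<path>.yaml}), or as raw
#' little-endian float64 arrays with an 16-byte header (magic \code{"SMAR"},
#' int32 rows, int32 columns, int32 reserved). Binary masks are stored as
#' 8-bit PNG (0/255). Geometry round-trips through YAML with explicit units.
#'
#' @param x Numeric matrix to write.
#' @param path File path.
#' @param offset,scale Affine mapping for PNG input: value = stored * scale
#'   + offset.
NULL

#' @rdname sinomar_io
#' @export
write_image_tiff <- function(x, path) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((x - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(offset = lo, scale = scale,
                        rows = nrow(x), cols = ncol(x)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname sinomar_io
#' @export
read_image_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  v <- tiff::readTIFF(path)
  v * meta$scale + meta$offset
}

#' @rdname sinomar_io
#' @export
write_array_raw <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SMAR"), con)
  writeBin(as.integer(c(nrow(x), ncol(x), 0L)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname sinomar_io
#' @export
read_array_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "SMAR")) stop("not a sinomar raw array file")
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  matrix(readBin(con, "numeric", hdr[1] * hdr[2], size = 8L,
                 endian = "little"), hdr[1], hdr[2])
}

#' @rdname sinomar_io
#' @export
write_mask_png <- function(x, path) {
  png::writePNG(matrix(as.numeric(x != 0), nrow(x), ncol(x)), path)
  invisible(path)
}

#' @rdname sinomar_io
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  (v > 0.5) + 0L
}

#' @rdname sinomar_io
#' @export
read_image_png <- function(path, offset = 0, scale = 1) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  round(v * 65535) * scale + offset
}

#' Serialize acquisition geometry to YAML
#'
#' @param geom A [fan_geometry()].
#' @param path Output path; \code{NULL} returns the YAML string.
#' @return The path (or YAML string), invisibly.
#' @export
geometry_to_yaml <- function(geom, path = NULL) {
  fields <- list(
    n_detectors = geom$n_detectors,
    n_views = geom$n_views,
    angular_range_deg = geom$angular_range,
    source_to_iso_mm = geom$source_to_iso,
    source_to_detector_mm = geom$source_to_detector,
    detector_bin_width_mm = geom$detector_bin_width,
    image_shape_px = as.integer(geom$image_shape),
    pixel_spacing_mm = geom$pixel_spacing)
  if (is.null(path)) return(yaml::as.yaml(fields, precision = 15L))
  yaml::write_yaml(fields, path, precision = 15L)
  invisible(path)
}

#' Read acquisition geometry from YAML
#'
#' @param path YAML file written by [geometry_to_yaml()].
#' @return A [fan_geometry()].
#' @export
geometry_from_yaml <- function(path) {
  f <- yaml::read_yaml(path)
  fan_geometry(n_detectors = f$n_detectors, n_views = f$n_views,
               angular_range = f$angular_range_deg,
               source_to_iso = f$source_to_iso_mm,
               source_to_detector = f$source_to_detector_mm,
               detector_bin_width = f$detector_bin_width_mm,
               image_shape = f$image_shape_px,
               pixel_spacing = f$pixel_spacing_mm)
}

#' Write every stage of a pipeline run to a directory
#'
#' Stores the uncorrected and corrected sinograms and images (32-bit TIFF
#' with sidecars), the metal and trace masks (PNG), the prior image, the
#' geometry YAML, per-method iteration CSVs, the metrics report
#' (CSV and JSON), and a \code{manifest.json} listing every file plus the
#' resolved settings.
#'
#' @param run A \code{mar_run} from [run_mar()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(name, writer) {
    p <- file.path(dir, name)
    writer(p)
    files <<- c(files, name)
  }
  put("sino_uncorrected.tif", function(p) write_image_tiff(run$sino_uncorrected, p))
  put("image_uncorrected.tif", function(p) write_image_tiff(run$image_uncorrected, p))
  if (!is.null(run$sino_truth))
    put("sino_truth.tif", function(p) write_image_tiff(run$sino_truth, p))
  put("metal_mask.png", function(p) write_mask_png(run$metal_mask, p))
  put("trace_omega.png", function(p) write_mask_png(run$trace$omega, p))
  put("prior_image.tif", function(p) write_image_tiff(run$prior$values, p))
  put("geometry.yaml", function(p) geometry_to_yaml(run$geometry, p))
  for (m in names(run$results)) {
    res <- run$results[[m]]
    put(sprintf("sino_%s.tif", m), function(p) write_image_tiff(res$sinogram, p))
    put(sprintf("image_%s.tif", m), function(p) write_image_tiff(res$image, p))
    if (!is.null(res$state))
      put(sprintf("iterations_%s.csv", m),
          function(p) write_iteration_log(res$state, p))
  }
  if (!is.null(run$report)) {
    put("report.csv", function(p) write.csv(run$report, p, row.names = FALSE))
    put("report.json", function(p)
      jsonlite::write_json(run$report, p, auto_unbox = TRUE, digits = NA))
  }
  settings <- run$settings
  settings$cfg <- unclass(settings$cfg)
  if (!is.null(settings$noise)) settings$noise <- unclass(settings$noise)
  manifest <- list(files = files, settings = settings)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}
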