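#' Read and write point patterns as CSV
#'
#' Patterns travel as plain CSV with columns `x_um`, `y_um`, `type`,
#' `layer` (the latter two optional); the window is not stored in the CSV
#' and must be supplied on read.
#'
#' @param pattern a [point_pattern()].
#' @param path file path.
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern), path, row.names = FALSE)
  invisible(path)
}

#' @param window a `cm_window` for the pattern read back.
#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path, window) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  point_pattern(df$x_um, df$y_um, window,
                type = if (!all(is.na(df$type))) df$type,
                layer = if (!is.null(df$layer) && !all(is.na(df$layer)))
                  df$layer)
}

#' Read and write annotations as JSON
#'
#' JSON layout: `{"roi": [[x, y], ...], "boundaries": {"name": [[x, y],
#' ...], ...}, "layer_names": [...]}` with um coordinates; boundaries
#' ordered top to bottom.
#'
#' @param annotation a [cortical_annotation()].
#' @param path file path.
#' @export
write_annotation_json <- function(annotation, path) {
  obj <- list(
    roi = unname(apply(annotation$roi, 1, function(r) as.numeric(r),
                       simplify = FALSE)),
    boundaries = lapply(annotation$boundaries, function(b)
      unname(apply(b, 1, function(r) as.numeric(r), simplify = FALSE))),
    layer_names = annotation$layer_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundaries <- lapply(obj$boundaries, function(b) {
    m <- if (is.list(b)) do.call(rbind, b) else as.matrix(b)
    colnames(m) <- c("x", "y")
    m
  })
  cortical_annotation(boundaries, obj$layer_names)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are scaled to `[0, 1]` float pages; the scale factor and
#' the spatial calibration (`pixel_size_um`, `z_interval_um`, `origin_um`,
#' `channel`) live in `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path TIFF path; sidecar written next to it.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- stack$voxels
  sc <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(s) t(v[, , s]) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size, z_interval_um = stack$z_interval,
         channel = stack$channel_name, origin_um = stack$origin_um,
         intensity_scale = sc),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) v[, , s] <- t(pages[[s]]) * meta$intensity_scale
  image_stack(v, pixel_size = meta$pixel_size_um,
              z_interval = meta$z_interval_um, channel_name = meta$channel,
              origin_um = meta$origin_um)
}
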