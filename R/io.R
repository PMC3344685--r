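#' Write or read a section field as PNG with a JSON sidecar
#'
#' The label image is stored as a single-channel 8-bit PNG (gray value =
#' label code) and the metadata — pixel size, plane parameters, field
#' origin and the label legend — in `<path>.json`. Particles are not
#' serialized.
#'
#' @param field a `section_field`.
#' @param path PNG file path.
#' @return `read_section_field` returns a `section_field`.
#' @export
write_section_field <- function(field, path) {
  stopifnot(inherits(field, "section_field"))
  png::writePNG(t(field$labels)[ncol(field$labels):1, , drop = FALSE] / 255,
                path)
  meta <- list(pixel_size = field$pixel_size,
               origin = field$origin,
               legend = list(outside = 0, lumen = 1, epithelium = 2,
                             stroma = 3))
  if (!is.null(field$plane))
    meta$plane <- list(normal = field$plane$normal,
                       offset = field$plane$offset,
                       thickness = field$plane$thickness,
                       vertical_axis = field$plane$vertical_axis)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_section_field
#' @export
read_section_field <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  lab <- t(img[nrow(img):1, , drop = FALSE]) * 255
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  plane <- NULL
  if (!is.null(meta$plane))
    plane <- section_plane(meta$plane$normal, meta$plane$offset,
                           meta$plane$thickness)
  section_field(matrix(as.integer(round(lab)), nrow(lab)),
                pixel_size = meta$pixel_size, plane = plane,
                origin = meta$origin)
}

#' Write or read tidy per-field raw counts
#'
#' Long-format CSV with columns `animal_id`, `section_id`, `field_id`,
#' `measure`, `value` — the raw-count exchange format between the
#' sampling and estimation layers.
#'
#' @param counts data frame in the tidy layout.
#' @param path CSV path.
#' @return `read_field_counts` returns the data frame.
#' @export
write_field_counts <- function(counts, path) {
  need <- c("animal_id", "section_id", "field_id", "measure", "value")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  write.csv(counts[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_counts
#' @export
read_field_counts <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
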