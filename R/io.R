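# Frame and mask I/O plus YAML (de)serialization of the configuration.

#' Read grayscale frames
#'
#' Reads a directory of PNG/TIFF/JPEG images (lexicographic order) or a
#' single file, converting to grayscale matrices on the 0-255 scale.
#'
#' @param path directory or file path.
#' @return named list of numeric matrices.
#' @export
read_frames <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                    ignore.case = TRUE, full.names = TRUE))
  } else path
  if (!length(files)) stop(sprintf("no image files found under '%s'", path))
  out <- lapply(files, function(f) {
    img <- EBImage::readImage(f)
    if (EBImage::colorMode(img) != 0) img <- EBImage::channel(img, "gray")
    d <- EBImage::imageData(img)
    if (length(dim(d)) > 2) d <- d[, , 1]
    t(d) * 255          # EBImage stores (x, y); rows = y for matrices here
  })
  names(out) <- sub("\\.[^.]+$", "", basename(files))
  out
}

#' Write a binary mask as an 8-bit 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  m <- .as_mask(mask)
  EBImage::writeImage(EBImage::Image(t(m * 1)), path)
  invisible(path)
}

#' Serialize a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  yaml::write_yaml(list(hwf = strip(config$hwf),
                        diffusion = strip(config$diffusion),
                        synthesis = strip(config$synthesis),
                        detect = strip(config$detect),
                        epsilon = config$epsilon,
                        boundary = config$boundary,
                        refresh_interval = config$refresh_interval), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path file written by [write_config()].
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    hwf = do.call(hwf_params, y$hwf),
    diffusion = do.call(diffusion_params, y$diffusion),
    synthesis = do.call(synthesis_params, y$synthesis),
    detect = do.call(detect_params, y$detect),
    epsilon = y$epsilon,
    boundary = y$boundary %||% "symmetric",
    refresh_interval = y$refresh_interval %||% 0L)
}
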