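# Readers and writers for spectral stacks and reconstructions.
#
# Two containers are supported:
#   * "rds"  — native, lossless (bit-identical round trip), one file;
#   * "tiff" — interoperable multi-page TIFF (one page per spectral frame,
#     32-bit float, data affinely scaled into [0, 1]) plus a JSON sidecar
#     holding the k axis, the scaling, and acquisition metadata.

#' Write a spectral stack to disk
#'
#' @param stack A [spectral_stack()].
#' @param path Output path. `.rds` selects the native container; `.tif`/
#'   `.tiff` writes a multi-page TIFF with a `.json` sidecar next to it.
#' @param format Override the container inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "rds", "tiff")) {
  stopifnot(inherits(stack, "spectral_stack"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "rds"
  }
  if (format == "rds") {
    saveRDS(stack, path)
    return(invisible(path))
  }
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(l) (stack$data[, , l] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(list(
    k_axis = stack$k_axis,
    mask_id = as.character(stack$mask_id),
    acquisition_mode = stack$acquisition_mode,
    scale = scale, offset = lo,
    dims = d
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral stack from disk
#'
#' @param path `.rds` file, or `.tif`/`.tiff` with its JSON sidecar.
#' @return A [spectral_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stack <- readRDS(path)
    if (!inherits(stack, "spectral_stack")) {
      stop("file does not contain a spectral_stack", call. = FALSE)
    }
    return(stack)
  }
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (!file.exists(sidecar)) {
    stop("missing sidecar JSON (k_axis metadata): ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$k_axis)) {
    stop("sidecar lacks the k_axis entry", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$k_axis)) {
    stop(sprintf("sidecar lists %d wavelengths but the TIFF has %d pages",
                 length(meta$k_axis), length(pages)), call. = FALSE)
  }
  d <- c(dim(pages[[1]]), length(pages))
  data <- array(0, d)
  for (l in seq_along(pages)) {
    data[, , l] <- pages[[l]] * meta$scale + meta$offset
  }
  mask_id <- meta$mask_id
  if (grepl("^-?[0-9]+$", mask_id)) mask_id <- as.integer(mask_id)
  spectral_stack(pmax(data, 0), meta$k_axis, mask_id = mask_id,
                 acquisition_mode = meta$acquisition_mode)
}

#' Write a reconstruction volume
#'
#' Native RDS container (complex data plus provenance); magnitude-only TIFF
#' export is available through `format = "tiff"` with a JSON sidecar holding
#' the z axis and the affine scaling.
#'
#' @param volume A [recon_volume()].
#' @param path Output path.
#' @param format `"auto"`, `"rds"`, or `"tiff"` (magnitude only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "rds", "tiff")) {
  stopifnot(inherits(volume, "recon_volume"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "rds"
  }
  if (format == "rds") {
    saveRDS(volume, path)
    return(invisible(path))
  }
  mag <- Mod(volume$data)
  d <- dim(mag)
  hi <- max(mag)
  scale <- if (hi > 0) hi else 1
  pages <- lapply(seq_len(d[3]), function(l) mag[, , l] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(list(z_axis = volume$z_axis, scale = scale,
                            content = "magnitude",
                            provenance = volume$provenance),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
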