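# TIFF payloads are stored as 32-bit unsigned samples scaled into [0, 1];
# the true intensity scale lives in the sidecar JSON, so round-trips are
# exact to 2^-32 relative quantization.

#' Write a hyperspectral stack as multi-page TIFF + sidecar JSON
#'
#' One page per wavenumber in ascending order. The sidecar
#' (`<path>.json`) records the axis, pixel size, the intensity scale used
#' for the 32-bit quantization, and any extra metadata supplied (seed,
#' parameters).
#'
#' @param stack An [hs_stack()].
#' @param path Output TIFF path.
#' @param extra Named list of additional metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "hs_stack"))
  lo <- min(stack$data)
  if (lo < 0) stop("cannot store negative intensities; offset the stack first",
                   call. = FALSE)
  scale <- max(stack$data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_along(stack$axis), function(i) stack$data[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(axis_cm1 = stack$axis, pixel_size_um = stack$pixel_size,
                 intensity_scale = scale, n_pages = length(stack$axis)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a hyperspectral stack from multi-page TIFF
#'
#' The wavenumber axis is taken from the sidecar JSON written by
#' [write_stack()], or from the `axis` argument when no sidecar exists.
#' Pages are reordered by ascending wavenumber.
#'
#' @param path TIFF path.
#' @param axis Wavenumber axis override (required without a sidecar).
#' @param pixel_size Pixel size override.
#' @return An [hs_stack()].
#' @export
read_stack <- function(path, axis = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(axis)) axis <- meta$axis_cm1
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(axis))
    stop("no sidecar JSON found for ", path,
         " and no wavenumber axis supplied", call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- NA_real_
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(axis))
    stop("stack has ", length(pages), " pages but the axis lists ",
         length(axis), " wavenumbers", call. = FALSE)
  o <- order(axis)
  arr <- array(0, dim = c(length(axis), dim(pages[[1L]])[1:2]))
  for (i in seq_along(o)) arr[i, , ] <- pages[[o[i]]][, , drop = TRUE] * scale
  hs_stack(arr, axis[o], pixel_size)
}

# write one 2D float map (same quantized scheme, per-map scale sidecar)
write_map <- function(m, path) {
  lo <- min(m)
  offset <- if (lo < 0) -lo else 0
  scale <- max(m + offset)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((m + offset) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(intensity_scale = scale, offset = offset),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-channel float map written by the package
#'
#' @param path TIFF path (with `<path>.json` scale sidecar).
#' @return 2D matrix.
#' @export
read_map <- function(path) {
  scale <- 1; offset <- 0
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    if (!is.null(meta$offset)) offset <- meta$offset
  }
  m <- tiff::readTIFF(path)
  m[, , drop = TRUE] * scale - offset
}

#' Write all pipeline outputs and a checksummed manifest
#'
#' Writes one 32-bit float TIFF per concentration channel plus the
#' residual map, 16-bit integer mask TIFFs, CSV feature tables, JSON
#' summaries, and finally `manifest.json` listing every file with its
#' MD5 checksum. No timestamps are embedded, so reruns with the same
#' inputs are byte-identical.
#'
#' @param maps A `concentration_maps` (or NULL).
#' @param masks Named list with optional `cells` ([cell_mask()]) and
#'   `aggregates` ([aggregate_mask()]).
#' @param tables Named list of data.frames written as CSV.
#' @param summaries Named list written as JSON.
#' @param outdir Output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
write_outputs <- function(maps = NULL, masks = list(), tables = list(),
                          summaries = list(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(f) files <<- c(files, f)
  if (!is.null(maps)) {
    for (nm in maps$names) {
      f <- file.path(outdir, paste0("map_", nm, ".tif"))
      write_map(maps$maps[[nm]], f); add(f); add(paste0(f, ".json"))
    }
    f <- file.path(outdir, "residual_norm.tif")
    write_map(maps$residual_norm, f); add(f); add(paste0(f, ".json"))
  }
  for (nm in names(masks)) {
    f <- file.path(outdir, paste0("mask_", nm, ".tif"))
    write_mask(masks[[nm]], f); add(f)
    if (inherits(masks[[nm]], "aggregate_mask")) add(paste0(f, ".parent.csv"))
  }
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE); add(f)
  }
  for (nm in names(summaries)) {
    f <- file.path(outdir, paste0(nm, ".json"))
    jsonlite::write_json(summaries[[nm]], f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    add(f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
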