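#' Cell label mask
#'
#' @param labels 2D integer matrix; 0 = background, 1..n = cells with no
#'   label skipped.
#' @param pixel_size um per pixel.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(labels, pixel_size = NA_real_) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(n)))
    stop("cell labels must be consecutive 1..n (found gaps)", call. = FALSE)
  structure(list(labels = labels, pixel_size = pixel_size), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d cells, %d x %d px\n", max(x$labels, 0L),
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Aggregate label mask with parent-cell mapping
#'
#' @param labels 2D integer matrix (0 = none, 1..m = aggregates).
#' @param parent Integer vector, `parent[j]` = cell label owning
#'   aggregate j.
#' @param cells Optional [cell_mask()]; when given, every aggregate pixel
#'   is checked to lie inside its parent cell.
#' @return An object of class `aggregate_mask`.
#' @export
aggregate_mask <- function(labels, parent, cells = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  m <- max(labels, 0L)
  parent <- as.integer(parent)
  if (length(parent) < m)
    stop("parent mapping missing for some aggregate labels", call. = FALSE)
  if (!is.null(cells)) {
    for (j in seq_len(m)) {
      owner <- cells$labels[labels == j]
      if (length(owner) && any(owner != parent[j]))
        stop("aggregate ", j, " has pixels outside its parent cell ",
             parent[j], call. = FALSE)
    }
  }
  structure(list(labels = labels, parent = parent), class = "aggregate_mask")
}

#' @export
print.aggregate_mask <- function(x, ...) {
  cat(sprintf("<aggregate_mask> %d aggregates, %d x %d px\n",
              max(x$labels, 0L), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# drop labels below a size, relabel consecutively preserving order
relabel_filtered <- function(labels, min_area_px) {
  m <- max(labels, 0L)
  if (m == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = m)
  keep <- which(sizes >= min_area_px)
  newlab <- integer(m)
  newlab[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- newlab[labels[labels > 0L]]
  out
}

#' Segment cells from a summed-intensity image
#'
#' Classical pipeline: Gaussian smooth, global Otsu (or fixed) threshold,
#' hole filling, optional watershed split seeded by distance-transform
#' maxima, removal of objects below `min_area_px`, consecutive
#' relabelling. Deterministic; a stand-in for interactive pixel
#' classification workflows whose corrected masks can instead be loaded
#' with [import_labels()].
#'
#' @param image 2D matrix (typically the spectrally summed fingerprint
#'   image or a concentration map).
#' @param smooth_sigma Gaussian smoothing sd in px (0 disables).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value when `threshold_method = "fixed"`.
#' @param min_area_px Minimum object area kept.
#' @param split Watershed-split touching cells (default TRUE).
#' @param pixel_size um per pixel, stored in the mask.
#' @return A [cell_mask()].
#' @export
segment_cells <- function(image, smooth_sigma = 1,
                          threshold_method = c("otsu", "fixed"),
                          threshold = NULL, min_area_px = 30L, split = TRUE,
                          pixel_size = NA_real_) {
  threshold_method <- match.arg(threshold_method)
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite 2D matrix", call. = FALSE)
  img <- if (smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma = smooth_sigma))
  else image
  if (threshold_method == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0)
      stop("constant image: Otsu threshold is degenerate", call. = FALSE)
    threshold <- EBImage::otsu(EBImage::Image(img), range = rng)
  } else if (is.null(threshold))
    stop("threshold_method='fixed' needs a threshold", call. = FALSE)
  bin <- EBImage::fillHull(EBImage::Image(img > threshold))
  labels <- if (split) {
    dm <- EBImage::distmap(bin)
    EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(bin))
  }
  storage.mode(labels) <- "integer"
  cell_mask(relabel_filtered(labels, min_area_px), pixel_size)
}

#' Segment intracellular aggregates
#'
#' White top-hat (disc of radius `tophat_radius_px`) to isolate bright
#' spots, fixed threshold, restriction to cell pixels, connected
#' components (8-connected), size filter, and parenting of each
#' aggregate to the cell under its centroid. Components whose centroid
#' falls on background after restriction are dropped with a warning.
#'
#' @param image 2D matrix: the limonene concentration map (preferred) or
#'   a spectrally summed image.
#' @param cells A [cell_mask()] aligned with `image`.
#' @param tophat_radius_px Disc radius of the top-hat structuring element.
#' @param agg_threshold Threshold on the top-hat response.
#' @param min_area_px Minimum aggregate area kept.
#' @return An [aggregate_mask()].
#' @export
segment_aggregates <- function(image, cells, tophat_radius_px = 4L,
                               agg_threshold = 0.15, min_area_px = 4L) {
  stopifnot(inherits(cells, "cell_mask"))
  if (!all(dim(image) == dim(cells$labels)))
    stop("image and cell mask shapes differ", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius_px) + 1L, "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(image), brush))
  bin <- th >= agg_threshold & cells$labels > 0L
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  storage.mode(labels) <- "integer"
  labels <- relabel_filtered(labels, min_area_px)
  parent_of <- function(lab) {
    m <- max(lab, 0L)
    par <- integer(m); drop <- integer()
    for (j in seq_len(m)) {
      pix <- which(lab == j, arr.ind = TRUE)
      ctr <- round(colMeans(pix))
      p <- cells$labels[ctr[1], ctr[2]]
      if (p == 0L) { drop <- c(drop, j) } else par[j] <- p
    }
    list(parent = par, drop = drop)
  }
  pp <- parent_of(labels)
  if (length(pp$drop)) {
    warning("dropped ", length(pp$drop),
            " aggregate component(s) with centroid on background",
            call. = FALSE)
    labels[labels %in% pp$drop] <- 0L
    labels <- relabel_filtered(labels, 1L)
    pp <- parent_of(labels)
  }
  aggregate_mask(labels, pp$parent)
}

#' Import an externally produced label mask
#'
#' Loads integer label masks (e.g. from an interactive classification
#' tool, after manual correction), validates them, compacts labels to
#' 1..n preserving order, and for aggregate masks re-derives the parent
#' mapping against the supplied cell mask (parent = cell containing the
#' aggregate centroid; if the centroid pixel is background the cell with
#' the largest pixel overlap is used). An aggregate with no overlap with
#' any cell is a validation error.
#'
#' @param path TIFF file with a single integer-valued channel.
#' @param kind `"cell"` or `"aggregate"`.
#' @param cells_for_parenting [cell_mask()], required for
#'   `kind = "aggregate"`.
#' @param pixel_size um per pixel for cell masks.
#' @return A [cell_mask()] or [aggregate_mask()].
#' @export
import_labels <- function(path, kind = c("cell", "aggregate"),
                          cells_for_parenting = NULL, pixel_size = NA_real_) {
  kind <- match.arg(kind)
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) != 2L)
    stop("label mask must be a single-channel image: ", path, call. = FALSE)
  if (any(raw != round(raw)))
    stop("non-integer pixel values in label mask: ", path, call. = FALSE)
  labels <- matrix(as.integer(raw), nrow(raw), ncol(raw))
  present <- sort(unique(labels[labels > 0L]))
  compact <- integer(max(labels, 0L))
  compact[present] <- seq_along(present)
  labels[labels > 0L] <- compact[labels[labels > 0L]]
  if (kind == "cell") return(cell_mask(labels, pixel_size))
  cells <- cells_for_parenting
  if (is.null(cells))
    stop("aggregate import requires cells_for_parenting", call. = FALSE)
  m <- max(labels, 0L)
  par <- integer(m); bad <- integer()
  for (j in seq_len(m)) {
    pix <- which(labels == j, arr.ind = TRUE)
    ctr <- round(colMeans(pix))
    p <- cells$labels[ctr[1], ctr[2]]
    if (p == 0L) {
      under <- cells$labels[pix]
      under <- under[under > 0L]
      if (length(under) == 0L) { bad <- c(bad, j); next }
      p <- as.integer(names(which.max(table(under))))
    }
    par[j] <- p
  }
  if (length(bad))
    stop("aggregate label(s) lying wholly on background: ",
         paste(bad, collapse = ", "), call. = FALSE)
  aggregate_mask(labels, par)
}

#' Write a label mask as 16-bit integer TIFF
#'
#' @param mask A [cell_mask()] or [aggregate_mask()].
#' @param path Output TIFF path. For aggregate masks the parent mapping is
#'   written alongside as `<path>.parent.csv`
#'   (columns `aggregate_label,cell_label`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  labels <- mask$labels
  if (max(labels, 0L) > 65535L)
    stop("more than 65535 labels do not fit a 16-bit TIFF", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  if (inherits(mask, "aggregate_mask"))
    utils::write.csv(data.frame(aggregate_label = seq_along(mask$parent),
                                cell_label = mask$parent),
                     paste0(path, ".parent.csv"), row.names = FALSE)
  invisible(path)
}
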