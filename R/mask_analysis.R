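#' Membrane activity between two binary masks
#'
#' Pixel count of the symmetric difference between consecutive cell masks,
#' compared in the absolute frame (no recentring of barycentres): a moving
#' cell scores both its protruding front and retracting rear.
#'
#' @param m1,m2 logical matrices of identical dimensions.
#' @return integer pixel count.
#' @export
membrane_activity <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) {
    stop("mask dimensions differ: ", paste(dim(m1), collapse = "x"), " vs ",
         paste(dim(m2), collapse = "x"), call. = FALSE)
  }
  sum(xor(as.logical(m1), as.logical(m2)))
}

#' Membrane-activity time series of a mask sequence
#'
#' [membrane_activity()] applied to each consecutive pair of masks.
#'
#' @param masks list of logical matrices (ordered in time).
#' @return integer vector of length `length(masks) - 1`.
#' @export
activity_series <- function(masks) {
  if (length(masks) < 2) stop("need at least 2 masks", call. = FALSE)
  vapply(seq_len(length(masks) - 1), function(i) {
    membrane_activity(masks[[i]], masks[[i + 1]])
  }, numeric(1))
}

#' Binary mask from a Cellular Potts lattice
#'
#' Foreground is exactly the set of cell-labelled sites.
#'
#' @param lattice integer matrix (0 = medium, positive = cell).
#' @return logical matrix.
#' @export
mask_from_cpm <- function(lattice) {
  lattice > 0
}

#' Segmentation settings
#'
#' @param bg_radius background-subtraction radius (pixels; morphological
#'   opening with a disc of this radius estimates the background).
#' @param min_size minimum particle area (pixels).
#' @param circularity admissible range of `4 pi A / P^2`.
#' @param fill_holes fill holes in particles before measuring.
#' @param exclude_edges drop particles touching the image border.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(bg_radius = 50, min_size = 1000,
                                circularity = c(0.3, 1.0), fill_holes = TRUE,
                                exclude_edges = TRUE) {
  stopifnot(min_size >= 1, length(circularity) == 2,
            circularity[1] >= 0, circularity[2] <= 1 + 1e-9,
            circularity[1] <= circularity[2])
  structure(list(bg_radius = bg_radius, min_size = min_size,
                 circularity = circularity, fill_holes = fill_holes,
                 exclude_edges = exclude_edges),
            class = "segmentation_config")
}

#' Segment cells from a grayscale image
#'
#' A simplified fluorescence segmentation pipeline: morphological background
#' subtraction (opening with a disc of radius `bg_radius`), Otsu threshold
#' on a dark background, connected components, hole filling, removal of
#' edge-touching particles, and filtering by minimum area and circularity
#' `4 pi A / P^2` within the configured range.
#'
#' @param img numeric matrix (grayscale intensities) or logical matrix
#'   (already-binary input, thresholding then reduces to identity).
#' @param cfg a [segmentation_config()].
#' @return list of particles, each a list with `mask` (logical matrix over
#'   the full image), `area`, `perimeter`, `circularity`, `centroid`.
#' @export
segment_image <- function(img, cfg = segmentation_config()) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("segment_image() requires the EBImage package", call. = FALSE)
  }
  stopifnot(inherits(cfg, "segmentation_config"))
  img <- matrix(as.numeric(img), nrow = nrow(img))
  if (length(img) == 0 || max(img) == min(img)) return(list())
  rng <- range(img)
  img <- (img - rng[1]) / (rng[2] - rng[1])
  if (cfg$bg_radius > 0) {
    sz <- 2 * floor(cfg$bg_radius) + 1
    brush <- EBImage::makeBrush(min(sz, 2 * floor((min(dim(img)) - 1) / 2) - 1),
                                shape = "disc")
    bg <- EBImage::opening(img, brush)
    img <- pmax(img - bg, 0)
    if (max(img) == 0) return(list())
    img <- img / max(img)
  }
  th <- EBImage::otsu(EBImage::Image(img))
  bw <- img > th
  if (cfg$fill_holes) bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(labm)), 0)
  if (!length(ids)) return(list())
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  out <- list()
  for (id in ids) {
    m <- labm == id
    if (cfg$exclude_edges &&
        (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))) next
    area <- shp[id, "s.area"]
    per <- shp[id, "s.perimeter"]
    circ <- if (per > 0) 4 * pi * area / per^2 else 0
    circ <- min(circ, 1)  # discrete perimeter underestimates can exceed 1
    if (area < cfg$min_size) next
    if (circ < cfg$circularity[1] || circ > cfg$circularity[2]) next
    out[[length(out) + 1]] <- list(
      mask = m, area = unname(area), perimeter = unname(per),
      circularity = unname(circ),
      centroid = c(mom[id, "m.cx"], mom[id, "m.cy"]))
  }
  out
}

#' Read a mask stack from TIFF
#'
#' @param file multi-page TIFF of 0/255 (or 0/1) masks.
#' @return list of logical matrices.
#' @export
read_mask_stack <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    pg > 0.5
  })
}

#' Write a mask stack to TIFF
#'
#' @param masks list of logical matrices.
#' @param file output path (multi-page TIFF, 0/255 coding).
#' @export
write_mask_stack <- function(masks, file) {
  imgs <- lapply(masks, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(imgs, file, bits.per.sample = 8)
  invisible(file)
}
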