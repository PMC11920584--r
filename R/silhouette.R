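# Images are plain numeric matrices in [0, 1], dimensions rows x columns
# (row = image row). Color inputs are converted to luma on read.

#' Read an image as a grayscale intensity matrix
#'
#' Reads PNG or TIFF (8- or 16-bit, single- or 3-channel); multi-channel
#' images are converted to luma (0.299 R + 0.587 G + 0.114 B), an alpha
#' channel is dropped, and intensities are returned in `[0, 1]`.
#'
#' @param path Image file; format chosen by extension.
#' @return Numeric matrix, rows x columns, values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_rootcarve(sprintf("unsupported image format '%s'", ext),
                   "rootcarve_bad_format"))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

#' Otsu's global threshold
#'
#' Bins the intensities into a `levels`-bin histogram over `[0, 1]` and
#' returns the threshold maximizing the between-class variance of the
#' resulting two-class split.
#'
#' @param image Numeric matrix in `[0, 1]` (values are clamped into range).
#' @param levels Histogram bins (256 for 8-bit imagery).
#' @return Scalar threshold in `(0, 1)`; foreground/background split at
#'   `value < threshold`.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  x <- pmin(1, pmax(0, as.numeric(image)))
  if (length(unique(x)) < 2)
    stop_rootcarve("constant image: Otsu threshold is undefined",
                   "rootcarve_constant_image")
  bin <- pmin(levels - 1L, floor(x * levels))
  counts <- tabulate(bin + 1L, nbins = levels)
  p <- counts / sum(counts)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  # between-class variance for a split after bin k (k = 1..levels-1)
  k <- seq_len(levels - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  k_star <- which.max(bcv)
  k_star / levels
}

#' Sobel gradient magnitude
#'
#' Per-pixel `sqrt(gx^2 + gy^2)` from the 3x3 Sobel kernels; the border is
#' handled by symmetric reflection.
#'
#' @param image Numeric matrix.
#' @return Numeric matrix of gradient magnitudes, same dimensions.
#' @export
sobel_magnitude <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  .sobel_mag_cpp(image)
}

#' Hysteresis thresholding of an edge-magnitude image
#'
#' Pixels with magnitude `>= high` are kept; pixels in `[low, high)` are
#' kept iff they connect (8-connectivity, through other kept pixels) to a
#' `>= high` pixel.
#'
#' @param magnitude Numeric matrix (e.g. from [sobel_magnitude()]).
#' @param low,high Thresholds, `0 <= low <= high`.
#' @return Logical matrix.
#' @export
hysteresis_threshold <- function(magnitude, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low >= 0 && low <= high))
    stop_rootcarve("hysteresis thresholds must satisfy 0 <= low <= high",
                   "rootcarve_invalid_threshold")
  m <- .hysteresis_cpp(magnitude, low, high)
  storage.mode(m) <- "logical"
  m
}

#' Simple global thresholding
#'
#' Foreground where the root is darker (default: dark roots on a bright,
#' backlit background) or brighter than the threshold.
#'
#' @param image Numeric matrix.
#' @param threshold Scalar.
#' @param polarity `"dark"` (foreground `< threshold`) or `"bright"`
#'   (foreground `> threshold`).
#' @return Logical matrix.
#' @export
simple_threshold <- function(image, threshold, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (polarity == "dark") image < threshold else image > threshold
}

#' Morphological opening of a binary mask
#'
#' Erosion then dilation with a square structuring element of side
#' `2 * radius + 1`; removes isolated pixels and pixel-wide specks while
#' leaving solid regions unchanged. The structuring element is clipped at
#' the image boundary.
#'
#' @param mask Logical matrix.
#' @param radius Integer >= 1.
#' @return Logical matrix.
#' @export
morphological_open <- function(mask, radius = 1L) {
  stopifnot(radius >= 1)
  m <- EBImage::opening(mask * 1, EBImage::makeBrush(2L * radius + 1L, "box"))
  m > 0.5
}

#' Default silhouette-extraction configuration
#'
#' @param polarity Foreground polarity for the simple threshold
#'   (`"dark"` roots against a backlit background by default).
#' @param hysteresis_low_frac,hysteresis_high_frac Hysteresis thresholds as
#'   fractions of the Otsu threshold of the normalized Sobel magnitude.
#' @param open_radius Radius of the final morphological opening, pixels.
#' @param roi Optional logical matrix restricting the silhouette to the
#'   canister interior (e.g. the `valid` mask of a traced view reshaped to
#'   the image grid); `NULL` keeps the full frame.
#' @param levels Histogram bins for the Otsu thresholds.
#' @export
silhouette_config <- function(polarity = c("dark", "bright"),
                              hysteresis_low_frac = 0.5,
                              hysteresis_high_frac = 1.0,
                              open_radius = 1L, roi = NULL, levels = 256L) {
  polarity <- match.arg(polarity)
  stopifnot(hysteresis_low_frac >= 0,
            hysteresis_low_frac <= hysteresis_high_frac)
  structure(list(polarity = polarity,
                 hysteresis_low_frac = hysteresis_low_frac,
                 hysteresis_high_frac = hysteresis_high_frac,
                 open_radius = as.integer(open_radius), roi = roi,
                 levels = as.integer(levels)),
            class = "silhouette_config")
}

#' Extract a binary root silhouette from a grayscale image
#'
#' The hybrid pipeline: (1) a global Otsu threshold of the intensity image
#' gives a simple-threshold mask that captures large structures; (2) Sobel
#' edges, hysteresis-thresholded at fractions of the Otsu threshold of the
#' normalized gradient magnitude, preserve thin roots; (3) the union of the
#' two masks, restricted to the region of interest, is morphologically
#' opened to drop pixel-wide specks.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param config A [silhouette_config()].
#' @return Object of class `silhouette`: list with logical `mask` and a
#'   `provenance` record of every threshold used.
#' @export
extract_silhouette <- function(image, config = silhouette_config()) {
  stopifnot(is.matrix(image))
  t_int <- tryCatch(otsu_threshold(image, config$levels),
                    error = function(e) NA_real_)
  if (is.na(t_int)) {
    # constant image: no structure anywhere
    mask <- matrix(FALSE, nrow(image), ncol(image))
    return(structure(list(mask = mask, provenance = list(
      otsu_intensity = NA_real_, otsu_edge = NA_real_,
      hysteresis_low = NA_real_, hysteresis_high = NA_real_,
      open_radius = config$open_radius, polarity = config$polarity)),
      class = "silhouette"))
  }
  simple <- simple_threshold(image, t_int, config$polarity)
  mag <- sobel_magnitude(image)
  mx <- max(mag)
  if (mx > 0) {
    nmag <- mag / mx
    t_edge <- tryCatch(otsu_threshold(nmag, config$levels),
                       error = function(e) NA_real_)
  } else t_edge <- NA_real_
  if (is.na(t_edge)) {
    edges <- matrix(FALSE, nrow(image), ncol(image))
    lo <- hi <- NA_real_
  } else {
    lo <- config$hysteresis_low_frac * t_edge
    hi <- config$hysteresis_high_frac * t_edge
    edges <- hysteresis_threshold(nmag, lo, hi)
  }
  mask <- simple | edges
  if (!is.null(config$roi)) {
    stopifnot(all(dim(config$roi) == dim(mask)))
    mask <- mask & config$roi
  }
  if (config$open_radius >= 1 && any(mask))
    mask <- morphological_open(mask, config$open_radius)
  structure(list(mask = mask, provenance = list(
    otsu_intensity = t_int, otsu_edge = t_edge,
    hysteresis_low = lo, hysteresis_high = hi,
    open_radius = config$open_radius, polarity = config$polarity)),
    class = "silhouette")
}

# accept either a silhouette object or a bare logical matrix
silhouette_mask <- function(x) {
  if (inherits(x, "silhouette")) x$mask
  else if (is.logical(x) && is.matrix(x)) x
  else stop_rootcarve("expected a silhouette or a logical matrix",
                      "rootcarve_bad_silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("<silhouette> %d x %d, %.2f%% foreground\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Region of interest from a traced view
#'
#' The canister-interior mask: pixels whose refracted ray validly enters
#' the water volume. Everything outside (the wall, the background, end-cap
#' and total-internal-reflection rays) is excluded from silhouettes.
#'
#' @param rf A [trace_view()] result.
#' @return Logical `height x width` matrix.
#' @export
roi_from_rayfield <- function(rf) {
  matrix(rf$valid, rf$height, rf$width)
}

#' Write a silhouette as a 1-bit PNG with a JSON provenance sidecar
#'
#' @param sil A `silhouette` (or logical matrix).
#' @param path PNG output path; provenance goes to `paste0(path, ".json")`.
#' @export
write_silhouette <- function(sil, path) {
  mask <- silhouette_mask(sil)
  png::writePNG(mask * 1, path)
  if (inherits(sil, "silhouette"))
    jsonlite::write_json(sil$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a silhouette written by [write_silhouette()]
#' @param path PNG path.
#' @export
read_silhouette <- function(path) {
  img <- read_gray_image(path)
  mask <- img > 0.5
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path)) jsonlite::fromJSON(prov_path) else NULL
  structure(list(mask = mask, provenance = prov), class = "silhouette")
}

#' Resample a silhouette to the ray grid
#'
#' Nearest-neighbor resampling from the image resolution to the (typically
#' coarser) ray-grid resolution used for tracing and carving.
#'
#' @param sil Silhouette or logical matrix at image resolution.
#' @param width,height Target grid size.
#' @export
resample_silhouette <- function(sil, width, height) {
  m <- silhouette_mask(sil)
  if (nrow(m) == height && ncol(m) == width) return(m)
  ri <- pmin(nrow(m), pmax(1L, round((seq_len(height) - 0.5) * nrow(m) / height + 0.5)))
  ci <- pmin(ncol(m), pmax(1L, round((seq_len(width) - 0.5) * ncol(m) / width + 0.5)))
  m[ri, ci, drop = FALSE]
}
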