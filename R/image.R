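#' Grayscale mammogram-like image container
#'
#' A plain integer intensity matrix plus its bit depth and physical pixel
#' spacing. Intensities must lie in `[0, 2^bit_depth)`; film digitizations
#' conventionally use 12-bit depth (0-4095).
#'
#' @param pixels Integer matrix of intensities (rows x columns).
#' @param bit_depth Bits per pixel (default 12).
#' @param pixel_spacing Physical side length of one pixel in cm (default
#'   0.01).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 12L, pixel_spacing = 0.01) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (pixel_spacing <= 0) abort("`pixel_spacing` must be positive.")
  if (bit_depth < 1 || bit_depth > 32) abort("`bit_depth` must be in 1..32.")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval) {
    abort(sprintf("Intensities must lie in [0, %d].", maxval))
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_spacing = pixel_spacing),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d px, %d-bit, %.4g cm/px (range %d-%d)\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_spacing,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Background/density threshold pair
#'
#' The two operator-chosen grey-level thresholds of computer-assisted
#' density measurement: the first separates the breast from the background,
#' the second marks dense tissue. The background threshold may not exceed
#' the density threshold.
#'
#' @param background_threshold,density_threshold Intensity thresholds.
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(background_threshold, density_threshold) {
  if (background_threshold > density_threshold) {
    abort("`background_threshold` must not exceed `density_threshold`.")
  }
  structure(
    list(background_threshold = background_threshold,
         density_threshold = density_threshold),
    class = "threshold_pair"
  )
}

#' Dual-threshold density measurement of a grayscale image
#'
#' Counts the superlevel sets of the two thresholds (inclusive: a pixel
#' belongs to a region when its intensity is greater than or equal to the
#' threshold): total breast area from the background threshold, dense area
#' from the density threshold, each converted to cm^2 via the pixel spacing.
#'
#' @param img A [gray_image()].
#' @param thr A [threshold_pair()].
#' @return A one-row tibble: `total_area`, `dense_area`, `nondense_area`
#'   (all cm^2) and `percent_density` (%).
#' @examples
#' px <- matrix(0L, 60, 60)
#' px[6:55, 6:55] <- 500L
#' px[20:29, 20:29] <- 3000L
#' img <- gray_image(px, pixel_spacing = 0.1)
#' measure_density(img, threshold_pair(400, 2000))
#' @export
measure_density <- function(img, thr) {
  stopifnot(inherits(img, "gray_image"), inherits(thr, "threshold_pair"))
  maxval <- 2^img$bit_depth - 1
  if (thr$background_threshold < 0 || thr$density_threshold > maxval + 1) {
    abort("Thresholds must lie within the image intensity range.")
  }
  px_area <- img$pixel_spacing^2
  n_total <- sum(img$pixels >= thr$background_threshold)
  if (n_total == 0L) {
    abort("Empty breast: no pixel reaches the background threshold.")
  }
  n_dense <- sum(img$pixels >= thr$density_threshold)
  total <- n_total * px_area
  dense <- n_dense * px_area
  tibble::tibble(
    total_area = total,
    dense_area = dense,
    nondense_area = total - dense,
    percent_density = 100 * dense / total
  )
}

#' Nested multi-threshold density measurement
#'
#' Measures density at an ascending ladder of density thresholds over a
#' common background threshold, emulating density definitions at
#' conventional, higher and highest brightness cut-offs. Dense areas are
#' weakly decreasing along the ladder and the total area is identical for
#' every row.
#'
#' @param img A [gray_image()].
#' @param bg_threshold Background threshold.
#' @param density_thresholds Non-decreasing vector of density thresholds,
#'   all `>= bg_threshold`.
#' @return A tibble with one row per threshold: `density_threshold` plus the
#'   columns of [measure_density()].
#' @export
measure_nested <- function(img, bg_threshold, density_thresholds) {
  if (is.unsorted(density_thresholds, strictly = FALSE)) {
    abort("`density_thresholds` must be in ascending order.")
  }
  if (any(density_thresholds < bg_threshold)) {
    abort("All density thresholds must be at least the background threshold.")
  }
  rows <- purrr::map(density_thresholds, function(t) {
    measure_density(img, threshold_pair(bg_threshold, t))
  })
  dplyr::bind_cols(
    tibble::tibble(density_threshold = density_thresholds),
    dplyr::bind_rows(rows)
  )
}

#' Synthesize a phantom mammogram with known ground truth
#'
#' Paints rectangular and circular regions of fixed intensity on a zero
#' background, optionally adds rounded Gaussian noise (clamped to the valid
#' intensity range), and reports the exact pixel count of every region.
#' Overlapping regions must agree in intensity unless later shapes are
#' explicitly allowed to overwrite (`allow_overlap = TRUE`); nested brighter
#' patches are naturally expressed by listing the brighter shape after the
#' enclosing one with `allow_overlap = TRUE`.
#'
#' @param width,height Canvas size in pixels.
#' @param shapes A data frame with columns `shape` ("rect" or "disc"),
#'   `x0`, `y0` (top-left corner for rect, centre for disc), `w`, `h`
#'   (rect size) or `r` (disc radius), `intensity`.
#' @param noise_sd SD of additive Gaussian noise (0 = none).
#' @param seed Optional seed for the noise.
#' @param bit_depth,pixel_spacing Passed to [gray_image()].
#' @param allow_overlap Let later shapes overwrite earlier ones.
#' @return A [gray_image()] with attribute `"ground_truth"`: a tibble of
#'   per-shape painted pixel counts (after overwriting).
#' @export
synth_mammogram <- function(width, height, shapes, noise_sd = 0, seed = NULL,
                            bit_depth = 12L, pixel_spacing = 0.01,
                            allow_overlap = FALSE) {
  px <- matrix(0L, nrow = height, ncol = width)
  owner <- matrix(0L, nrow = height, ncol = width)
  shapes <- tibble::as_tibble(shapes)
  for (i in seq_len(nrow(shapes))) {
    s <- shapes[i, ]
    mask <- matrix(FALSE, height, width)
    if (s$shape == "rect") {
      rows <- s$y0:(s$y0 + s$h - 1L)
      cols <- s$x0:(s$x0 + s$w - 1L)
      if (min(rows) < 1 || max(rows) > height || min(cols) < 1 || max(cols) > width) {
        abort(sprintf("Shape %d does not fit in the canvas.", i))
      }
      mask[rows, cols] <- TRUE
    } else if (s$shape == "disc") {
      rc <- expand.grid(r = seq_len(height), c = seq_len(width))
      inside <- (rc$r - s$y0)^2 + (rc$c - s$x0)^2 <= s$r^2
      if (s$y0 - s$r < 1 || s$y0 + s$r > height || s$x0 - s$r < 1 || s$x0 + s$r > width) {
        abort(sprintf("Shape %d does not fit in the canvas.", i))
      }
      mask[cbind(rc$r[inside], rc$c[inside])] <- TRUE
    } else {
      abort(paste0("Unknown shape type: ", s$shape))
    }
    clash <- mask & owner > 0L & px != as.integer(s$intensity)
    if (any(clash) && !allow_overlap) {
      abort(sprintf(
        "Shape %d overlaps an earlier region with a different intensity (%d clashing pixel(s)).",
        i, sum(clash)
      ))
    }
    px[mask] <- as.integer(s$intensity)
    owner[mask] <- i
  }
  counts <- tibble::tibble(
    shape_index = seq_len(nrow(shapes)),
    intensity = as.integer(shapes$intensity),
    n_pixels = purrr::map_int(seq_len(nrow(shapes)), function(i) sum(owner == i))
  )
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(px), 0, noise_sd))
    px <- matrix(
      pmin(pmax(as.integer(round(px + noise)), 0L), as.integer(2^bit_depth - 1)),
      nrow = height
    )
  }
  img <- gray_image(px, bit_depth = bit_depth, pixel_spacing = pixel_spacing)
  attr(img, "ground_truth") <- counts
  img
}

#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8- or 16-bit container. By default the normalized values are
#' rescaled to the full target range; with `right_aligned = TRUE` the raw
#' 16-bit integers are reinterpreted directly as right-aligned `bit_depth`
#' data (e.g. 12-bit scans stored in 16-bit containers).
#'
#' @param path Image file (.png, .tif or .tiff).
#' @param bit_depth Target bit depth of the data (default 12).
#' @param pixel_spacing Physical pixel size in cm.
#' @param right_aligned Treat the container's integers as already on the
#'   `bit_depth` scale rather than spanning the container range.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, bit_depth = 12L, pixel_spacing = 0.01,
                            right_aligned = FALSE) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) abort("Package 'png' is required to read PNG files.")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) abort("Package 'tiff' is required to read TIFF files.")
    tiff::readTIFF(path)
  } else {
    abort("Unsupported image format; use PNG or TIFF.")
  }
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L] # first channel of grayscale-as-RGB
  px <- if (right_aligned) {
    pmin(round(arr * 65535), 2^bit_depth - 1)
  } else {
    round(arr * (2^bit_depth - 1))
  }
  gray_image(px, bit_depth = bit_depth, pixel_spacing = pixel_spacing)
}
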