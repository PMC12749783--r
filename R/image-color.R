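# Representative-color extraction from image patches: per-channel median of
# the 8-bit RGB pixels, then the CIELAB/ITA conversion chain. Matches the
# extraction order used for dermoscopy imagery: median first, convert after.

#' Construct an image patch
#'
#' A patch is a grid of 8-bit RGB pixels with an optional logical inclusion
#' mask (`TRUE` = pixel participates in color extraction). Masking supports
#' excluding dermoscopy artifacts such as dark corners or stickers; by
#' default every pixel is included.
#'
#' @param pixels An `h x w x 3` array of integer channel values in
#'   `[0, 255]`.
#' @param mask Optional `h x w` logical matrix; `NULL` includes all pixels.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, mask = NULL) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_tonescale("pixels must be an h x w x 3 array", "invalid_patch")
  }
  if (any(dim(pixels)[1:2] == 0L)) {
    stop_tonescale("patch grid must be non-empty", "invalid_patch")
  }
  if (any(pixels < 0) || any(pixels > 255) || any(pixels != round(pixels))) {
    stop_tonescale("pixel channels must be integers in [0, 255]",
                   "invalid_patch")
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pixels)[1:2]) || !is.logical(mask)) {
      stop_tonescale("mask must be a logical h x w matrix", "invalid_patch")
    }
    if (!any(mask)) {
      stop_tonescale("mask excludes every pixel", "empty_mask")
    }
  }
  structure(list(pixels = pixels, mask = mask), class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  d <- dim(x$pixels)
  n_in <- if (is.null(x$mask)) d[1] * d[2] else sum(x$mask)
  cat(sprintf("<image_patch> %d x %d px, %d included\n", d[1], d[2], n_in))
  invisible(x)
}

# Even-count median on integers: midpoint of the two central values, rounded
# half away from zero (round() in R rounds half to even, so do it by hand).
.median_int <- function(x) {
  m <- stats::median(x)
  sign(m) * floor(abs(m) + 0.5)
}

#' Median pixel-wise RGB color of a patch
#'
#' Computes the per-channel (marginal) median over included pixels on the
#' 8-bit integer scale, before any linearization. Even pixel counts use the
#' midpoint of the two central values, rounded half away from zero.
#'
#' @param img An [image_patch()].
#' @return Length-3 integer vector `(r, g, b)`.
#' @export
median_rgb <- function(img) {
  stopifnot(inherits(img, "image_patch"))
  px <- img$pixels
  keep <- if (is.null(img$mask)) rep(TRUE, prod(dim(px)[1:2])) else as.vector(img$mask)
  if (!any(keep)) stop_tonescale("no pixels included", "empty_mask")
  out <- vapply(1:3, function(ch) {
    v <- as.vector(px[, , ch])[keep]
    .median_int(v)
  }, numeric(1))
  out <- pmin(pmax(out, 0), 255)
  names(out) <- c("r", "g", "b")
  out
}

#' ITA of an image patch
#'
#' The individual typology angle of the patch's median RGB color:
#' `ita_from_lab(rgb_to_lab(median_rgb(img)))`. Near-neutral median colors
#' (gray patches) raise `tonescale_degenerate_chromaticity`.
#'
#' @inheritParams median_rgb
#' @param b_floor Passed to [ita_from_lab()].
#' @return Angle in degrees.
#' @export
image_ita <- function(img, b_floor = 1e-6) {
  ita_from_lab(rgb_to_lab(median_rgb(img)), b_floor = b_floor)
}

#' Read an image file as a patch
#'
#' Reads PNG or JPEG into an [image_patch()]; 16-bit or grayscale input is
#' rescaled/expanded to 8-bit RGB. An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [image_patch()].
#' @export
read_patch <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop_tonescale("the jpeg package is required to read JPEG files",
                       "missing_dependency")
      }
      jpeg::readJPEG(path)
    },
    stop_tonescale(sprintf("unsupported image format '%s'", ext),
                   "unsupported_format")
  )
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (dim(arr)[3] == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
  image_patch(round(arr * 255))
}

#' Write a patch as PNG
#'
#' @param img An [image_patch()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_patch <- function(img, path) {
  stopifnot(inherits(img, "image_patch"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' Batch ITA extraction over a directory of images
#'
#' Applies [median_rgb()] and [image_ita()] to every PNG/JPEG in a directory,
#' returning one row per image: path, median channels, CIELAB values and ITA.
#' Patches whose median color is neutral get `NA` ITA.
#'
#' @param dir Directory containing image files.
#' @param pattern Filename regexp, default PNG/JPEG extensions.
#' @return A tibble with columns `path`, `r`, `g`, `b`, `L`, `a`, `b_star`,
#'   `ita`.
#' @export
extract_ita_dir <- function(dir, pattern = "\\.(png|jpe?g)$") {
  files <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    med <- median_rgb(read_patch(f))
    lab <- rgb_to_lab(med)
    ita <- tryCatch(ita_from_lab(lab),
                    tonescale_degenerate_chromaticity = function(e) NA_real_)
    tibble::tibble(path = f, r = med[1], g = med[2], b = med[3],
                   L = lab[1, "L"], a = lab[1, "a"], b_star = lab[1, "b"],
                   ita = ita)
  })
  dplyr::bind_rows(rows)
}
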