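# sRGB (IEC 61966-2-1) <-> CIELAB conversion chain and the individual
# typology angle. D65 white, 2 degree observer. All functions are pure and
# vectorised over rows/elements.

# sRGB -> XYZ matrix (linear light, D65). The reference white is taken as the
# row sums so that (1,1,1) maps exactly to L*=100, a*=b*=0.
.srgb_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.white_xyz <- rowSums(.srgb_xyz)

.check_rgb8 <- function(rgb) {
  rgb <- as_rgb_matrix(rgb)
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    stop_tonescale("RGB channels must be finite values in [0, 255]",
                   "invalid_rgb")
  }
  if (any(rgb != round(rgb))) {
    stop_tonescale("8-bit RGB channels must be integers", "invalid_rgb")
  }
  rgb
}

# Accept a length-3 vector or an n x 3 matrix; always return an n x 3 matrix.
as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) {
      stop_tonescale("an RGB color is 3 channel values", "invalid_rgb")
    }
    rgb <- matrix(as.numeric(rgb), nrow = 1L)
  } else {
    rgb <- as.matrix(rgb)
    storage.mode(rgb) <- "double"
    if (ncol(rgb) != 3L) {
      stop_tonescale("an RGB matrix needs 3 columns", "invalid_rgb")
    }
  }
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Decode 8-bit sRGB channels to linear-light reflectance
#'
#' Applies the IEC 61966-2-1 piecewise electro-optical transfer function to
#' 8-bit sRGB channel values, mapping 0 to 0 and 255 to 1.
#'
#' @param rgb A length-3 integer vector `(r, g, b)` in `[0, 255]`, or an
#'   `n x 3` matrix of such rows.
#' @return A matrix of the same shape with linear-light values in `[0, 1]`.
#' @examples
#' srgb_to_linear(c(118, 118, 118)) # mid gray, ~0.1845
#' @export
srgb_to_linear <- function(rgb) {
  rgb <- .check_rgb8(rgb)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  dimnames(lin) <- dimnames(rgb)
  lin
}

# Inverse transfer function: linear light in [0,1] -> 8-bit sRGB.
linear_to_srgb <- function(lin) {
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, lin * 12.92, 1.055 * lin^(1 / 2.4) - 0.055)
  round(v * 255)
}

#' Linear sRGB to XYZ tristimulus values
#'
#' Linear map under the sRGB primaries with D65 white; `(1,1,1)` maps to the
#' D65 reference white (X ~ 0.9505, Y = 1, Z ~ 1.0888).
#'
#' @param rgb_linear Length-3 vector or `n x 3` matrix of linear-light values
#'   in `[0, 1]`.
#' @return Matrix with columns X, Y, Z.
#' @export
linear_to_xyz <- function(rgb_linear) {
  if (is.null(dim(rgb_linear))) rgb_linear <- matrix(rgb_linear, nrow = 1L)
  xyz <- rgb_linear %*% t(.srgb_xyz)
  colnames(xyz) <- c("X", "Y", "Z")
  xyz
}

xyz_to_linear <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lin <- xyz %*% t(solve(.srgb_xyz))
  colnames(lin) <- c("r", "g", "b")
  lin
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' XYZ to CIELAB
#'
#' Standard CIE 1976 L*a*b* against the D65 white point. The white point maps
#' to `(100, 0, 0)`; black to `(0, 0, 0)`.
#'
#' @param xyz Length-3 vector or `n x 3` matrix of nonnegative tristimulus
#'   values.
#' @return Matrix with columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (any(xyz < -1e-12)) {
    stop_tonescale("tristimulus values must be nonnegative", "invalid_xyz")
  }
  fx <- .lab_f(pmax(xyz[, 1], 0) / .white_xyz[1])
  fy <- .lab_f(pmax(xyz[, 2], 0) / .white_xyz[2])
  fz <- .lab_f(pmax(xyz[, 3], 0) / .white_xyz[3])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  lab
}

lab_to_xyz <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1L)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(X = .lab_f_inv(fx) * .white_xyz[1],
               Y = .lab_f_inv(fy) * .white_xyz[2],
               Z = .lab_f_inv(fz) * .white_xyz[3])
  xyz
}

#' 8-bit sRGB to CIELAB
#'
#' Composition of [srgb_to_linear()], [linear_to_xyz()] and [xyz_to_lab()]:
#' the conversion chain used when extracting skin color from standard RGB
#' imagery. Grays map onto the neutral axis (`a = b = 0`).
#'
#' @inheritParams srgb_to_linear
#' @return Matrix with columns `L`, `a`, `b` (one row per input color).
#' @examples
#' rgb_to_lab(c(255, 255, 255)) # L = 100
#' @export
rgb_to_lab <- function(rgb) {
  xyz_to_lab(linear_to_xyz(srgb_to_linear(rgb)))
}

#' CIELAB to 8-bit sRGB
#'
#' Inverse of [rgb_to_lab()] up to 8-bit quantization; out-of-gamut linear
#' values are clipped to `[0, 1]` before encoding.
#'
#' @param lab Length-3 vector `(L, a, b)` or `n x 3` matrix.
#' @return Integer matrix with columns `r`, `g`, `b` in `[0, 255]`.
#' @export
lab_to_rgb <- function(lab) {
  lin <- xyz_to_linear(lab_to_xyz(lab))
  rgb <- linear_to_srgb(lin)
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Individual typology angle (ITA) from CIELAB
#'
#' `ITA = atan((L - 50) / b) * 180 / pi`, in degrees. Larger angles
#' correspond to lighter skin. The plain arctangent is used (not `atan2`), so
#' a negative `b` flips the sign of the angle; near-neutral colors with
#' `|b|` below `b_floor` have no meaningful hue angle and raise a
#' `tonescale_degenerate_chromaticity` error rather than returning +/-90.
#'
#' @param lab Length-3 vector `(L, a, b)` or `n x 3` matrix (column `a` may
#'   be omitted: a 2-column matrix is read as `(L, b)`).
#' @param b_floor Minimum `|b|` for the angle to be defined. Default `1e-6`.
#' @return Numeric vector of angles in degrees, in `(-90, 90)`.
#' @examples
#' ita_from_lab(c(70, 5, 20)) # 45 degrees
#' @export
ita_from_lab <- function(lab, b_floor = 1e-6) {
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1L)
  L <- lab[, 1]
  b <- lab[, ncol(lab)]
  if (any(abs(b) < b_floor)) {
    stop_tonescale(
      "ITA is undefined for near-neutral colors (|b*| below floor)",
      "degenerate_chromaticity"
    )
  }
  atan((L - 50) / b) * 180 / pi
}
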