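#' Elliptical phantom specification
#'
#' Describes a set of elliptical (or circular) signal sources on the centred
#' normalized grid, standing in for the cylindrical, spherical and dual glass
#' phantoms used on the bench: each shape has a centre in `[-1, 1)^2`
#' (readout, phase-encode), semi-axes in the same units, and a non-negative
#' intensity.
#'
#' @param shapes list of shapes, each a list/vector with elements
#'   `cx, cy, rx, ry, intensity` (normalized coords; intensity >= 0).
#' @param matrix integer vector `c(n_readout, n_pe)`.
#' @return an object of class `phantom_spec`.
#' @examples
#' # a single centred disk of radius 0.5, as used throughout the tests
#' ph <- phantom_spec(list(shape(0, 0, 0.5)), c(32, 32))
#' @export
phantom_spec <- function(shapes, matrix = c(32L, 32L)) {
  stopifnot(length(matrix) == 2, all(matrix >= 2), all(matrix %% 2 == 0))
  shapes <- lapply(shapes, function(s) {
    s <- as.list(s)
    stopifnot(all(c("cx", "cy", "rx", "ry", "intensity") %in% names(s)))
    if (s$intensity < 0) stop("shape intensities must be >= 0", call. = FALSE)
    if (abs(s$cx) + s$rx > 1 || abs(s$cy) + s$ry > 1)
      stop("shape extends beyond the FOV", call. = FALSE)
    s
  })
  structure(list(shapes = shapes, matrix = as.integer(matrix)),
            class = "phantom_spec")
}

#' Shorthand for one elliptical shape
#' @param cx,cy centre, normalized coordinates in `[-1, 1)`.
#' @param rx semi-axis along readout; `ry` defaults to `rx` (a disk).
#' @param ry semi-axis along phase-encode.
#' @param intensity non-negative signal level.
#' @return a named list usable in [phantom_spec()].
#' @export
shape <- function(cx, cy, rx, ry = rx, intensity = 1) {
  list(cx = cx, cy = cy, rx = rx, ry = ry, intensity = intensity)
}

#' Rasterize a phantom
#'
#' Deterministic: pixel (n, m) (0-based) has centre
#' `((n - N/2)/(N/2), (m - M/2)/(M/2))`; a pixel belongs to a shape when its
#' centre lies inside the ellipse. Overlapping shapes add.
#'
#' @param spec a [phantom_spec].
#' @return an [image_grid] with a real, non-negative image.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$matrix[1]; nc <- spec$matrix[2]
  xs <- centered_coord(nr); ys <- centered_coord(nc)
  img <- matrix(0, nr, nc)
  for (s in spec$shapes) {
    inside <- outer(((xs - s$cx) / s$rx)^2, ((ys - s$cy) / s$ry)^2, `+`) <= 1
    img <- img + s$intensity * inside
  }
  image_grid(img)
}

#' Object mask of a phantom
#' @param spec a [phantom_spec].
#' @return logical matrix, `TRUE` where any shape has signal.
#' @export
phantom_mask <- function(spec) magnitude(make_phantom(spec)) > 0

#' Stock phantoms
#'
#' `default_phantom()` is a centred disk (radius 0.5 of the half-FOV).
#' `dual_phantom()` emulates the bench configuration with one small and one
#' large disk at different phase-encode offsets. `tumour_phantom()` is an
#' off-centre ellipse resembling a subcutaneous tumour in the lower flank.
#'
#' @param matrix integer vector `c(n_readout, n_pe)`.
#' @return a [phantom_spec].
#' @export
default_phantom <- function(matrix = c(32L, 32L))
  phantom_spec(list(shape(0, 0, 0.5)), matrix)

#' @rdname default_phantom
#' @export
dual_phantom <- function(matrix = c(32L, 32L))
  phantom_spec(list(shape(-0.30, -0.35, 0.16, 0.16, 1.0),
                    shape(0.20, 0.25, 0.38, 0.38, 0.8)), matrix)

#' @rdname default_phantom
#' @export
tumour_phantom <- function(matrix = c(32L, 32L))
  phantom_spec(list(shape(0.15, -0.10, 0.42, 0.30, 1.0)), matrix)
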