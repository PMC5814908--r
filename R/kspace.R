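#' EPI k-space container
#'
#' Bundles a complex single-shot EPI k-space matrix with its acquisition
#' metadata. Rows index the readout (frequency-encode, x) axis and columns the
#' phase-encode lines, 0-based in acquisition order after standard odd-echo
#' time reversal, with the DC line at 0-based column `n_pe/2`. Partial-Fourier
#' acquisitions keep a contiguous block of acquired lines containing the DC
#' line; the remaining early lines are zero-filled.
#'
#' @param data complex matrix, `n_readout x n_pe`.
#' @param echo_spacing echo spacing in seconds (time between consecutive
#'   gradient echoes).
#' @param lines_before_center number of acquired lines preceding the ky = 0
#'   line. `n_pe/2` means a full acquisition.
#' @param acquired_mask logical vector, one flag per phase-encode line
#'   (`TRUE` = acquired). Defaults to the contiguous block implied by
#'   `lines_before_center` with a full tail.
#' @param nucleus `"C13"` or `"H1"`.
#' @param fov_readout readout field of view in metres.
#'
#' @return an object of class `epi_kspace`.
#' @examples
#' k <- epi_kspace(matrix(0i, 32, 32), echo_spacing = 552e-6,
#'                 lines_before_center = 4)
#' sum(k$acquired_mask)  # 20 of 32 lines = 62.5% of k-space
#' @export
epi_kspace <- function(data, echo_spacing = 552e-6,
                       lines_before_center = ncol(data) / 2,
                       acquired_mask = NULL,
                       nucleus = c("C13", "H1"),
                       fov_readout = 0.04) {
  if (!is.matrix(data)) stop("data must be a matrix", call. = FALSE)
  data[] <- as.complex(data)
  n_pe <- ncol(data)
  nucleus <- match.arg(nucleus)
  lines_before_center <- as.integer(lines_before_center)
  if (is.null(acquired_mask)) {
    first <- n_pe / 2 + 1L - lines_before_center
    if (first < 1L) stop("lines_before_center exceeds available early lines",
                         call. = FALSE)
    acquired_mask <- seq_len(n_pe) >= first
  }
  obj <- structure(list(
    data = data,
    echo_spacing = echo_spacing,
    acquired_mask = as.logical(acquired_mask),
    lines_before_center = lines_before_center,
    nucleus = nucleus,
    fov_readout = fov_readout
  ), class = "epi_kspace")
  validate_epi_kspace(obj)
}

validate_epi_kspace <- function(k) {
  n_pe <- ncol(k$data)
  if (length(k$acquired_mask) != n_pe)
    stop("acquired_mask length (", length(k$acquired_mask),
         ") does not match n_pe (", n_pe, ")", call. = FALSE)
  acq <- which(k$acquired_mask)
  if (length(acq) == 0L) stop("no acquired lines", call. = FALSE)
  if (!all(diff(acq) == 1L))
    stop("acquired lines must form one contiguous block", call. = FALSE)
  dc <- n_pe / 2 + 1L
  if (!(dc %in% acq))
    stop("acquired block must contain the ky = 0 line", call. = FALSE)
  if (dc - min(acq) != k$lines_before_center)
    stop("lines_before_center (", k$lines_before_center,
         ") inconsistent with acquired_mask (", dc - min(acq), " before centre)",
         call. = FALSE)
  if (!is.finite(k$echo_spacing) || k$echo_spacing <= 0)
    stop("echo_spacing must be positive", call. = FALSE)
  k
}

#' @export
print.epi_kspace <- function(x, ...) {
  cat(sprintf("<epi_kspace> %d x %d, %d/%d lines acquired (%.1f%%), %s, echo spacing %.0f us\n",
              nrow(x$data), ncol(x$data), sum(x$acquired_mask), ncol(x$data),
              100 * mean(x$acquired_mask), x$nucleus, x$echo_spacing * 1e6))
  invisible(x)
}

#' Fraction of k-space acquired
#'
#' With a 32-line matrix and 4 lines before centre (full tail), 20 of 32 lines
#' are acquired, i.e. 62.5% of k-space.
#'
#' @param k an [epi_kspace].
#' @return acquired fraction in percent.
#' @export
kspace_fraction <- function(k) {
  stopifnot(inherits(k, "epi_kspace"))
  100 * sum(k$acquired_mask) / length(k$acquired_mask)
}

#' Complex reconstructed image on a centred grid
#'
#' Holds a complex image with the same orientation as [epi_kspace] after the 2D
#' transform. Index n (0-based) on either axis maps to the centred normalized
#' coordinate `(n - N/2)/(N/2)` in `[-1, 1)`; the phase-encode matrix size `N`
#' makes the half-FOV ghost a circular shift by exactly `N/2` pixels.
#'
#' @param data complex (or real) matrix, `n_readout x n_pe`.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(data) {
  if (!is.matrix(data)) stop("data must be a matrix", call. = FALSE)
  data[] <- as.complex(data)
  structure(list(data = data, N = ncol(data)), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d complex, N = %d\n",
              nrow(x$data), ncol(x$data), x$N))
  invisible(x)
}

#' Magnitude view of an image
#' @param img an [image_grid] or complex/numeric matrix.
#' @return numeric matrix of magnitudes.
#' @export
magnitude <- function(img) {
  if (inherits(img, "image_grid")) img <- img$data
  Mod(img)
}

as_image_matrix <- function(img) {
  if (inherits(img, "image_grid")) img$data else {
    if (!is.matrix(img)) stop("expected a matrix or image_grid", call. = FALSE)
    m <- img; m[] <- as.complex(m); m
  }
}

#' Forward-transform an image into a fully-sampled EPI k-space
#'
#' Convenience inverse of [reconstruct()] for building test and simulation
#' inputs: applies the centred 2D Fourier transform and wraps the result with
#' acquisition metadata (full sampling unless `lines_before_center` says
#' otherwise; unacquired lines are zeroed).
#'
#' @param img an [image_grid] or matrix.
#' @inheritParams epi_kspace
#' @return an [epi_kspace].
#' @export
forward_kspace <- function(img, echo_spacing = 552e-6,
                           lines_before_center = NULL,
                           nucleus = "C13", fov_readout = 0.04) {
  m <- as_image_matrix(img)
  if (is.null(lines_before_center)) lines_before_center <- ncol(m) / 2
  k <- epi_kspace(ft2(m), echo_spacing = echo_spacing,
                  lines_before_center = lines_before_center,
                  nucleus = nucleus, fov_readout = fov_readout)
  k$data[, !k$acquired_mask] <- 0i
  k
}
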