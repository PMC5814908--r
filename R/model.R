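#' Apply the odd/even alternating phase error to a k-space
#'
#' Forward model of EPI Nyquist ghosting: in x-ky hybrid space (1D inverse
#' transform of each line along the readout axis) line `j` is multiplied by
#' `exp(+i * (-1)^j * theta(x))` with `theta(x) = alpha + beta * x`, then
#' transformed back to k-space. Even 0-based lines carry `+theta`. Zero-filled
#' lines remain zero. Pure phase multiplication: the k-space 2-norm is
#' preserved exactly.
#'
#' @param k an [epi_kspace] holding an uncorrupted (ideal) k-space.
#' @param c a [phase_coeffs].
#' @return an [epi_kspace] with the corruption applied.
#' @export
apply_phase_error <- function(k, c) {
  stopifnot(inherits(k, "epi_kspace"), inherits(c, "phase_coeffs"))
  validate_epi_kspace(k)
  k$data <- apply_line_phase(k$data, c, sign = +1)
  k$data[, !k$acquired_mask] <- 0i
  k
}

# Multiply hybrid-space line j by exp(sign * i * (-1)^j * theta(x)).
apply_line_phase <- function(data, c, sign) {
  nr <- nrow(data); nc <- ncol(data)
  th <- theta_matrix(c, nr, nc)
  pol <- matrix(line_polarity(nc), nr, nc, byrow = TRUE)
  h <- ift_readout(data)
  ft_readout(h * exp(1i * sign * pol * th))
}

#' Reconstruct an image from an EPI k-space
#'
#' Zero-fills any unacquired lines (the partial-Fourier choice used
#' throughout: no conjugate synthesis) and applies the centred 2D inverse
#' Fourier transform.
#'
#' @param k an [epi_kspace].
#' @return an [image_grid] (complex; use [magnitude()] for display).
#' @export
reconstruct <- function(k) {
  stopifnot(inherits(k, "epi_kspace"))
  validate_epi_kspace(k)
  d <- k$data
  d[, !k$acquired_mask] <- 0i
  image_grid(ift2(d))
}

#' Closed-form Nyquist ghost image
#'
#' Analytic oracle for the alternating phase error on a fully sampled
#' k-space: given the ideal image `rho` and `theta(x) = alpha + beta * x`,
#' the reconstructed image is
#' `rho(x, y) * cos(theta(x)) + i * rho(x, y - N/2) * sin(theta(x))`,
#' i.e. the ideal image splits into a real copy in place and an imaginary
#' copy displaced by half the field of view in the phase-encode direction.
#' Agrees with `reconstruct(apply_phase_error(...))` to floating-point
#' round-off on full k-space.
#'
#' @param img an [image_grid] holding the ideal (uncorrupted) image.
#' @param c a [phase_coeffs].
#' @return an [image_grid] with the predicted ghosted image.
#' @export
closed_form_ghost <- function(img, c) {
  stopifnot(inherits(c, "phase_coeffs"))
  m <- as_image_matrix(img)
  check_even_dims(m)
  th <- c$alpha + c$beta * centered_coord(nrow(m))
  out <- m * cos(th) + 1i * shift_half_fov_pe(m) * sin(th)
  image_grid(out)
}

#' Phase-correct a k-space and reconstruct
#'
#' Multiplies hybrid-space line `j` by `exp(-i * (-1)^j * theta)` — the
#' conjugate of the corruption phase — and reconstructs. Accepts a single
#' coefficient pair, per-line pairs (reference-scan estimates), or the 2D
#' model in which `theta = theta_col(x) + beta_y * j_centred`. Correcting
#' with the true coefficients on a noiseless k-space restores the ideal
#' (zero-filled, for partial acquisitions) image to floating-point tolerance.
#'
#' @param k an [epi_kspace].
#' @param c a [phase_coeffs], [per_line_coeffs] or [coeffs_2d].
#' @return an [image_grid].
#' @export
correct_with_coeffs <- function(k, c) {
  stopifnot(inherits(k, "epi_kspace"))
  validate_epi_kspace(k)
  d <- k$data
  d[, !k$acquired_mask] <- 0i
  d <- apply_line_phase(d, c, sign = -1)
  d[, !k$acquired_mask] <- 0i
  image_grid(ift2(d))
}
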