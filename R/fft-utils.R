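# Centred Fourier transform helpers. All image/k-space matrices in this package
# are n_readout x n_pe with DC at the matrix centre (0-based index n/2), so a
# half-FOV ghost is a circular shift by exactly n_pe/2 columns. Matrix sizes are
# required to be even; for even n, fftshift is its own inverse.

swap_idx <- function(n) c((n %/% 2 + 1L):n, 1L:(n %/% 2))

fftshift2 <- function(m) m[swap_idx(nrow(m)), swap_idx(ncol(m)), drop = FALSE]

check_even_dims <- function(m) {
  if (nrow(m) %% 2L != 0L || ncol(m) %% 2L != 0L)
    stop("matrix dimensions must be even (DC-at-centre convention)", call. = FALSE)
  invisible(m)
}

#' @noRd
ft2 <- function(img) {
  check_even_dims(img)
  fftshift2(stats::fft(fftshift2(img)))
}

#' @noRd
ift2 <- function(k) {
  check_even_dims(k)
  fftshift2(stats::fft(fftshift2(k), inverse = TRUE)) / length(k)
}

# 1D inverse transform along the readout axis (rows) of every phase-encode
# column: k-space -> x-ky hybrid space, where EPI phase errors are separable.
ift_readout <- function(k) {
  check_even_dims(k)
  sh <- swap_idx(nrow(k))
  h <- stats::mvfft(k[sh, , drop = FALSE], inverse = TRUE) / nrow(k)
  h[sh, , drop = FALSE]
}

ft_readout <- function(h) {
  check_even_dims(h)
  sh <- swap_idx(nrow(h))
  k <- stats::mvfft(h[sh, , drop = FALSE])
  k[sh, , drop = FALSE]
}

# 1D inverse transform of a single k-space line (vector) along readout.
ift_line <- function(v) {
  n <- length(v)
  sh <- swap_idx(n)
  h <- stats::fft(v[sh], inverse = TRUE) / n
  h[sh]
}

# Centred normalized coordinate for 1-based index i of n samples:
# 0-based index n0 maps to (n0 - n/2)/(n/2), covering [-1, 1).
centered_coord <- function(n) ((seq_len(n) - 1L) - n / 2) / (n / 2)

# Alternating line polarity: +1 on even 0-based column indices.
line_polarity <- function(n_pe) rep_len(c(1, -1), n_pe)

# Circular shift by half the field of view along the phase-encode axis
# (columns). Self-inverse for even n_pe.
shift_half_fov_pe <- function(m) m[, swap_idx(ncol(m)), drop = FALSE]

# Same along the frequency-encode (readout) axis.
shift_half_fov_ro <- function(m) m[swap_idx(nrow(m)), , drop = FALSE]
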