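#' Phase-error coefficients
#'
#' The EPI odd/even phase error is modelled as `theta(x) = alpha + beta * x`
#' with `x` the centred normalized readout coordinate in `[-1, 1)`: `alpha` is
#' the zero-order error (radians, e.g. a B0 shift induced by a gradient pulse)
#' and `beta` the first-order error (radians at the readout FOV edge, from
#' readout-direction eddy currents and group delays). The error alternates in
#' sign between even and odd phase-encode lines, producing the half-FOV
#' Nyquist ghost.
#'
#' Since the magnitude image is invariant under `theta -> theta + pi`, `alpha`
#' is canonicalized into `(-pi/2, pi/2]`. `beta + pi` is not a model symmetry
#' (it would add `pi * x` to the error), so `beta` is never wrapped.
#'
#' @param alpha zero-order phase error, radians.
#' @param beta first-order phase error, radians per normalized readout
#'   coordinate (i.e. phase at the FOV edge).
#' @param canonicalize wrap `alpha` into `(-pi/2, pi/2]`? Default `TRUE`.
#' @return an object of class `phase_coeffs`.
#' @examples
#' phase_coeffs(0.25, 0.40)
#' phase_coeffs(0.25 + pi, 0.40)$alpha  # 0.25 after canonicalization
#' @export
phase_coeffs <- function(alpha, beta, canonicalize = TRUE) {
  stopifnot(is.finite(alpha), is.finite(beta))
  if (canonicalize) alpha <- wrap_half_pi(alpha)
  structure(list(alpha = alpha, beta = beta), class = "phase_coeffs")
}

# Map into (-pi/2, pi/2] by adding multiples of pi.
wrap_half_pi <- function(v) pi / 2 - ((pi / 2 - v) %% pi)

#' Default simulated corruption
#'
#' The phase-error pair used as the simulator's study condition:
#' `(alpha, beta) = (0.56, 0.86)` rad, chosen once so that a noiseless
#' regular-FOV disk-phantom acquisition shows an uncorrected ghosting level
#' of about 63%, matching the severity the correction methods are expected
#' to handle.
#'
#' @return a [phase_coeffs].
#' @export
default_corruption <- function() phase_coeffs(0.56, 0.86, canonicalize = FALSE)

#' Canonicalize phase coefficients
#'
#' Wraps the zero-order term into `(-pi/2, pi/2]` using the pi-periodicity of
#' the phase error (a global pi shift flips the sign of both `cos` and `sin`
#' in the ghost model, leaving the magnitude image unchanged).
#'
#' @param c a [phase_coeffs].
#' @return a [phase_coeffs] with `alpha` in `(-pi/2, pi/2]`.
#' @export
canonicalize_coeffs <- function(c) {
  stopifnot(inherits(c, "phase_coeffs"))
  phase_coeffs(c$alpha, c$beta, canonicalize = TRUE)
}

#' @export
print.phase_coeffs <- function(x, ...) {
  cat(sprintf("<phase_coeffs> alpha = %.6f rad, beta = %.6f rad/FOV-edge\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Per-line phase-error coefficients
#'
#' One `(alpha, beta)` pair per phase-encode line, as produced by
#' reference-scan estimation where coefficients are calculated for each line
#' in the phase-encoding direction.
#'
#' @param alpha_j,beta_j numeric vectors of equal length `n_pe`.
#' @return an object of class `per_line_coeffs`.
#' @export
per_line_coeffs <- function(alpha_j, beta_j) {
  stopifnot(length(alpha_j) == length(beta_j),
            all(is.finite(alpha_j)), all(is.finite(beta_j)))
  structure(list(alpha_j = as.numeric(alpha_j), beta_j = as.numeric(beta_j)),
            class = "per_line_coeffs")
}

#' @export
print.per_line_coeffs <- function(x, ...) {
  cat(sprintf("<per_line_coeffs> %d lines, alpha in [%.4f, %.4f], beta in [%.4f, %.4f]\n",
              length(x$alpha_j), min(x$alpha_j), max(x$alpha_j),
              min(x$beta_j), max(x$beta_j)))
  invisible(x)
}

#' Mean of per-line coefficients
#' @param c a [per_line_coeffs].
#' @param lines optional subset of 1-based line indices to average over.
#' @return a [phase_coeffs] with the averaged pair.
#' @export
average_coeffs <- function(c, lines = NULL) {
  stopifnot(inherits(c, "per_line_coeffs"))
  if (is.null(lines)) lines <- seq_along(c$alpha_j)
  phase_coeffs(mean(c$alpha_j[lines]), mean(c$beta_j[lines]),
               canonicalize = FALSE)
}

#' Two-dimensional phase-error coefficients
#'
#' Extends the 1D model with a first-order term along the phase-encode (y)
#' direction: the correction phase for line `j` is
#' `theta_col[x] + beta_y * j_centred` where `theta_col` holds one scalar
#' phase per readout position (subsuming `alpha + beta * x`) and `j_centred`
#' is the centred normalized line index.
#'
#' @param theta_col numeric vector, one phase (radians) per readout position.
#' @param beta_y radians per normalized phase-encode line index.
#' @param flagged_rows optional 1-based readout indices whose `theta_col` was
#'   not locally determined (empty ghost-band intersection) and inherited the
#'   global 1D solution.
#' @return an object of class `coeffs_2d`.
#' @export
coeffs_2d <- function(theta_col, beta_y, flagged_rows = integer(0)) {
  stopifnot(all(is.finite(theta_col)), is.finite(beta_y))
  structure(list(theta_col = as.numeric(theta_col), beta_y = beta_y,
                 flagged_rows = as.integer(flagged_rows)),
            class = "coeffs_2d")
}

#' @export
print.coeffs_2d <- function(x, ...) {
  cat(sprintf("<coeffs_2d> %d readout phases in [%.4f, %.4f], beta_y = %.4f (%d flagged rows)\n",
              length(x$theta_col), min(x$theta_col), max(x$theta_col),
              x$beta_y, length(x$flagged_rows)))
  invisible(x)
}

# Correction phase matrix theta(x, j), n_readout x n_pe, for any coefficient
# container. The signed (parity-carrying) phase is applied elsewhere.
theta_matrix <- function(c, n_readout, n_pe) {
  xn <- centered_coord(n_readout)
  if (inherits(c, "phase_coeffs")) {
    matrix(c$alpha + c$beta * xn, n_readout, n_pe)
  } else if (inherits(c, "per_line_coeffs")) {
    if (length(c$alpha_j) != n_pe)
      stop("per_line_coeffs length (", length(c$alpha_j),
           ") does not match n_pe (", n_pe, ")", call. = FALSE)
    outer(xn, c$beta_j) + matrix(c$alpha_j, n_readout, n_pe, byrow = TRUE)
  } else if (inherits(c, "coeffs_2d")) {
    if (length(c$theta_col) != n_readout)
      stop("coeffs_2d theta_col length (", length(c$theta_col),
           ") does not match n_readout (", n_readout, ")", call. = FALSE)
    jn <- centered_coord(n_pe)
    matrix(c$theta_col, n_readout, n_pe) +
      matrix(c$beta_y * jn, n_readout, n_pe, byrow = TRUE)
  } else stop("unsupported coefficient container", call. = FALSE)
}
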