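# Reference-based coefficient estimators. All of them exploit the same
# algebra: with phase-encoding off, adjacent hybrid-space lines differ in
# phase by exactly 2*theta(x) (with alternating sign), so a 1D unwrap along
# the readout followed by a line fit recovers (alpha, beta).

# Estimate theta(x) = alpha + beta*x from one adjacent line pair in hybrid
# space. `sgn` is the polarity of the phase difference: Arg(h2 * Conj(h1)) =
# sgn * 2 * theta(x). Returns c(alpha, beta).
fit_pair_theta <- function(h1, h2, sgn, fit_mask_threshold = 0.1) {
  prod <- h2 * Conj(h1)
  mag <- sqrt(Mod(h1) * Mod(h2))
  if (max(mag) == 0) stop("reference lines have zero magnitude", call. = FALSE)
  uw <- phase_unwrap_1d(prod)
  u <- uw$phase
  # anchor the 2*pi-ambiguous offset at the most reliable sample
  i0 <- which.max(mag)
  u <- u - u[i0] + Arg(prod[i0])
  theta <- sgn * u / 2
  keep <- mag > fit_mask_threshold * max(mag) & !uw$carried
  if (sum(keep) < 2) stop("too few samples above the fit threshold", call. = FALSE)
  xn <- centered_coord(length(h1))
  fit <- stats::lm.wfit(cbind(1, xn[keep]), theta[keep], w = mag[keep])
  unname(fit$coefficients)
}

#' Estimate per-line coefficients from a reference scan
#'
#' Takes an EPI acquisition with the phase-encode gradients turned off,
#' 1D-transforms each line along the readout, forms the inter-line phase
#' difference of every adjacent acquired pair (equal to `2*theta(x)` under the
#' alternating-error model), unwraps it with [phase_unwrap_1d()], restricts
#' and magnitude-weights the linear fit to samples whose projection magnitude
#' exceeds `fit_mask_threshold` of the maximum, and assigns the fitted
#' `(alpha, beta)` per line. Lines outside the acquired block (and the first
#' acquired line, which has no preceding pair) inherit the nearest estimate.
#'
#' @param ref an [epi_kspace] acquired with phase-encoding off
#'   (see [acquire_reference()]).
#' @param fit_mask_threshold fraction of the maximum projection magnitude
#'   below which samples are excluded from the fit.
#' @return a [per_line_coeffs] of length `n_pe`.
#' @export
estimate_from_reference <- function(ref, fit_mask_threshold = 0.1) {
  stopifnot(inherits(ref, "epi_kspace"))
  acq <- which(ref$acquired_mask)
  if (length(acq) < 2) stop("need at least 2 acquired reference lines", call. = FALSE)
  h <- ift_readout(ref$data)
  n_pe <- ncol(ref$data)
  alpha_j <- rep(NA_real_, n_pe); beta_j <- rep(NA_real_, n_pe)
  for (i in seq_len(length(acq) - 1L)) {
    c1 <- acq[i]; c2 <- acq[i + 1L]
    j <- c1 - 1L                       # 0-based index of the first line in pair
    sgn <- if (j %% 2L == 0L) -1 else 1   # Arg(h2*Conj(h1)) = (-1)^(j+1) * 2 theta
    ab <- fit_pair_theta(h[, c1], h[, c2], sgn, fit_mask_threshold)
    alpha_j[c2] <- ab[1]; beta_j[c2] <- ab[2]
  }
  alpha_j[acq[1]] <- alpha_j[acq[2]]; beta_j[acq[1]] <- beta_j[acq[2]]
  # unacquired (zero-filled) lines inherit the nearest acquired estimate
  filled <- which(!is.na(alpha_j))
  for (idx in which(is.na(alpha_j))) {
    nearest <- filled[which.min(abs(filled - idx))]
    alpha_j[idx] <- alpha_j[nearest]; beta_j[idx] <- beta_j[nearest]
  }
  per_line_coeffs(wrap_half_pi(alpha_j), beta_j)
}

#' Estimate averaged coefficients from integrated reference echoes
#'
#' Applies the adjacent-pair estimator of [estimate_from_reference()] to the
#' prepended non-phase-encoded echoes and averages the per-pair estimates
#' into a single `(alpha, beta)` pair, which is then applied to all
#' phase-encoding lines. Pure magnitude decay (T2*) between echoes carries no
#' phase and does not bias the estimate.
#'
#' @param echoes complex `n_readout x n_echoes` matrix of ky = 0 k-space
#'   lines (see [acquire_integrated_echoes()]), first echo having even (+)
#'   polarity.
#' @param fit_mask_threshold as in [estimate_from_reference()].
#' @return a [phase_coeffs].
#' @export
estimate_from_integrated_echoes <- function(echoes, fit_mask_threshold = 0.1) {
  stopifnot(is.matrix(echoes))
  n_echoes <- ncol(echoes)
  if (n_echoes < 2) stop("need at least 2 reference echoes", call. = FALSE)
  h <- vapply(seq_len(n_echoes), function(e) ift_line(echoes[, e]),
              complex(nrow(echoes)))
  est <- vapply(seq_len(n_echoes - 1L), function(e) {
    sgn <- if ((e - 1L) %% 2L == 0L) -1 else 1
    fit_pair_theta(h[, e], h[, e + 1L], sgn, fit_mask_threshold)
  }, numeric(2))
  phase_coeffs(wrap_half_pi(mean(est[1, ])), mean(est[2, ]))
}

#' Rescale reference coefficients to another nucleus
#'
#' Phase errors measured on a 1H reference scan must be corrected for the
#' difference in gyromagnetic ratios before being applied to 13C images:
#' `alpha` scales by `gamma_ratio = gamma_target / gamma_reference`, and
#' `beta` — expressed per normalized readout-FOV coordinate — additionally
#' divides by `fov_ratio = FOV_reference / FOV_target`. With the same readout
#' gradient the 1H FOV is about one quarter (gamma_13C / gamma_1H) of the 13C
#' FOV, so the two scalings nearly cancel for `beta`
#' (0.2515 / 0.25 = 1.006).
#'
#' @param c a [phase_coeffs] or [per_line_coeffs] measured on the reference
#'   nucleus.
#' @param gamma_ratio target/reference gyromagnetic ratio (> 0).
#' @param fov_ratio reference/target readout FOV ratio (> 0).
#' @return rescaled coefficients of the same class.
#' @export
scale_reference_coeffs <- function(c, gamma_ratio, fov_ratio = 1) {
  if (!is.finite(gamma_ratio) || gamma_ratio <= 0 ||
      !is.finite(fov_ratio) || fov_ratio <= 0)
    stop("gamma_ratio and fov_ratio must be positive", call. = FALSE)
  if (inherits(c, "phase_coeffs")) {
    phase_coeffs(c$alpha * gamma_ratio, c$beta * gamma_ratio / fov_ratio,
                 canonicalize = FALSE)
  } else if (inherits(c, "per_line_coeffs")) {
    per_line_coeffs(c$alpha_j * gamma_ratio, c$beta_j * gamma_ratio / fov_ratio)
  } else stop("unsupported coefficient container", call. = FALSE)
}
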