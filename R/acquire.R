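#' Acquisition parameters for the EPI simulator
#'
#' Collects the ground-truth corruption and sequence settings used by
#' [acquire_epi()] and friends. Defaults mirror the single-shot 13C protocol
#' the package targets: a 32 x 32 matrix with only 4 lines acquired before the
#' k-space centre (20 bipolar readouts, 62.5% of k-space) and a 552 us echo
#' spacing.
#'
#' @param coeffs a [phase_coeffs]: the true corruption. The default,
#'   [default_corruption()], reproduces the uncorrected ghosting level of a
#'   regular-FOV phantom acquisition (about 63%).
#' @param lines_before_center acquired lines preceding ky = 0 (full tail
#'   assumed).
#' @param noise_sd standard deviation of complex Gaussian noise added per
#'   k-space sample and channel (real/imag), acquired lines only.
#' @param t2star apparent transverse decay constant in seconds, or `NULL` for
#'   no decay. Echo `j` (0-based, acquisition order) is attenuated by
#'   `exp(-j * echo_spacing / t2star)`.
#' @param echo_spacing seconds between consecutive echoes.
#' @param seed integer; identical parameters give bit-identical output.
#' @param fov_readout readout FOV in metres.
#' @return an object of class `acq_params`.
#' @export
acquisition_params <- function(coeffs = default_corruption(),
                               lines_before_center = 4L,
                               noise_sd = 0,
                               t2star = NULL,
                               echo_spacing = 552e-6,
                               seed = 1L,
                               fov_readout = 0.04) {
  stopifnot(inherits(coeffs, "phase_coeffs"), is.finite(noise_sd), noise_sd >= 0)
  if (!is.null(t2star)) stopifnot(is.finite(t2star), t2star > 0)
  structure(list(coeffs = coeffs,
                 lines_before_center = as.integer(lines_before_center),
                 noise_sd = noise_sd, t2star = t2star,
                 echo_spacing = echo_spacing, seed = as.integer(seed),
                 fov_readout = fov_readout),
            class = "acq_params")
}

# Run expr with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-line T2* attenuation in acquisition order; echo_offset shifts the echo
# index of the first acquired line (integrated reference echoes prolong TE).
t2star_weights <- function(acquired_mask, echo_spacing, t2star, echo_offset = 0) {
  w <- rep(1, length(acquired_mask))
  if (is.null(t2star)) return(w)
  acq <- which(acquired_mask)
  echo_idx <- seq_along(acq) - 1L + echo_offset
  w[acq] <- exp(-echo_idx * echo_spacing / t2star)
  w
}

complex_noise <- function(nr, nc, sd) {
  matrix(complex(real = stats::rnorm(nr * nc, sd = sd),
                 imaginary = stats::rnorm(nr * nc, sd = sd)), nr, nc)
}

#' Simulate a single-shot EPI acquisition
#'
#' Forward-transforms the object, applies per-echo T2* decay in acquisition
#' order, corrupts the lines with the alternating phase error, zero-fills the
#' unacquired early lines, and adds seeded complex Gaussian noise to the
#' acquired lines only.
#'
#' @param img an [image_grid] (real or complex object).
#' @param p an [acquisition_params].
#' @param echo_offset internal: advance of the first echo index (used by
#'   [acquire_integrated_echoes()]).
#' @param seed_offset added to `p$seed` (dynamic series use per-frame seeds).
#' @return an [epi_kspace].
#' @export
acquire_epi <- function(img, p, echo_offset = 0, seed_offset = 0L) {
  stopifnot(inherits(p, "acq_params"))
  m <- as_image_matrix(img)
  k <- forward_kspace(m, echo_spacing = p$echo_spacing,
                      lines_before_center = p$lines_before_center,
                      fov_readout = p$fov_readout)
  w <- t2star_weights(k$acquired_mask, p$echo_spacing, p$t2star, echo_offset)
  k$data <- sweep(k$data, 2, w, `*`)
  k <- apply_phase_error(k, p$coeffs)
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed + seed_offset,
                       complex_noise(nrow(k$data), ncol(k$data), p$noise_sd))
    noise[, !k$acquired_mask] <- 0i
    k$data <- k$data + noise
  }
  k
}

#' Simulate a reference scan (phase-encode gradients off)
#'
#' Identical to [acquire_epi()] except that every acquired line samples
#' ky = 0: each hybrid line is the 1D projection of the object along the
#' phase-encode direction, carrying the same alternating corruption, decay
#' and noise. A 1H reference acquired with the same gradients sees phase
#' errors scaled by the inverse of the gyromagnetic/FOV scaling that
#' [scale_reference_coeffs()] later undoes.
#'
#' @inheritParams acquire_epi
#' @param nucleus `"C13"` (default) or `"H1"`.
#' @param gamma_ratio,fov_ratio for `nucleus = "H1"`: the target/reference
#'   gyromagnetic ratio (gamma_13C / gamma_1H = 0.2515) and reference/target
#'   readout-FOV ratio the corresponding 13C acquisition would use.
#' @return an [epi_kspace] with `nucleus` recorded.
#' @export
acquire_reference <- function(img, p, nucleus = c("C13", "H1"),
                              gamma_ratio = 0.2515, fov_ratio = 0.25) {
  stopifnot(inherits(p, "acq_params"))
  nucleus <- match.arg(nucleus)
  m <- as_image_matrix(img)
  kfull <- ft2(m)
  dc_line <- kfull[, ncol(m) / 2 + 1L]
  c_eff <- p$coeffs
  if (nucleus == "H1") {
    # invert the scaling applied when transferring 1H estimates to 13C
    c_eff <- phase_coeffs(p$coeffs$alpha / gamma_ratio,
                          p$coeffs$beta / gamma_ratio * fov_ratio,
                          canonicalize = FALSE)
  }
  d <- matrix(dc_line, nrow(m), ncol(m))
  k <- epi_kspace(d, echo_spacing = p$echo_spacing,
                  lines_before_center = p$lines_before_center,
                  nucleus = nucleus, fov_readout = p$fov_readout)
  w <- t2star_weights(k$acquired_mask, p$echo_spacing, p$t2star)
  k$data <- sweep(k$data, 2, w, `*`)
  k <- apply_phase_error(k, c_eff)
  k$nucleus <- nucleus
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, complex_noise(nrow(k$data), ncol(k$data), p$noise_sd))
    noise[, !k$acquired_mask] <- 0i
    k$data <- k$data + noise
  }
  k$data[, !k$acquired_mask] <- 0i
  k
}

#' Simulate integrated reference echoes plus the imaging acquisition
#'
#' Prepends `n_echoes` non-phase-encoded echoes (alternating polarity,
#' T2*-decayed from echo index 0) to the imaging train. The imaging k-space
#' then starts `n_echoes` echo spacings later, so its per-line T2* decay is
#' advanced accordingly — the SNR penalty of integrated reference echoes: the
#' noiseless amplitude is reduced by `exp(-n_echoes * echo_spacing / t2star)`
#' relative to a plain acquisition.
#'
#' @inheritParams acquire_epi
#' @param n_echoes number of reference echoes (>= 2; 3 matches the sequence
#'   the package emulates).
#' @return a list with `echoes` (complex `n_readout x n_echoes` matrix of
#'   ky = 0 k-space lines) and `kspace` (the imaging [epi_kspace]).
#' @export
acquire_integrated_echoes <- function(img, p, n_echoes = 3L) {
  stopifnot(inherits(p, "acq_params"))
  if (n_echoes < 2) stop("need at least 2 reference echoes", call. = FALSE)
  m <- as_image_matrix(img)
  dc_line <- ft2(m)[, ncol(m) / 2 + 1L]
  xn <- centered_coord(nrow(m))
  th <- p$coeffs$alpha + p$coeffs$beta * xn
  pol <- line_polarity(n_echoes)
  h_dc <- ift_line(dc_line)
  echoes <- vapply(seq_len(n_echoes), function(e) {
    w <- if (is.null(p$t2star)) 1 else exp(-(e - 1L) * p$echo_spacing / p$t2star)
    ft_line_vec(h_dc * w * exp(1i * pol[e] * th))
  }, complex(nrow(m)))
  if (p$noise_sd > 0)
    echoes <- echoes + with_seed(p$seed + 7L,
                                 complex_noise(nrow(m), n_echoes, p$noise_sd))
  k <- acquire_epi(m, p, echo_offset = n_echoes)
  list(echoes = echoes, kspace = k)
}

ft_line_vec <- function(v) {
  n <- length(v); sh <- swap_idx(n)
  k <- stats::fft(v[sh]); k[sh]
}

#' Noise level for a target object SNR
#'
#' Computes the k-space noise standard deviation that yields a requested
#' object SNR (mean object magnitude over the Rayleigh standard deviation of
#' the background magnitude) for a given object and acquisition geometry,
#' using the noiseless reconstruction and the analytic propagation of white
#' complex k-space noise through the zero-filled transform.
#'
#' @param img an [image_grid].
#' @param p an [acquisition_params] (its `noise_sd` is ignored).
#' @param target_snr requested object SNR (> 0).
#' @param object_mask logical matrix; defaults to pixels above 50% of the
#'   maximum noiseless magnitude.
#' @return the k-space `noise_sd` to put into [acquisition_params()].
#' @export
noise_sd_for_snr <- function(img, p, target_snr, object_mask = NULL) {
  stopifnot(target_snr > 0)
  p0 <- p; p0$noise_sd <- 0
  rec <- magnitude(reconstruct(acquire_epi(img, p0)))
  if (is.null(object_mask)) object_mask <- rec > 0.5 * max(rec)
  mean_obj <- mean(rec[object_mask])
  nr <- nrow(rec); nc <- ncol(rec)
  n_lines <- sum(epi_kspace(matrix(0i, nr, nc),
                            lines_before_center = p$lines_before_center)$acquired_mask)
  # image-domain complex noise sd per channel after 1/(nr*nc)-scaled inverse FT
  sd_im_per_sigma <- sqrt(nr * n_lines) / (nr * nc)
  rayleigh_sd <- sqrt((4 - pi) / 2) * sd_im_per_sigma
  mean_obj / (target_snr * rayleigh_sd)
}
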