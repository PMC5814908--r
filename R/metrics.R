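#' Measurement regions for the ghosting-level metric
#'
#' Region 5 is the object region. Regions 1 and 2 are the two pieces of
#' region 5 circularly shifted by half the FOV in the phase-encode direction
#' (split at the image midline); regions 3 and 4 are the analogous pieces for
#' a half-FOV shift in the frequency-encode direction. For restricted-FOV or
#' multi-source images all five regions may instead be supplied explicitly.
#'
#' @param object_mask logical matrix: region 5.
#' @param region1,region2,region3,region4 optional explicit logical masks
#'   overriding the constructed shifts.
#' @return an object of class `roi_set` with elements `region1` .. `region5`.
#' @export
build_roi_set <- function(object_mask, region1 = NULL, region2 = NULL,
                          region3 = NULL, region4 = NULL) {
  stopifnot(is.logical(object_mask), is.matrix(object_mask), any(object_mask))
  n_pe <- ncol(object_mask); n_ro <- nrow(object_mask)
  pe_shift <- shift_half_fov_pe(object_mask)
  ro_shift <- shift_half_fov_ro(object_mask)
  half_pe <- col(object_mask) <= n_pe / 2
  half_ro <- row(object_mask) <= n_ro / 2
  rois <- list(
    region1 = if (is.null(region1)) pe_shift & half_pe else region1,
    region2 = if (is.null(region2)) pe_shift & !half_pe else region2,
    region3 = if (is.null(region3)) ro_shift & half_ro else region3,
    region4 = if (is.null(region4)) ro_shift & !half_ro else region4,
    region5 = object_mask
  )
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> pixels: r1=%d r2=%d r3=%d r4=%d r5=%d\n",
              sum(x$region1), sum(x$region2), sum(x$region3), sum(x$region4),
              sum(x$region5)))
  invisible(x)
}

#' Residual ghosting level in percent
#'
#' `(mean r1 + mean r2 - mean r3 - mean r4) / (2 * mean r5) * 100`, with all
#' means taken over the magnitude signal: the excess mean magnitude in the
#' half-FOV phase-encode copies of the object region (where the Nyquist ghost
#' lands), with the frequency-encode copies subtracting the noise floor,
#' normalized by the object mean. May be slightly negative under noise
#' fluctuation; not clamped. Invariant to global intensity scaling.
#'
#' @param img_magnitude numeric matrix of magnitudes (or an [image_grid],
#'   whose magnitude is taken).
#' @param rois a [build_roi_set()] result.
#' @return ghosting level in percent.
#' @export
ghosting_level <- function(img_magnitude, rois) {
  stopifnot(inherits(rois, "roi_set"))
  m <- if (inherits(img_magnitude, "image_grid")) magnitude(img_magnitude)
       else img_magnitude
  stopifnot(is.numeric(m), all(is.finite(m)))
  means <- vapply(rois[c("region1", "region2", "region3", "region4", "region5")],
                  function(r) {
                    if (!any(r)) stop("empty measurement region", call. = FALSE)
                    mean(m[r])
                  }, numeric(1))
  if (means[5] == 0) stop("object region mean is zero: ghosting level undefined",
                          call. = FALSE)
  unname((means[1] + means[2] - means[3] - means[4]) / (2 * means[5]) * 100)
}

#' Signal-to-noise ratio of a magnitude image
#'
#' Mean object magnitude divided by the standard deviation of the magnitude
#' over a noise source — either a noise region in the same image or a
#' designated noise-only frame (e.g. the last substrate image of a dynamic
#' series).
#'
#' @param img_magnitude numeric magnitude matrix or [image_grid].
#' @param object_mask logical matrix over the object.
#' @param noise_source logical matrix (noise region in the same image) or a
#'   numeric matrix / [image_grid] (noise-only frame whose whole magnitude
#'   distribution is used).
#' @return the SNR (dimensionless).
#' @export
snr <- function(img_magnitude, object_mask, noise_source) {
  m <- if (inherits(img_magnitude, "image_grid")) magnitude(img_magnitude)
       else img_magnitude
  stopifnot(is.logical(object_mask), any(object_mask))
  noise_vals <- if (is.logical(noise_source)) {
    stopifnot(any(noise_source))
    m[noise_source]
  } else {
    nm <- if (inherits(noise_source, "image_grid")) magnitude(noise_source)
          else noise_source
    as.vector(nm)
  }
  s <- stats::sd(noise_vals)
  if (!is.finite(s) || s == 0) stop("noise standard deviation is zero", call. = FALSE)
  mean(m[object_mask]) / s
}

# normalized 2D Gaussian kernel, size x size, standard deviation sigma
gaussian_kernel <- function(size = 7L, sigma = 1.5) {
  r <- (size - 1L) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-mode 2D correlation with a small kernel
conv2_valid <- function(m, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  nr <- nrow(m) - kr + 1L; nc <- ncol(m) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr))
    for (j in seq_len(kc))
      out <- out + kern[i, j] * m[i:(i + nr - 1L), j:(j + nc - 1L)]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM between two magnitude images with the standard constants
#' (`K1 = 0.01`, `K2 = 0.03`), a 7 x 7 Gaussian window of standard deviation
#' 1.5, Gaussian-weighted (population) variances and covariance, and the
#' joint maximum as the dynamic range. The SSIM map is averaged over the
#' region where the window lies fully inside both images, so borders carry no
#' padding artefacts. SSIM = 1 indicates identical images.
#'
#' @param img_a,img_b numeric magnitude matrices (or [image_grid]s) of equal
#'   size, at least 7 x 7.
#' @param data_range dynamic range; defaults to the joint maximum.
#' @return the mean SSIM, in `[-1, 1]`.
#' @export
ssim <- function(img_a, img_b, data_range = NULL) {
  a <- if (inherits(img_a, "image_grid")) magnitude(img_a) else img_a
  b <- if (inherits(img_b, "image_grid")) magnitude(img_b) else img_b
  if (!all(dim(a) == dim(b))) stop("image shapes differ", call. = FALSE)
  if (any(dim(a) < 7L)) stop("images must be at least 7 x 7", call. = FALSE)
  if (is.null(data_range)) data_range <- max(a, b)
  if (data_range <= 0) stop("degenerate dynamic range", call. = FALSE)
  kern <- gaussian_kernel(7L, 1.5)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_a <- conv2_valid(a, kern); mu_b <- conv2_valid(b, kern)
  var_a <- conv2_valid(a * a, kern) - mu_a^2
  var_b <- conv2_valid(b * b, kern) - mu_b^2
  cov_ab <- conv2_valid(a * b, kern) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(map)
}

#' Per-pixel bandwidth in the phase-encode direction
#'
#' `1 / (n_pe * echo_spacing)` in hertz: the B0 offset that shifts the image
#' by one pixel along phase-encode, i.e. the off-resonance immunity of the
#' acquisition. A 32-line matrix at 552 us echo spacing gives about 57 Hz.
#'
#' @param n_pe number of phase-encode lines (>= 1).
#' @param echo_spacing seconds (> 0).
#' @return bandwidth in Hz.
#' @examples
#' pe_pixel_bandwidth(32, 552e-6)  # ~56.6 Hz
#' @export
pe_pixel_bandwidth <- function(n_pe, echo_spacing) {
  if (n_pe < 1 || !is.finite(n_pe)) stop("n_pe must be >= 1", call. = FALSE)
  if (!is.finite(echo_spacing) || echo_spacing <= 0)
    stop("echo_spacing must be positive", call. = FALSE)
  1 / (n_pe * echo_spacing)
}
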