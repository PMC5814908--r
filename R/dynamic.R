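#' Metabolite signal-time curves
#'
#' Simple amplitude curves for a dynamic hyperpolarized experiment: the
#' injected substrate (pyruvate) follows a gamma-variate rise and fall
#' (shape 3, scale 4 s by default), and the metabolic product (lactate) the
#' same family delayed by 4 s and scaled to 0.3. Curves are normalized so the
#' pyruvate peak is 1. No kinetic model is claimed; these are fixed,
#' documented defaults giving a realistic rising-then-falling series.
#'
#' @param times numeric vector of acquisition times in seconds.
#' @param shape,scale gamma-variate parameters.
#' @param delay seconds before the curve starts.
#' @param amplitude peak scaling relative to the undelayed curve.
#' @return numeric vector of non-negative amplitudes.
#' @export
gamma_variate_curve <- function(times, shape = 3, scale = 4, delay = 0,
                                amplitude = 1) {
  t0 <- pmax(times - delay, 0)
  v <- stats::dgamma(t0, shape = shape, scale = scale)
  peak <- stats::dgamma((shape - 1) * scale, shape = shape, scale = scale)
  amplitude * v / peak
}

#' @rdname gamma_variate_curve
#' @export
default_curves <- function(times) {
  list(pyruvate = gamma_variate_curve(times),
       lactate = gamma_variate_curve(times, delay = 4, amplitude = 0.3))
}

#' Simulate a dynamic two-metabolite EPI series
#'
#' Frame `t` of metabolite `m` is `acquire_epi(curve_m(t) * phantom_m, p)`
#' with a per-frame seed derived from the master seed (master + frame offset),
#' so golden outputs are stable. All frames share the matrix, echo spacing and
#' — crucially for the workflow — the same true phase-error coefficients.
#'
#' @param phantoms named list of [phantom_spec]s, one per metabolite
#'   (defaults: pyruvate = [tumour_phantom()] scaled geometry, lactate =
#'   the same object).
#' @param curves named list of amplitude vectors (one per metabolite, length
#'   `n_frames`), or `NULL` for [default_curves()] at `tr`-spaced times.
#' @param p an [acquisition_params].
#' @param n_frames frames per metabolite.
#' @param tr repetition time per metabolite in seconds (frame `i` is at
#'   `i * tr`).
#' @return an object of class `dynamic_series`: list with `frames` (named list
#'   of lists of [epi_kspace]), `times`, `curves`, `params`.
#' @export
make_dynamic_series <- function(phantoms = NULL, curves = NULL, p = acquisition_params(),
                                n_frames = 10L, tr = 2) {
  stopifnot(inherits(p, "acq_params"))
  if (is.null(phantoms))
    phantoms <- list(pyruvate = tumour_phantom(), lactate = tumour_phantom())
  times <- seq_len(n_frames) * tr
  if (is.null(curves)) curves <- lapply(default_curves(times), function(v) v)
  stopifnot(identical(sort(names(phantoms)), sort(names(curves))))
  mets <- names(phantoms)
  frames <- stats::setNames(vector("list", length(mets)), mets)
  for (mi in seq_along(mets)) {
    m <- mets[mi]
    amp <- curves[[m]]
    stopifnot(length(amp) == n_frames, all(amp >= 0))
    img <- make_phantom(phantoms[[m]])
    frames[[m]] <- lapply(seq_len(n_frames), function(t) {
      acquire_epi(image_grid(amp[t] * img$data), p,
                  seed_offset = (mi - 1L) * n_frames + (t - 1L))
    })
  }
  structure(list(frames = frames, times = times, curves = curves,
                 phantoms = phantoms, params = p),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %s; %d frames each, t = %g..%g s\n",
              paste(names(x$frames), collapse = " + "),
              length(x$frames[[1]]), min(x$times), max(x$times)))
  invisible(x)
}
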