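#' One-dimensional phase unwrapping (Ahn's cumulative algorithm)
#'
#' Unwraps a phase profile by accumulating the principal-value phase of the
#' lag-one complex product: `phi(1) = Arg(S_1)`,
#' `phi(n) = phi(n-1) + Arg(S_n * Conj(S_{n-1}))`. Computed from the complex
#' samples, this is immune to +/-2*pi wraps as long as the true inter-sample
#' phase steps stay below pi in magnitude. Zero-magnitude samples contribute
#' no increment (the last phase is carried forward) and are flagged.
#'
#' @param samples complex vector; alternatively supply `phase` and
#'   `magnitude` vectors.
#' @param phase,magnitude numeric vectors used when `samples` is missing.
#' @return list with `phase` (unwrapped, radians) and `carried` (logical,
#'   `TRUE` where a zero-magnitude sample carried the previous phase forward).
#' @export
phase_unwrap_1d <- function(samples = NULL, phase = NULL, magnitude = NULL) {
  if (is.null(samples)) {
    stopifnot(!is.null(phase), !is.null(magnitude),
              length(phase) == length(magnitude))
    samples <- complex(modulus = magnitude, argument = phase)
  }
  n <- length(samples)
  if (n == 0L) stop("no samples", call. = FALSE)
  zero <- Mod(samples) == 0
  out <- numeric(n)
  carried <- logical(n)
  out[1] <- if (zero[1]) 0 else Arg(samples[1])
  carried[1] <- zero[1]
  if (n > 1L) {
    step <- Arg(samples[-1] * Conj(samples[-n]))
    dead <- zero[-1] | zero[-n]
    step[dead] <- 0
    carried[-1] <- zero[-1]
    out[-1] <- out[1] + cumsum(step)
  }
  list(phase = out, carried = carried)
}
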