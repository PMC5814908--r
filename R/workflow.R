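#' Noise mask for SNR measurements on simulated frames
#'
#' Background pixels that are neither in the object region nor in any of its
#' half-FOV copies (where ghost signal may land), suitable as the noise source
#' for [snr()].
#'
#' @param object_mask logical matrix.
#' @return logical matrix of noise-only pixels.
#' @export
noise_mask_for <- function(object_mask) {
  !object_mask & !shift_half_fov_pe(object_mask) &
    !shift_half_fov_ro(object_mask) &
    !shift_half_fov_ro(shift_half_fov_pe(object_mask))
}

select_search_frame <- function(series, object_mask, frame_selector) {
  nmask <- noise_mask_for(object_mask)
  # SNR is undefined on noiseless frames (zero background SD); ranking then
  # falls back to mean object signal, which orders frames identically
  frame_stats <- function(k) {
    m <- magnitude(reconstruct(k))
    s <- stats::sd(m[nmask])
    sig <- mean(m[object_mask])
    c(snr = if (s > 0) sig / s else NA_real_, signal = sig)
  }
  if (is.numeric(frame_selector)) {
    st <- frame_stats(series$frames$lactate[[frame_selector]])
    list(kspace = series$frames$lactate[[frame_selector]],
         label = sprintf("lactate[%d]", frame_selector), snr = st[["snr"]])
  } else if (frame_selector == "peak-lactate") {
    st <- vapply(series$frames$lactate, frame_stats, numeric(2))
    i <- if (any(is.finite(st["snr", ]))) which.max(st["snr", ])
         else which.max(st["signal", ])
    list(kspace = series$frames$lactate[[i]],
         label = sprintf("lactate[%d]", i), snr = st["snr", i])
  } else if (frame_selector %in% c("sum-pyruvate", "sum-lactate")) {
    met <- sub("^sum-", "", frame_selector)
    ks <- series$frames[[met]]
    ksum <- ks[[1]]
    for (t in seq_along(ks)[-1]) ksum$data <- ksum$data + ks[[t]]$data
    st <- frame_stats(ksum)
    list(kspace = ksum, label = frame_selector, snr = st[["snr"]])
  } else stop("unknown frame selector: ", frame_selector, call. = FALSE)
}

#' Run the referenceless correction workflow on a dynamic series
#'
#' Implements the dynamic workflow: select one frame (by default the lactate
#' frame with the highest object SNR; alternatives are the summed frames of
#' either metabolite or an explicit lactate frame index), run the 1D
#' exhaustive search on it once, and apply the resulting coefficient pair to
#' every frame of every metabolite. If the selected frame's object SNR falls
#' below `snr_floor` a warning is issued — searches on very low-SNR frames
#' yield essentially random coefficients — but the search still executes.
#'
#' @param series a [make_dynamic_series()] result.
#' @param object_mask logical matrix enclosing all signal sources; defaults
#'   to the union of the series' phantom masks.
#' @param cfg a [search_config].
#' @param frame_selector `"peak-lactate"` (default), `"sum-pyruvate"`,
#'   `"sum-lactate"`, or an integer lactate frame index.
#' @param snr_floor object-SNR warning threshold (default 4.7, the empirical
#'   level below which searched coefficients become unreliable).
#' @return list with `corrected` (per-metabolite lists of [image_grid]s),
#'   `uncorrected` (plain reconstructions), `coeffs`, `search` (the
#'   [search_1d()] result), `search_frame`, `search_snr`, `object_mask`.
#' @export
apply_workflow <- function(series, object_mask = NULL, cfg = search_config(),
                           frame_selector = "peak-lactate", snr_floor = 4.7) {
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(object_mask)) {
    masks <- lapply(series$phantoms, phantom_mask)
    object_mask <- Reduce(`|`, masks)
  }
  sel <- select_search_frame(series, object_mask, frame_selector)
  if (is.finite(sel$snr) && sel$snr < snr_floor)
    warning(sprintf(paste0("search frame %s has object SNR %.2f, below the ",
                           "reliability floor of %.2f; coefficients may be random"),
                    sel$label, sel$snr, snr_floor), call. = FALSE)
  bands <- build_ghost_bands(object_mask)
  res <- search_1d(sel$kspace, bands, cfg)
  corrected <- lapply(series$frames, function(ks)
    lapply(ks, correct_with_coeffs, c = res$coeffs))
  uncorrected <- lapply(series$frames, function(ks) lapply(ks, reconstruct))
  list(corrected = corrected, uncorrected = uncorrected,
       coeffs = res$coeffs, search = res,
       search_frame = sel$label, search_snr = sel$snr,
       object_mask = object_mask)
}
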