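#' Ghost-containing background bands
#'
#' The referenceless search minimizes signal in bands lying outside the
#' object region of interest in the phase-encode direction: all phase-encode
#' positions strictly before the first and strictly after the last object
#' position (optionally shrunk by a safety margin), across the full readout
#' width. These bands catch the half-FOV ghost of any object confined to the
#' ROI.
#'
#' @param object_mask logical matrix (`n_readout x n_pe`), `TRUE` over the
#'   object ROI (a single ROI should enclose all signal sources).
#' @param margin_rows phase-encode positions to drop from each band edge
#'   adjacent to the object.
#' @return an object of class `ghost_bands`: list with `mask` (logical matrix)
#'   and the band position indices.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[, 11:21] <- TRUE  # object at PE 10..20 (0-based)
#' b <- build_ghost_bands(m)
#' range(which(apply(b$mask, 2, any)))  # bands at PE 1..10 and 22..32 (1-based)
#' @export
build_ghost_bands <- function(object_mask, margin_rows = 0L) {
  stopifnot(is.logical(object_mask), is.matrix(object_mask))
  pe_any <- apply(object_mask, 2, any)
  if (!any(pe_any)) stop("object mask is empty", call. = FALSE)
  first <- min(which(pe_any)); last <- max(which(pe_any))
  n_pe <- ncol(object_mask)
  lo <- seq_len(max(first - 1L - margin_rows, 0L))
  hi <- if (last + 1L + margin_rows <= n_pe) (last + 1L + margin_rows):n_pe else integer(0)
  cols <- c(lo, hi)
  if (length(cols) == 0L)
    stop("object spans all phase-encode positions: no ghost-containing band ",
         "is available; supply bands manually (the search requires signal ",
         "that does not cover the whole FOV)", call. = FALSE)
  mask <- matrix(FALSE, nrow(object_mask), n_pe)
  mask[, cols] <- TRUE
  if (any(mask & object_mask))
    stop("ghost bands overlap the object mask", call. = FALSE)
  structure(list(mask = mask, band_cols = cols,
                 object_extent = c(first, last)), class = "ghost_bands")
}

#' Wrap an explicit band mask
#'
#' For restricted-FOV or multi-source cases where automatic band construction
#' is inappropriate and the bands are drawn manually.
#'
#' @param mask logical matrix of ghost-containing background pixels.
#' @return a `ghost_bands` object.
#' @export
ghost_bands <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask), any(mask))
  structure(list(mask = mask, band_cols = which(apply(mask, 2, any)),
                 object_extent = NULL), class = "ghost_bands")
}

#' @export
print.ghost_bands <- function(x, ...) {
  cat(sprintf("<ghost_bands> %d pixels over %d phase-encode positions\n",
              sum(x$mask), length(x$band_cols)))
  invisible(x)
}
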