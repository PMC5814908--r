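#' Search configuration for the exhaustive coefficient search
#'
#' The search covers `[-pi/2, pi/2]` (the phase error is periodic in pi) with
#' `n_steps` evenly spaced grid points including both endpoints, i.e. a step
#' of `pi/(n_steps - 1)` at the defaults. The objective is the mean magnitude
#' over the ghost-band pixels; exact ties are broken towards the smallest
#' `|alpha| + |beta|`, then the smallest `|beta|`, for determinism.
#'
#' @param grid_min,grid_max search range in radians.
#' @param n_steps number of grid points per coefficient (>= 2; 100 gives the
#'   10,000-combination search used throughout).
#' @return an object of class `search_config`.
#' @export
search_config <- function(grid_min = -pi / 2, grid_max = pi / 2, n_steps = 100L) {
  stopifnot(grid_min < grid_max, n_steps >= 2)
  structure(list(grid_min = grid_min, grid_max = grid_max,
                 n_steps = as.integer(n_steps)), class = "search_config")
}

#' @rdname search_config
#' @param cfg a `search_config`.
#' @return `grid_step()`: the spacing between grid points in radians.
#' @export
grid_step <- function(cfg) (cfg$grid_max - cfg$grid_min) / (cfg$n_steps - 1L)

search_grid <- function(cfg) seq(cfg$grid_min, cfg$grid_max, length.out = cfg$n_steps)

# Precompute the factorized band evaluation: corrected band-pixel values are
# exp(-i*theta(x)) * A + exp(+i*theta(x)) * B per readout row, where A/B are
# the even-/odd-line contributions transformed onto the band columns once.
band_factorization <- function(k, bands) {
  stopifnot(inherits(k, "epi_kspace"), inherits(bands, "ghost_bands"))
  d <- k$data
  d[, !k$acquired_mask] <- 0i
  h <- ift_readout(d)
  n_pe <- ncol(d)
  if (nrow(bands$mask) != nrow(d) || ncol(bands$mask) != n_pe)
    stop("band mask dimensions do not match the k-space", call. = FALSE)
  if (!any(bands$mask)) stop("empty ghost bands", call. = FALSE)
  cols <- bands$band_cols
  # inverse-DFT matrix of the centred phase-encode transform, band columns only
  Wfull <- vapply(seq_len(n_pe), function(m) {
    v <- rep(0i, n_pe); v[m] <- 1i^0 * 1; ift_line(v)
  }, complex(n_pe))                      # Wfull[p, m]: image p from k-line m
  Wt <- t(Wfull)[, cols, drop = FALSE]   # [m, band col]
  pol <- line_polarity(n_pe)
  even <- pol > 0
  list(A = h[, even, drop = FALSE] %*% Wt[even, , drop = FALSE],
       B = h[, !even, drop = FALSE] %*% Wt[!even, , drop = FALSE],
       band_sub = bands$mask[, cols, drop = FALSE],
       cols = cols, h = h, Wt = Wt, pol = pol)
}

#' Referenceless 1D exhaustive search
#'
#' Evaluates every combination of `(alpha, beta)` on the search grid: for each
#' candidate the k-space is phase-corrected, reconstructed, and scored by the
#' mean magnitude over the ghost-containing background bands; the minimizing
#' grid point is returned. The evaluation is factorized in hybrid space (the
#' correction phase depends only on the readout position and line parity), so
#' the full 100 x 100 search is exhaustive yet takes well under a second for a
#' 32 x 32 matrix.
#'
#' @param k an [epi_kspace] (phase-encoding on).
#' @param bands a [ghost_bands] (see [build_ghost_bands()]).
#' @param cfg a [search_config].
#' @return an object of class `search_result_1d`: list with `coeffs` (the
#'   minimizing [phase_coeffs]), `objective` (the `n_steps x n_steps` surface,
#'   alpha by row), `alpha_grid`, `beta_grid`, `band_mean` (objective at the
#'   optimum) and `corrected` (the corrected [image_grid]).
#' @export
search_1d <- function(k, bands, cfg = search_config()) {
  fac <- band_factorization(k, bands)
  grid <- search_grid(cfg)
  n <- cfg$n_steps
  xn <- centered_coord(nrow(k$data))
  sel <- which(fac$band_sub)
  # |e^{-ia}U + e^{ia}V|^2 = |U|^2 + |V|^2 + 2 Re(Conj(U) V e^{2ia}):
  # evaluate all alphas per beta in real arithmetic
  cos2a <- cos(2 * grid); sin2a <- sin(2 * grid)
  obj <- matrix(NA_real_, n, n, dimnames = list(alpha = NULL, beta = NULL))
  for (bi in seq_len(n)) {
    ephase <- exp(-1i * grid[bi] * xn)
    U <- (fac$A * ephase)[sel]
    V <- (fac$B * Conj(ephase))[sel]
    w <- Conj(U) * V
    s0 <- Mod(U)^2 + Mod(V)^2
    m2 <- s0 + 2 * (Re(w) %o% cos2a - Im(w) %o% sin2a)
    m2[m2 < 0] <- 0
    obj[, bi] <- colMeans(sqrt(m2))
  }
  ia <- as.vector(row(obj)); ib <- as.vector(col(obj))
  ord <- order(as.vector(obj),
               abs(grid[ia]) + abs(grid[ib]),
               abs(grid[ib]))[1]
  best <- phase_coeffs(grid[ia[ord]], grid[ib[ord]], canonicalize = FALSE)
  structure(list(coeffs = best, objective = obj,
                 alpha_grid = grid, beta_grid = grid,
                 band_mean = obj[ia[ord], ib[ord]],
                 corrected = correct_with_coeffs(k, best),
                 grid_step = grid_step(cfg)),
            class = "search_result_1d")
}

#' @export
print.search_result_1d <- function(x, ...) {
  cat(sprintf("<search_result_1d> alpha = %.4f, beta = %.4f (band mean %.4g, step %.4f)\n",
              x$coeffs$alpha, x$coeffs$beta, x$band_mean, x$grid_step))
  invisible(x)
}

#' Referenceless 2D exhaustive search
#'
#' Extends the 1D search with a first-order term along the phase-encode
#' direction: for each candidate `beta_y` on the grid, every readout row is
#' independently assigned the phase `theta_col[x]` that minimizes the band
#' magnitude within that row, and the `beta_y` with the lowest total band
#' magnitude wins. Readout rows with no ghost-band pixels (possible with
#' manually drawn bands) cannot be locally determined; they inherit the global
#' 1D solution and are flagged. Local per-row minimization can be biased in
#' rows with little ghost signal — the known weakness of the 2D search with
#' multiple sources.
#'
#' @inheritParams search_1d
#' @return an object of class `search_result_2d`: list with `coeffs` (a
#'   [coeffs_2d]), `beta_y_objective` (total band magnitude per `beta_y`
#'   candidate), `beta_y_grid`, `corrected` and `flagged_rows`.
#' @export
search_2d <- function(k, bands, cfg = search_config()) {
  fac <- band_factorization(k, bands)
  grid <- search_grid(cfg)
  n <- cfg$n_steps
  nr <- nrow(k$data); n_pe <- ncol(k$data)
  jn <- centered_coord(n_pe)
  z2 <- exp(2i * grid)
  row_has_band <- rowSums(fac$band_sub) > 0
  flagged <- which(!row_has_band)
  even <- fac$pol > 0
  total <- rep(NA_real_, n)
  best <- NULL
  for (yi in seq_len(n)) {
    line_ph <- exp(-1i * fac$pol * grid[yi] * jn)
    hb <- sweep(fac$h, 2, line_ph, `*`)
    A <- hb[, even, drop = FALSE] %*% fac$Wt[even, , drop = FALSE]
    B <- hb[, !even, drop = FALSE] %*% fac$Wt[!even, , drop = FALSE]
    theta_col <- numeric(nr)
    tot <- 0
    for (x in which(row_has_band)) {
      bm <- fac$band_sub[x, ]
      vals <- colMeans(Mod(A[x, bm] + outer(B[x, bm], z2)))
      cand <- order(vals, abs(grid))[1]        # tie-break: smallest |theta|
      theta_col[x] <- grid[cand]
      tot <- tot + vals[cand] * sum(bm)
    }
    total[yi] <- tot
    if (yi == order(total[seq_len(yi)], abs(grid[seq_len(yi)]))[1])
      best <- list(theta_col = theta_col, beta_y = grid[yi])
  }
  if (length(flagged) > 0) {
    g1 <- search_1d(k, bands, cfg)
    xn <- centered_coord(nr)
    best$theta_col[flagged] <- g1$coeffs$alpha + g1$coeffs$beta * xn[flagged]
    warning(length(flagged), " readout row(s) had no ghost-band pixels; ",
            "they inherit the global 1D solution", call. = FALSE)
  }
  cf <- coeffs_2d(best$theta_col, best$beta_y, flagged_rows = flagged)
  structure(list(coeffs = cf, beta_y_objective = total, beta_y_grid = grid,
                 corrected = correct_with_coeffs(k, cf),
                 flagged_rows = flagged, grid_step = grid_step(cfg)),
            class = "search_result_2d")
}

#' @export
print.search_result_2d <- function(x, ...) {
  cat(sprintf("<search_result_2d> beta_y = %.4f, theta_col in [%.4f, %.4f]\n",
              x$coeffs$beta_y, min(x$coeffs$theta_col), max(x$coeffs$theta_col)))
  invisible(x)
}
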