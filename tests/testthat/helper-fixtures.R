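# Shared fixtures, all generated in code.

random_complex_image <- function(n = 32L, seed = 1L) {
  withr::with_seed(seed, matrix(complex(real = rnorm(n * n),
                                        imaginary = rnorm(n * n)), n, n))
}

disk_fixture <- function() {
  spec <- default_phantom()
  list(spec = spec, img = make_phantom(spec), mask = phantom_mask(spec),
       bands = build_ghost_bands(phantom_mask(spec)),
       rois = build_roi_set(phantom_mask(spec)))
}

# search-grid point helper: value of the i-th point of the default grid
grid_point <- function(i, cfg = search_config()) {
  seq(cfg$grid_min, cfg$grid_max, length.out = cfg$n_steps)[i]
}

expect_ghost_free <- function(img, rois, tol = 1e-8) {
  expect_lt(abs(ghosting_level(magnitude(img), rois)), tol)
}
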