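CONTAINER_SCHEMA <- "epighost-container-1"

kspace_to_list <- function(k) {
  list(kspace_real = Re(k$data), kspace_imag = Im(k$data),
       acquired_mask = k$acquired_mask,
       echo_spacing_s = k$echo_spacing,
       lines_before_center = k$lines_before_center,
       nucleus = k$nucleus, fov_readout_m = k$fov_readout,
       matrix = dim(k$data))
}

require_fields <- function(x, fields, context) {
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0)
    stop("container schema error in ", context, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

list_to_kspace <- function(x, context = "kspace") {
  require_fields(x, c("kspace_real", "kspace_imag", "acquired_mask",
                      "echo_spacing_s", "lines_before_center", "nucleus",
                      "fov_readout_m"), context)
  re <- as.matrix(x$kspace_real); im <- as.matrix(x$kspace_imag)
  epi_kspace(matrix(complex(real = re, imaginary = im), nrow(re), ncol(re)),
             echo_spacing = x$echo_spacing_s,
             lines_before_center = x$lines_before_center,
             acquired_mask = as.logical(x$acquired_mask),
             nucleus = x$nucleus, fov_readout = x$fov_readout_m)
}

#' Write a k-space or dynamic-series container
#'
#' Serializes an [epi_kspace] or [dynamic_series] — complex data as separate
#' real/imaginary arrays alongside the acquisition metadata
#' (`echo_spacing_s`, `lines_before_center`, `nucleus`, `fov_readout_m`,
#' `acquired_mask`) — to a schema-versioned JSON container with full
#' double precision, so a write/read round trip is lossless.
#'
#' @param x an [epi_kspace] or [dynamic_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  if (inherits(x, "epi_kspace")) {
    payload <- c(list(schema_version = CONTAINER_SCHEMA, type = "kspace"),
                 kspace_to_list(x))
  } else if (inherits(x, "dynamic_series")) {
    payload <- list(
      schema_version = CONTAINER_SCHEMA, type = "series",
      metabolites = names(x$frames), times_s = x$times,
      curves = x$curves,
      frames = lapply(x$frames, function(ks) lapply(ks, kspace_to_list)),
      params = list(alpha = x$params$coeffs$alpha, beta = x$params$coeffs$beta,
                    lines_before_center = x$params$lines_before_center,
                    noise_sd = x$params$noise_sd,
                    t2star = x$params$t2star,
                    echo_spacing = x$params$echo_spacing,
                    seed = x$params$seed, fov_readout = x$params$fov_readout),
      phantoms = lapply(x$phantoms, function(p)
        list(shapes = p$shapes, matrix = p$matrix)))
  } else stop("unsupported object for container serialization", call. = FALSE)
  # 17 significant digits: doubles survive the text round trip bit-for-bit
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a k-space or dynamic-series container
#'
#' @param path a file written by [write_container()].
#' @return an [epi_kspace] or [dynamic_series], matching the written object.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  require_fields(x, c("schema_version", "type"), "root")
  if (!identical(x$schema_version, CONTAINER_SCHEMA))
    stop("unrecognized container schema: ", x$schema_version, call. = FALSE)
  if (x$type == "kspace") return(list_to_kspace(x))
  if (x$type != "series") stop("unknown container type: ", x$type, call. = FALSE)
  require_fields(x, c("metabolites", "times_s", "frames", "params"), "series")
  p <- x$params
  params <- acquisition_params(
    coeffs = phase_coeffs(p$alpha, p$beta, canonicalize = FALSE),
    lines_before_center = p$lines_before_center, noise_sd = p$noise_sd,
    t2star = p$t2star, echo_spacing = p$echo_spacing, seed = p$seed,
    fov_readout = p$fov_readout)
  frames <- lapply(x$frames, function(fl)
    lapply(fl, list_to_kspace, context = "series frame"))
  phantoms <- if (!is.null(x$phantoms))
    lapply(x$phantoms, function(ph) {
      shapes <- if (is.data.frame(ph$shapes))
        lapply(seq_len(nrow(ph$shapes)), function(i) as.list(ph$shapes[i, ]))
      else ph$shapes
      phantom_spec(shapes, ph$matrix)
    })
  curves <- if (is.data.frame(x$curves)) as.list(x$curves) else x$curves
  structure(list(frames = frames, times = x$times_s, curves = curves,
                 phantoms = phantoms, params = params),
            class = "dynamic_series")
}

#' Write a magnitude image as NIfTI-1
#'
#' @param img an [image_grid] or numeric matrix (magnitude taken if complex).
#' @param path output `.nii`/`.nii.gz` path.
#' @param pixdim pixel size in millimetres, length 2.
#' @return `path`, invisibly.
#' @export
write_magnitude_nifti <- function(img, path, pixdim = c(1.25, 1.25)) {
  m <- if (inherits(img, "image_grid")) magnitude(img) else abs(img)
  arr <- array(m, dim = c(dim(m), 1))
  nii <- RNifti::asNifti(arr, pixdim = c(pixdim, 1))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' @param path a NIfTI file holding a 2D (or singleton-3D) mask.
#' @return logical matrix (`TRUE` where the voxel value exceeds 0.5).
#' @export
read_mask_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 2) arr <- arr[, , 1]
  matrix(arr > 0.5, nrow(arr), ncol(arr))
}

# Small polynomial fingerprint of a string (provenance logging only).
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%07x", h)
}
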