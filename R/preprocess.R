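#' Resample a volume by B-spline interpolation
#'
#' Resamples onto a new voxel grid using separable B-spline interpolation of
#' the requested order (with the standard recursive prefilter, so values at
#' coincident grid points are reproduced exactly). Grids are corner-aligned:
#' output voxel `j` along an axis sits at physical position
#' `j * target_spacing`, i.e. at input index `j * target_spacing / spacing`.
#' Boundary handling is mirror reflection.
#'
#' The output shape defaults to `round(shape * spacing / target_spacing)` per
#' axis. Multi-scanner studies often instead resample a deviant acquisition
#' onto the study grid of the other scanners (e.g. a 256x256x344 half-mm-slice
#' series onto a 256x256x176 1-mm matrix even though the printed fields of
#' view disagree by a few mm); pass `target_shape` to pin the output matrix
#' explicitly for that use.
#'
#' @param vol an `spc_volume`.
#' @param target_spacing numeric length-3, desired voxel size in mm (> 0).
#' @param order B-spline order, integer 0..5 (default 3, cubic).
#' @param target_shape optional integer length-3 overriding the derived
#'   output shape (grid matching).
#' @return A resampled `spc_volume` with spacing `target_spacing`.
#' @export
resize_volume <- function(vol, target_spacing, order = 3L,
                          target_shape = NULL) {
  stopifnot(is_volume(vol))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("resize_volume: target_spacing must be 3 strictly positive values")
  order <- as.integer(order)
  if (order < 0L || order > 5L)
    stop("resize_volume: interpolation order must be in 0..5")
  out_shape <- if (is.null(target_shape)) {
    as.integer(round(vol$shape * vol$spacing / target_spacing))
  } else {
    as.integer(target_shape)
  }
  if (any(out_shape < 1L))
    stop("resize_volume: derived output shape has a non-positive axis")
  if (identical(out_shape, as.integer(vol$shape)) &&
      max(abs(target_spacing - vol$spacing)) < 1e-12)
    return(vol)
  scale <- target_spacing / vol$spacing  # input index step per output voxel
  out <- cpp_bspline_resample(as.vector(vol$data), as.integer(vol$shape),
                              scale, out_shape, order)
  volume(array(out, dim = out_shape), spacing = target_spacing,
         space_tag = vol$space_tag)
}

#' Zero all voxels outside a head/brain mask
#'
#' @param vol an `spc_volume`.
#' @param head_mask an `spc_labels` on the same grid; 0 marks background.
#' @return The masked `spc_volume`.
#' @export
remove_background <- function(vol, head_mask) {
  stopifnot(is_volume(vol), is_labels(head_mask))
  check_same_grid(list(volume = vol, head_mask = head_mask))
  d <- vol$data
  d[head_mask$labels == 0L] <- 0
  volume(d, spacing = vol$spacing, space_tag = vol$space_tag)
}

#' Global intensity normalization to the 0-1000 scale
#'
#' Linearly rescales the whole image so that, over in-mask voxels, the
#' minimum maps to 0 and the 99th percentile maps to 1000. Values above the
#' 99th percentile are deliberately left > 1000 (clamping would erase the
#' hyperintense tail that WM2MAX measures); negative outputs are clamped to 0
#' since MR magnitude signal is non-negative. Background voxels that are 0 on
#' input remain 0 (the map sends the in-mask minimum, not necessarily 0, to
#' 0, so background is re-zeroed from the mask).
#'
#' The percentile uses the type-7 quantile convention (R's default).
#'
#' @param vol an `spc_volume`.
#' @param mask an `spc_labels` on the same grid; statistics are computed over
#'   voxels with mask != 0.
#' @return The normalized `spc_volume`.
#' @export
normalize_intensity <- function(vol, mask) {
  stopifnot(is_volume(vol), is_labels(mask))
  check_same_grid(list(volume = vol, mask = mask))
  inmask <- mask$labels != 0L
  if (!any(inmask)) stop("normalize_intensity: empty mask")
  x <- vol$data[inmask]
  lo <- min(x)
  p99 <- stats::quantile(x, 0.99, names = FALSE, type = 7)
  if (p99 <= lo)
    stop("normalize_intensity: degenerate in-mask distribution ",
         "(99th percentile equals the minimum)")
  d <- 1000 * (vol$data - lo) / (p99 - lo)
  d[d < 0] <- 0
  d[!inmask] <- 0
  volume(d, spacing = vol$spacing, space_tag = vol$space_tag)
}

#' Within-subject cross-scanner average reference image
#'
#' Voxelwise arithmetic mean of one subject's matched images; the anatomy
#' proxy on which the superpixel parcellation is computed.
#'
#' @param set an `spc_matched_set` (>= 2 scanners, one grid).
#' @return An `spc_volume`.
#' @export
average_reference <- function(set) {
  stopifnot(inherits(set, "spc_matched_set"))
  acc <- set$images[[1]]$data
  for (k in seq_along(set$images)[-1]) acc <- acc + set$images[[k]]$data
  volume(acc / length(set$images), spacing = set$images[[1]]$spacing,
         space_tag = set$images[[1]]$space_tag)
}

#' Denoising hook
#'
#' Denoising (and bias-field correction) are delegated to external tools in
#' practice; this stage exists so preprocessing ablations can be expressed.
#' `"identity"` passes the input through unchanged; `"median"` applies the
#' bundled 3x3x3 median reference plugin; a function `Volume -> Volume` may
#' be supplied directly. Plugin output is grid-checked.
#'
#' @param vol an `spc_volume`.
#' @param plugin `"identity"`, `"median"`, or a function taking and returning
#'   an `spc_volume`.
#' @return The (possibly) filtered `spc_volume`.
#' @export
denoise_hook <- function(vol, plugin = "identity") {
  stopifnot(is_volume(vol))
  out <- if (is.function(plugin)) {
    plugin(vol)
  } else if (identical(plugin, "identity")) {
    return(vol)
  } else if (identical(plugin, "median")) {
    volume(array(cpp_median3(as.vector(vol$data), as.integer(vol$shape)),
                 dim = vol$shape),
           spacing = vol$spacing, space_tag = vol$space_tag)
  } else {
    stop("denoise_hook: unknown plugin; use 'identity', 'median' or a function")
  }
  if (!is_volume(out)) stop("denoise_hook: plugin did not return an spc_volume")
  check_same_grid(list(input = vol, `plugin output` = out))
  out
}
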