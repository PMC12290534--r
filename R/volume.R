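#' Construct a 3D intensity volume
#'
#' The shared data model for all image-valued quantities in the package: a
#' dense 3D array of finite real intensities together with per-axis voxel
#' spacing in millimetres and a free-text tag naming the common space the
#' volume lives in. All multi-volume operations require member volumes to
#' share shape, spacing and space tag (see [check_same_grid()]); the package
#' performs no registration or resampling decisions from orientation
#' information.
#'
#' @param data 3D numeric array of intensities; must be finite everywhere.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param space_tag single string identifying the common space
#'   (e.g. `"MNI-1.5mm"`, `"phantom-grid"`).
#' @return An object of class `spc_volume` with fields `data`, `spacing`,
#'   `shape`, `space_tag`.
#' @export
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$data)
volume <- function(data, spacing = c(1, 1, 1), space_tag = "unspecified") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume: 'data' must be a 3D array, got dimensions (",
         paste(dim(data), collapse = ", "), ")")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume: 'spacing' must be 3 strictly positive finite values")
  storage.mode(data) <- "double"
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop("volume: data contains ", nbad, " non-finite voxel(s)")
  structure(
    list(data = data, spacing = spacing, shape = dim(data),
         space_tag = as.character(space_tag)[1]),
    class = "spc_volume")
}

#' Construct a 3D label volume
#'
#' Integer-valued companion of [volume()]: non-negative labels on the same
#' kind of grid. Label 0 is reserved for background/unlabeled voxels and is
#' never modeled. Used for head/brain masks, tissue classes (CSF/GM/WM) and
#' superpixel parcellations.
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing,space_tag as in [volume()].
#' @param label_names optional named character vector mapping label id to a
#'   name, e.g. `c("1" = "CSF", "2" = "GM", "3" = "WM")`.
#' @return An object of class `spc_labels`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1),
                         space_tag = "unspecified", label_names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("label_volume: 'labels' must be a 3D array")
  if (any(!is.finite(labels)))
    stop("label_volume: labels contain non-finite values")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("label_volume: labels must be non-negative integers (0 = background)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("label_volume: 'spacing' must be 3 strictly positive finite values")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = spacing, shape = dim(labels),
         space_tag = as.character(space_tag)[1], label_names = label_names),
    class = "spc_labels")
}

is_volume <- function(x) inherits(x, "spc_volume")
is_labels <- function(x) inherits(x, "spc_labels")

grid_of <- function(x) {
  stopifnot(is_volume(x) || is_labels(x))
  list(shape = x$shape, spacing = x$spacing, space_tag = x$space_tag)
}

#' Check that volumes and label volumes share one grid
#'
#' Every multi-volume entry point in the package funnels through this check:
#' mixed grids are refused with an error naming the offending member and the
#' mismatching fields.
#'
#' @param vols list of `spc_volume` / `spc_labels` objects (optionally named).
#' @return Invisibly `TRUE` when all grids agree.
#' @export
check_same_grid <- function(vols) {
  if (!is.list(vols) || length(vols) == 0L)
    stop("check_same_grid: need a non-empty list of volumes")
  nms <- names(vols)
  if (is.null(nms)) nms <- paste0("volume ", seq_along(vols))
  ref <- grid_of(vols[[1]])
  for (k in seq_along(vols)) {
    g <- grid_of(vols[[k]])
    bad <- character(0)
    if (!identical(as.integer(g$shape), as.integer(ref$shape)))
      bad <- c(bad, sprintf("shape (%s) vs (%s)",
                            paste(g$shape, collapse = ","),
                            paste(ref$shape, collapse = ",")))
    if (max(abs(g$spacing - ref$spacing)) > 1e-9)
      bad <- c(bad, sprintf("spacing (%s) vs (%s)",
                            paste(signif(g$spacing, 8), collapse = ","),
                            paste(signif(ref$spacing, 8), collapse = ",")))
    if (!identical(g$space_tag, ref$space_tag))
      bad <- c(bad, sprintf("space_tag '%s' vs '%s'", g$space_tag, ref$space_tag))
    if (length(bad))
      stop("check_same_grid: grid mismatch for ", nms[k], ": ",
           paste(bad, collapse = "; "))
  }
  invisible(TRUE)
}

#' Bundle one subject's matched cross-scanner images
#'
#' A traveling-subject record: the same anatomy imaged on two or more
#' scanners, already co-registered onto one common grid. This is the unit the
#' per-subject ComBat fit consumes.
#'
#' @param subject_id single string.
#' @param images named list of [volume()] objects, one per scanner; the names
#'   are the scanner ids. At least two scanners; all on one grid.
#' @return An object of class `spc_matched_set`.
#' @export
matched_image_set <- function(subject_id, images) {
  if (!is.list(images) || length(images) < 2L)
    stop("matched_image_set: need >= 2 scanners per subject")
  if (is.null(names(images)) || any(!nzchar(names(images))) ||
      anyDuplicated(names(images)))
    stop("matched_image_set: 'images' must be uniquely named by scanner id")
  for (im in images) if (!is_volume(im))
    stop("matched_image_set: all images must be spc_volume objects")
  check_same_grid(images)
  structure(list(subject_id = as.character(subject_id)[1], images = images),
            class = "spc_matched_set")
}

#' Scanner ids of a matched image set
#' @param set an `spc_matched_set`.
#' @return Character vector of scanner ids.
#' @export
scanners_of <- function(set) names(set$images)

#' @export
print.spc_volume <- function(x, ...) {
  cat(sprintf("<spc_volume %s @ %s mm, space '%s', range [%.4g, %.4g]>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$space_tag, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.spc_labels <- function(x, ...) {
  u <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<spc_labels %s @ %s mm, space '%s', %d label(s)%s>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$space_tag, sum(u != 0L),
              if (0L %in% u) " + background" else ""))
  invisible(x)
}

#' @export
print.spc_matched_set <- function(x, ...) {
  cat(sprintf("<spc_matched_set subject '%s', %d scanners: %s>\n",
              x$subject_id, length(x$images),
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}
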