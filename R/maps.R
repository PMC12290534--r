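# Voxelwise parametric maps of the fitted scanner effects, leave-one-out
# group averaging, and map-based linear harmonization.

new_effect_maps <- function(additive, multiplicative, provenance, mode) {
  structure(list(additive = additive, multiplicative = multiplicative,
                 provenance = provenance, mode = mode),
            class = "spc_effect_maps")
}

#' Render a subject fit into voxelwise effect maps
#'
#' Every voxel of feature `f` receives that feature's fitted
#' `(gamma_star, delta_star)` for each scanner; voxels outside the mask are
#' padded neutrally (`gamma = 0`, `delta = 1`). Additive maps are in
#' standardized (z) units, exactly the fitted location effects.
#'
#' @param fit an `spc_combat_fit`.
#' @param parc the `spc_parcellation` the fit was computed on (fingerprints
#'   must match).
#' @return An `spc_effect_maps` with `mode = "individual"`.
#' @export
render_maps <- function(fit, parc) {
  stopifnot(inherits(fit, "spc_combat_fit"),
            inherits(parc, "spc_parcellation"))
  if (!identical(fit$source_hash, parc$source_hash))
    stop("render_maps: fit and parcellation come from different reference ",
         "images (fingerprint mismatch)")
  lab <- parc$labels$labels
  inm <- lab > 0L
  spacing <- parc$labels$spacing
  tag <- parc$labels$space_tag
  additive <- multiplicative <- list()
  for (j in fit$stats$scanners) {
    g <- fit$gamma_star[, j]
    d <- fit$delta_star[, j]
    g[!is.finite(g)] <- 0
    d[!is.finite(d) | d <= 0] <- 1
    ga <- array(0, dim = parc$labels$shape)
    da <- array(1, dim = parc$labels$shape)
    ga[inm] <- g[lab[inm]]
    da[inm] <- d[lab[inm]]
    additive[[j]] <- volume(ga, spacing = spacing, space_tag = tag)
    multiplicative[[j]] <- volume(da, spacing = spacing, space_tag = tag)
  }
  new_effect_maps(additive, multiplicative, fit$subject_id, "individual")
}

#' Average individual effect maps at the group level
#'
#' Additive (location) maps are averaged voxelwise arithmetically.
#' Multiplicative (scale) maps are averaged in the log domain and
#' exponentiated by default - the geometric mean respects the
#' reciprocal symmetry of scale factors (maps with `delta` 0.5 and 2 average
#' to 1, not 1.25); `delta_mean = "arithmetic"` restores the literal mean.
#' With `exclude_subject` the average is a leave-one-out group map for that
#' subject (`mode = "group_loo"`), never containing its own effects.
#'
#' @param maps_list list of `spc_effect_maps`, one per subject, same grid
#'   and scanner set.
#' @param exclude_subject optional subject id to hold out.
#' @param delta_mean `"geometric"` (default) or `"arithmetic"`.
#' @return An `spc_effect_maps` with provenance listing the contributors.
#' @export
average_maps <- function(maps_list, exclude_subject = NULL,
                         delta_mean = c("geometric", "arithmetic")) {
  delta_mean <- match.arg(delta_mean)
  stopifnot(is.list(maps_list), length(maps_list) >= 1L)
  contrib <- vapply(maps_list, function(m) m$provenance[1], character(1))
  if (!is.null(exclude_subject)) {
    keep <- contrib != exclude_subject
    maps_list <- maps_list[keep]
    contrib <- contrib[keep]
  }
  if (length(maps_list) < 2L)
    stop("average_maps: need >= 2 contributing subjects",
         if (!is.null(exclude_subject)) " after exclusion")
  scanners <- names(maps_list[[1]]$additive)
  for (m in maps_list) {
    if (!identical(names(m$additive), scanners))
      stop("average_maps: scanner sets differ across subjects")
    check_same_grid(c(m$additive, maps_list[[1]]$additive[1]))
  }
  n <- length(maps_list)
  additive <- multiplicative <- list()
  for (j in scanners) {
    ga <- Reduce(`+`, lapply(maps_list, function(m) m$additive[[j]]$data)) / n
    da <- if (delta_mean == "geometric") {
      exp(Reduce(`+`, lapply(maps_list,
                             function(m) log(m$multiplicative[[j]]$data))) / n)
    } else {
      Reduce(`+`, lapply(maps_list, function(m) m$multiplicative[[j]]$data)) / n
    }
    ref <- maps_list[[1]]$additive[[j]]
    additive[[j]] <- volume(ga, spacing = ref$spacing,
                            space_tag = ref$space_tag)
    multiplicative[[j]] <- volume(da, spacing = ref$spacing,
                                  space_tag = ref$space_tag)
  }
  new_effect_maps(additive, multiplicative, contrib,
                  if (is.null(exclude_subject)) "group" else "group_loo")
}

#' Remove the scanner effect from one image
#'
#' Applies the linear back-transform voxelwise:
#' `Y* = sigma_hat_f * (Z - gamma) / delta + m_hat_f` with
#' `Z = (Y - m_hat_f) / sigma_hat_f`. In `mode = "self"` the subject's own
#' fitted `(gamma_star, delta_star)` per feature are used; in `mode = "map"`
#' the supplied (typically leave-one-out group) maps provide `(gamma, delta)`
#' at each voxel while `m_hat_f`, `sigma_hat_f` still come from the subject's
#' own feature statistics. Background (unparcellated) voxels are unchanged.
#'
#' `map_units` selects how the additive map is interpreted: `"z"` (default)
#' treats it as standardized units inside the printed back-transform;
#' `"intensity"` applies the literal subtract-then-divide on intensities,
#' `Y* = (Y - sigma_hat_f * gamma) / delta`, without recentering.
#'
#' @param img `spc_volume` for one scanner.
#' @param scanner_id which scanner's maps/effects to remove.
#' @param maps an `spc_effect_maps` (required for `mode = "map"`).
#' @param fit the subject's `spc_combat_fit` (feature statistics and, for
#'   `mode = "self"`, the fitted effects).
#' @param parc the subject's `spc_parcellation`.
#' @param mode `"map"` or `"self"`.
#' @param map_units `"z"` (default) or `"intensity"`.
#' @param delta_floor minimum usable `delta` (default 1e-2), applied with a
#'   flagging warning.
#' @return The harmonized `spc_volume`.
#' @export
harmonize_image <- function(img, scanner_id, maps = NULL, fit, parc,
                            mode = c("map", "self"),
                            map_units = c("z", "intensity"),
                            delta_floor = 1e-2) {
  mode <- match.arg(mode)
  map_units <- match.arg(map_units)
  stopifnot(is_volume(img), inherits(fit, "spc_combat_fit"),
            inherits(parc, "spc_parcellation"))
  check_same_grid(list(image = img, parcellation = parc$labels))
  lab <- parc$labels$labels
  inm <- lab > 0L
  labv <- lab[inm]
  m_vox <- fit$stats$m_hat[labv]
  s_vox <- fit$stats$sigma_hat[labv]
  if (mode == "self") {
    if (!(scanner_id %in% fit$stats$scanners))
      stop("harmonize_image: scanner '", scanner_id, "' not in the fit")
    g_vox <- fit$gamma_star[labv, scanner_id]
    d_vox <- fit$delta_star[labv, scanner_id]
  } else {
    if (is.null(maps) || !inherits(maps, "spc_effect_maps"))
      stop("harmonize_image: mode = 'map' requires an spc_effect_maps")
    if (!(scanner_id %in% names(maps$additive)))
      stop("harmonize_image: scanner '", scanner_id, "' missing from maps")
    check_same_grid(list(image = img,
                         `additive map` = maps$additive[[scanner_id]]))
    g_vox <- maps$additive[[scanner_id]]$data[inm]
    d_vox <- maps$multiplicative[[scanner_id]]$data[inm]
  }
  g_vox[!is.finite(g_vox)] <- 0
  nfloor <- sum(!is.finite(d_vox) | d_vox < delta_floor)
  if (nfloor > 0)
    warning("harmonize_image: ", nfloor, " voxel(s) with delta below ",
            delta_floor, "; floored")
  d_vox[!is.finite(d_vox)] <- 1
  d_vox <- pmax(d_vox, delta_floor)
  # neutral voxels (gamma 0, delta 1) are the exact identity; only the
  # rest are transformed
  act <- g_vox != 0 | d_vox != 1
  y <- img$data[inm][act]
  m_vox <- m_vox[act]; s_vox <- s_vox[act]
  g_vox <- g_vox[act]; d_vox <- d_vox[act]
  out <- img$data
  out[inm][act] <- if (map_units == "z") {
    s_vox * ((y - m_vox) / s_vox - g_vox) / d_vox + m_vox
  } else {
    (y - s_vox * g_vox) / d_vox
  }
  volume(out, spacing = img$spacing, space_tag = img$space_tag)
}

#' Re-estimate scanner effects on harmonized images
#'
#' The evaluation loop: refits the per-subject model on (harmonized) matched
#' sets, renders and group-averages the resulting maps, and, when tissue
#' masks are given, summarizes residual effects tissue-wise (one row per
#' scanner-tissue pair, with one-sample tests against the normative values
#' gamma = 0, delta = 1 when >= 2 subjects contribute). Residual additive
#' effects near zero and multiplicative effects near one indicate successful
#' harmonization.
#'
#' @param sets list of `spc_matched_set` (typically harmonized copies).
#' @param parcs list of `spc_parcellation`, parallel to `sets`.
#' @param tissue_masks optional named list of `spc_labels` tissue masks
#'   (or one `spc_labels` with labelled tissues) for the summary table.
#' @param eb_enabled passed to [fit_subject()] (default FALSE: raw residual
#'   effects, the directly interpretable quantity).
#' @param ... further arguments to [fit_subject()].
#' @return List: `maps` (group-average `spc_effect_maps`), `subject_maps`,
#'   `tissue_table` (NULL without masks).
#' @export
reestimate_residuals <- function(sets, parcs, tissue_masks = NULL,
                                 eb_enabled = FALSE, ...) {
  stopifnot(length(sets) == length(parcs), length(sets) >= 1L)
  subject_maps <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    fit <- fit_subject(sets[[k]], parcs[[k]], eb_enabled = eb_enabled, ...)
    subject_maps[[k]] <- render_maps(fit, parcs[[k]])
  }
  maps <- if (length(subject_maps) >= 2L) average_maps(subject_maps)
          else subject_maps[[1]]
  tissue_table <- if (!is.null(tissue_masks))
    tissue_effect_summary(subject_maps, tissue_masks)
  list(maps = maps, subject_maps = subject_maps, tissue_table = tissue_table)
}

#' Write effect maps as NIfTI pairs
#'
#' @param maps an `spc_effect_maps`.
#' @param dir existing output directory; writes
#'   `gamma_<scanner>.nii.gz` / `delta_<scanner>.nii.gz`.
#' @return Character vector of written paths, invisibly.
#' @export
write_effect_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "spc_effect_maps"))
  paths <- character(0)
  for (j in names(maps$additive)) {
    pg <- file.path(dir, paste0("gamma_", j, ".nii.gz"))
    pd <- file.path(dir, paste0("delta_", j, ".nii.gz"))
    write_volume(maps$additive[[j]], pg)
    write_volume(maps$multiplicative[[j]], pd)
    paths <- c(paths, pg, pd)
  }
  invisible(paths)
}

#' @export
print.spc_effect_maps <- function(x, ...) {
  cat(sprintf("<spc_effect_maps mode '%s', scanners %s, %d subject(s)>\n",
              x$mode, paste(names(x$additive), collapse = ", "),
              length(x$provenance)))
  invisible(x)
}
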