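# End-to-end pipeline: preprocess -> reference -> parcellate -> per-subject
# fit -> leave-one-out group maps -> harmonize -> re-estimate residuals ->
# reports. Driven by a JSON config; every artifact carries provenance
# (settings, seeds, package version) and reruns with the same config are
# identical.

#' Rebuild a parcellation object from a label volume
#'
#' Used when a parcellation is loaded back from disk: recomputes sizes and
#' centroids and fingerprints the reference image it belongs to.
#'
#' @param labels an `spc_labels` with superpixel ids (0 outside the mask).
#' @param reference the reference `spc_volume` the parcellation was built
#'   from (same grid).
#' @return An `spc_parcellation`.
#' @export
parcellation_from_labels <- function(labels, reference) {
  stopifnot(is_labels(labels), is_volume(reference))
  check_same_grid(list(reference = reference, labels = labels))
  lab <- compact_labels(labels$labels)
  new_parcellation(lab, reference, labels$spacing, labels$space_tag,
                   volume_fingerprint(reference))
}

#' Surrogate tissue volumes from intensity classification
#'
#' Assigns each in-mask voxel to the nearest of the supplied tissue means
#' and returns per-tissue volumes in ml. A deliberately simple stand-in for
#' the out-of-scope tissue segmentation, sufficient to study how scanner
#' effects propagate into volumetric estimates on phantoms (location shifts
#' move boundary voxels across class means).
#'
#' @param img `spc_volume`.
#' @param mask `spc_labels`.
#' @param means named per-tissue reference means (default the phantom's
#'   CSF/GM/WM defaults).
#' @return Named numeric vector of volumes (ml).
#' @export
estimate_tissue_volumes <- function(img, mask,
                                    means = c(CSF = 150, GM = 450,
                                              WM = 700)) {
  v <- mask_values(img, mask, "estimate_tissue_volumes")
  cls <- apply(abs(outer(v, means, `-`)), 1L, which.min)
  vox_ml <- prod(img$spacing) / 1000
  counts <- tabulate(cls, nbins = length(means))
  stats::setNames(counts * vox_ml, names(means))
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    phantom = list(),
    preprocess = list(normalize = FALSE, denoise = "identity"),
    parcellate = list(n_superpixels = NULL, min_size = 27L,
                      compactness = NULL, max_iter = 10L),
    fit = list(eb_enabled = TRUE, sigma_floor = 1e-3, delta_floor = 1e-2),
    harmonize = list(enabled = TRUE, loo = TRUE,
                     delta_mean = "geometric", map_units = "z"),
    evaluate = list(tissue_summary = TRUE, image_metrics = TRUE,
                    tissue_volumes = TRUE),
    write_images = FALSE, write_maps = FALSE)
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

tissue_masks_from_labels <- function(lab) {
  nm <- lab$label_names
  u <- sort(setdiff(unique(as.vector(lab$labels)), 0L))
  ms <- lapply(u, function(l)
    label_volume(array(as.integer(lab$labels == l), dim = lab$shape),
                 spacing = lab$spacing, space_tag = lab$space_tag))
  names(ms) <- if (!is.null(nm)) nm[as.character(u)] else as.character(u)
  ms
}

#' Run the full harmonization pipeline
#'
#' Executes, on a phantom cohort described by the config (or one supplied
#' in-memory): optional preprocessing, the cross-scanner reference image,
#' SLIC parcellation, the per-subject ComBat fit, individual map rendering,
#' leave-one-out group averaging, map-based harmonization, residual
#' re-estimation, and the evaluation reports. All tabular outputs are TSV;
#' provenance (the fully resolved config, seed, package version) is written
#' as JSON. Reruns with an identical config produce identical tables.
#'
#' @param config path to a JSON config file, or a list with the same
#'   structure; unspecified entries take package defaults. Recognized
#'   blocks: `seed`, `out_dir`, `phantom` (arguments of [phantom_spec()]),
#'   `preprocess` (`normalize`, `denoise`), `parcellate` (`n_superpixels`,
#'   `min_size`, `compactness`, `max_iter`), `fit` (`eb_enabled`,
#'   `sigma_floor`, `delta_floor`), `harmonize` (`enabled`, `loo`,
#'   `delta_mean`, `map_units`), `evaluate`, `write_images`, `write_maps`.
#' @param data optional pre-built input: a list with `sets` (list of
#'   `spc_matched_set`), `head_masks` and `tissue_labels` (per-subject
#'   `spc_labels`); when NULL a phantom cohort is generated from the
#'   `phantom` block.
#' @return Invisibly, a list with the fitted objects and report tables
#'   (`raw_tissue`, `residual_tissue`, `metrics`, `volumes`, `out_dir`).
#' @export
run_pipeline <- function(config = list(), data = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(default_pipeline_config(), config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir))
    out_dir <- tempfile("spcombat_pipeline_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  if (is.null(data)) {
    spec <- stage("simulate", do.call(phantom_spec, c(
      cfg$phantom, if (!("seed" %in% names(cfg$phantom)))
        list(seed = cfg$seed))))
    ph <- stage("simulate", make_phantom(spec))
    sets <- ph$sets
    tissue_labels <- ph$truth$labels
    head_masks <- lapply(tissue_labels, function(l)
      label_volume(array(as.integer(l$labels > 0L), dim = l$shape),
                   spacing = l$spacing, space_tag = l$space_tag))
    truth <- ph$truth
  } else {
    sets <- data$sets
    head_masks <- data$head_masks
    tissue_labels <- data$tissue_labels
    truth <- NULL
  }
  n_sub <- length(sets)
  subjects <- vapply(sets, function(s) s$subject_id, character(1))

  # --- preprocess ---------------------------------------------------------
  sets <- stage("preprocess", lapply(seq_len(n_sub), function(k) {
    imgs <- lapply(sets[[k]]$images, function(im) {
      im <- denoise_hook(im, cfg$preprocess$denoise)
      im <- remove_background(im, head_masks[[k]])
      if (isTRUE(cfg$preprocess$normalize))
        im <- normalize_intensity(im, head_masks[[k]])
      im
    })
    matched_image_set(sets[[k]]$subject_id, imgs)
  }))

  # --- reference + parcellation + per-subject fit -------------------------
  refs <- lapply(sets, average_reference)
  parcs <- stage("parcellate", lapply(seq_len(n_sub), function(k)
    slic3d(refs[[k]], head_masks[[k]],
           n_superpixels = cfg$parcellate$n_superpixels,
           compactness = cfg$parcellate$compactness,
           max_iter = cfg$parcellate$max_iter, seed = cfg$seed,
           min_size = cfg$parcellate$min_size)))
  fits <- stage("fit", lapply(seq_len(n_sub), function(k)
    fit_subject(sets[[k]], parcs[[k]], eb_enabled = cfg$fit$eb_enabled,
                sigma_floor = cfg$fit$sigma_floor,
                min_size = max(2L, cfg$parcellate$min_size),
                delta_floor = cfg$fit$delta_floor)))
  subject_maps <- lapply(seq_len(n_sub), function(k)
    render_maps(fits[[k]], parcs[[k]]))

  tmasks <- if (!is.null(tissue_labels))
    lapply(tissue_labels, tissue_masks_from_labels)
  raw_tissue <- if (!is.null(tmasks)) {
    # per-subject maps sampled in that subject's own tissue masks
    tabs <- lapply(seq_len(n_sub), function(k)
      cbind(subject = subjects[k],
            tissue_effect_summary(subject_maps[[k]], tmasks[[k]])))
    agg <- tissue_effect_summary_pooled(subject_maps, tmasks)
    list(per_subject = do.call(rbind, tabs), pooled = agg)
  }

  # --- harmonize (leave-one-out group maps) -------------------------------
  harmonized <- NULL
  residual <- NULL
  if (isTRUE(cfg$harmonize$enabled)) {
    harmonized <- stage("harmonize", lapply(seq_len(n_sub), function(k) {
      gm <- if (isTRUE(cfg$harmonize$loo) && n_sub >= 3L) {
        average_maps(subject_maps, exclude_subject = subjects[k],
                     delta_mean = cfg$harmonize$delta_mean)
      } else if (n_sub >= 2L) {
        average_maps(subject_maps, delta_mean = cfg$harmonize$delta_mean)
      } else {
        subject_maps[[k]]
      }
      imgs <- lapply(scanners_of(sets[[k]]), function(j)
        harmonize_image(sets[[k]]$images[[j]], j, maps = gm,
                        fit = fits[[k]], parc = parcs[[k]], mode = "map",
                        map_units = cfg$harmonize$map_units,
                        delta_floor = cfg$fit$delta_floor))
      names(imgs) <- scanners_of(sets[[k]])
      matched_image_set(sets[[k]]$subject_id, imgs)
    }))
    residual <- stage("reestimate", reestimate_residuals(
      harmonized, parcs, tissue_masks = NULL, eb_enabled = FALSE))
    residual$tissue <- if (!is.null(tmasks))
      list(per_subject = do.call(rbind, lapply(seq_len(n_sub), function(k)
        cbind(subject = subjects[k],
              tissue_effect_summary(residual$subject_maps[[k]],
                                    tmasks[[k]])))),
        pooled = tissue_effect_summary_pooled(residual$subject_maps, tmasks))
  } else {
    # harmonization disabled: residuals are the raw estimates
    residual <- list(subject_maps = subject_maps, tissue = raw_tissue)
  }

  # --- evaluation ---------------------------------------------------------
  metrics_tab <- NULL
  volumes_tab <- NULL
  if (isTRUE(cfg$evaluate$image_metrics) && !is.null(tmasks)) {
    rows <- list()
    for (k in seq_len(n_sub)) {
      tm <- tmasks[[k]]
      for (cond in c("raw", if (!is.null(harmonized)) "harmonized")) {
        st <- if (cond == "raw") sets[[k]] else harmonized[[k]]
        for (j in scanners_of(st)) {
          im <- st$images[[j]]
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects[k], scanner = j, condition = cond,
            cjv = cjv(im, tm$GM, tm$WM), cnr = cnr(im, tm$GM, tm$WM),
            snr_wm = snr(im, tm$WM),
            wm2max = wm2max(im, tm$WM, head_masks[[k]]))
        }
        sc <- scanners_of(st)
        if (length(sc) >= 2L) {
          prs <- utils::combn(sc, 2L)
          ss <- mean(apply(prs, 2L, function(p)
            ssim(st$images[[p[1]]], st$images[[p[2]]],
                 mask = head_masks[[k]])))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects[k], scanner = "cross-scanner",
            condition = cond, cjv = NA, cnr = NA, snr_wm = NA,
            wm2max = ss)  # ssim stored in the last column for pairs
        }
      }
    }
    metrics_tab <- do.call(rbind, rows)
    names(metrics_tab)[names(metrics_tab) == "wm2max"] <- "wm2max_or_ssim"
  }
  if (isTRUE(cfg$evaluate$tissue_volumes) && !is.null(tmasks)) {
    vrows <- list()
    for (k in seq_len(n_sub))
      for (cond in c("raw", if (!is.null(harmonized)) "harmonized")) {
        st <- if (cond == "raw") sets[[k]] else harmonized[[k]]
        for (j in scanners_of(st)) {
          tv <- estimate_tissue_volumes(st$images[[j]], head_masks[[k]])
          vrows[[length(vrows) + 1L]] <- data.frame(
            subject = subjects[k], scanner = j, condition = cond,
            region = names(tv), volume = unname(tv))
        }
      }
    volumes_tab <- do.call(rbind, vrows)
  }

  # --- artifacts ----------------------------------------------------------
  wt <- function(x, name) if (!is.null(x))
    data.table::fwrite(data.table::as.data.table(x),
                       file.path(out_dir, name), sep = "\t")
  if (!is.null(raw_tissue)) {
    wt(raw_tissue$per_subject, "tissue_effects_raw_per_subject.tsv")
    wt(raw_tissue$pooled, "tissue_effects_raw.tsv")
  }
  if (!is.null(residual$tissue)) {
    wt(residual$tissue$per_subject, "tissue_effects_residual_per_subject.tsv")
    wt(residual$tissue$pooled, "tissue_effects_residual.tsv")
  }
  wt(metrics_tab, "image_metrics.tsv")
  wt(volumes_tab, "tissue_volumes.tsv")
  if (isTRUE(cfg$write_maps) && n_sub >= 2L)
    write_effect_maps(average_maps(subject_maps,
                                   delta_mean = cfg$harmonize$delta_mean),
                      out_dir)
  if (isTRUE(cfg$write_images) && !is.null(harmonized))
    for (k in seq_len(n_sub))
      for (j in scanners_of(harmonized[[k]]))
        write_volume(harmonized[[k]]$images[[j]],
                     file.path(out_dir, sprintf("%s_%s_harmonized.nii.gz",
                                                subjects[k], j)))
  prov <- list(package = "spcombat",
               version = as.character(utils::packageVersion("spcombat")),
               seed = cfg$seed, config = cfg,
               subjects = subjects,
               n_superpixels = vapply(parcs, function(p) p$n_features,
                                      numeric(1)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(
    config = cfg, out_dir = out_dir, sets = sets, parcs = parcs,
    fits = fits, subject_maps = subject_maps, harmonized = harmonized,
    residual = residual, raw_tissue = raw_tissue, metrics = metrics_tab,
    volumes = volumes_tab, truth = truth))
}

# pooled variant: each subject's maps sampled in its own masks, rows
# aggregated across subjects with the one-sample tests of
# tissue_effect_summary (subject tissue means as observations)
tissue_effect_summary_pooled <- function(subject_maps, tmask_list) {
  scanners <- names(subject_maps[[1]]$additive)
  tissues <- names(tmask_list[[1]])
  one_test <- function(x, null) {
    if (length(x) < 2L || stats::sd(x) == 0) {
      if (length(x) >= 2L && all(x == null)) return(c(t = 0, p = 1))
      return(c(t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x, mu = null)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  rows <- list()
  for (j in scanners) for (tn in tissues) {
    gm <- vapply(seq_along(subject_maps), function(k) {
      inm <- tmask_list[[k]][[tn]]$labels != 0L
      mean(subject_maps[[k]]$additive[[j]]$data[inm])
    }, numeric(1))
    dm <- vapply(seq_along(subject_maps), function(k) {
      inm <- tmask_list[[k]][[tn]]$labels != 0L
      mean(subject_maps[[k]]$multiplicative[[j]]$data[inm])
    }, numeric(1))
    tg <- one_test(gm, 0)
    td <- one_test(dm, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      scanner = j, tissue = tn, n_subjects = length(gm),
      mean_gamma = mean(gm), t_gamma = tg["t"], p_gamma = tg["p"],
      mean_delta = mean(dm), t_delta = td["t"], p_delta = td["p"],
      row.names = NULL)
  }
  do.call(rbind, rows)
}
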