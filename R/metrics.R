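# Image-quality and harmonization-evaluation metrics: SNR, CNR, CJV,
# WM2MAX, 3D SSIM, tissue-wise effect summaries with one-sample tests,
# cross-scanner coefficients of variation, Cohen's d.

mask_values <- function(img, mask, what = "metric") {
  stopifnot(is_volume(img), is_labels(mask))
  check_same_grid(list(image = img, mask = mask))
  v <- img$data[mask$labels != 0L]
  if (length(v) < 2L) stop(what, ": mask must contain >= 2 voxels")
  v
}

#' Signal-to-noise ratio within a tissue
#'
#' Mean in-tissue intensity over its spread. The default spread is the
#' standard deviation (the convention under which published magnitudes of
#' this metric are scale-free); `noise = "variance"` divides by the variance
#' literally.
#'
#' @param img `spc_volume`.
#' @param tissue_mask `spc_labels` (non-zero = tissue).
#' @param noise `"sd"` (default) or `"variance"`.
#' @return Scalar SNR.
#' @export
snr <- function(img, tissue_mask, noise = c("sd", "variance")) {
  noise <- match.arg(noise)
  v <- mask_values(img, tissue_mask, "snr")
  s <- stats::sd(v)
  if (s == 0) stop("snr: zero within-tissue spread")
  mean(v) / if (noise == "sd") s else s^2
}

#' Contrast-to-noise ratio between GM and WM
#'
#' `|mu_WM - mu_GM| / sqrt(sigma_GM^2 + sigma_WM^2)`. The air-noise term of
#' some formulations is omitted because background is zeroed upstream.
#' Invariant under global affine intensity changes.
#'
#' @param img `spc_volume`.
#' @param gm_mask,wm_mask `spc_labels` tissue masks.
#' @return Scalar CNR.
#' @export
cnr <- function(img, gm_mask, wm_mask) {
  g <- mask_values(img, gm_mask, "cnr")
  w <- mask_values(img, wm_mask, "cnr")
  den <- sqrt(stats::var(g) + stats::var(w))
  if (den == 0) {
    if (mean(w) == mean(g)) return(0)
    stop("cnr: zero spread in both tissues")
  }
  abs(mean(w) - mean(g)) / den
}

#' Coefficient of joint variation of GM and WM
#'
#' `(sigma_WM + sigma_GM) / |mu_WM - mu_GM|`; rises with head motion and
#' intensity non-uniformity, and is the quantity bias-field modulation
#' inflates.
#'
#' @inheritParams cnr
#' @return Scalar CJV.
#' @export
cjv <- function(img, gm_mask, wm_mask) {
  g <- mask_values(img, gm_mask, "cjv")
  w <- mask_values(img, wm_mask, "cjv")
  dm <- abs(mean(w) - mean(g))
  if (dm == 0) stop("cjv: equal GM and WM means")
  (stats::sd(w) + stats::sd(g)) / dm
}

#' White-matter median to high-percentile intensity ratio
#'
#' Median WM intensity relative to the 95th percentile of the in-head
#' intensity distribution; hyperintense outliers (vessels, fat) depress it.
#' `denom = "wm"` uses the 95th percentile of the WM distribution itself
#' (which pins the metric near 1 by construction).
#'
#' @param img `spc_volume`.
#' @param wm_mask `spc_labels` WM mask.
#' @param head_mask `spc_labels` over which the denominator percentile is
#'   taken when `denom = "global"`; defaults to all voxels > 0.
#' @param denom `"global"` (default) or `"wm"`.
#' @return Scalar ratio.
#' @export
wm2max <- function(img, wm_mask, head_mask = NULL,
                   denom = c("global", "wm")) {
  denom <- match.arg(denom)
  w <- mask_values(img, wm_mask, "wm2max")
  pool <- if (denom == "wm") {
    w
  } else if (!is.null(head_mask)) {
    mask_values(img, head_mask, "wm2max")
  } else {
    img$data[img$data > 0]
  }
  p95 <- stats::quantile(pool, 0.95, names = FALSE, type = 7)
  if (p95 == 0) stop("wm2max: zero denominator percentile")
  stats::median(w) / p95
}

#' Structural similarity index of two volumes
#'
#' Standard SSIM with Gaussian-weighted local windows (default 7^3 taps,
#' sigma 1.5) and stabilizers `C1 = (0.01 * data_range)^2`,
#' `C2 = (0.03 * data_range)^2`, averaged over in-mask voxels. Symmetric in
#' its two arguments; equals 1 for identical inputs.
#'
#' @param a,b `spc_volume` on one grid.
#' @param mask optional `spc_labels`; defaults to all voxels.
#' @param window odd window width (default 7).
#' @param sigma Gaussian window SD in voxels (default 1.5).
#' @param data_range intensity dynamic range (default 1000, the normalized
#'   scale).
#' @return Scalar mean SSIM.
#' @export
ssim <- function(a, b, mask = NULL, window = 7L, sigma = 1.5,
                 data_range = 1000) {
  stopifnot(is_volume(a), is_volume(b), data_range > 0)
  vols <- list(a = a, b = b)
  if (!is.null(mask)) vols$mask <- mask
  check_same_grid(vols)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("ssim: window must be a positive odd integer")
  half <- window %/% 2L
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  dims <- as.integer(a$shape)
  f <- function(x) cpp_sep_conv3(as.vector(x), dims, k)
  av <- as.vector(a$data); bv <- as.vector(b$data)
  mu_a <- f(av); mu_b <- f(bv)
  va <- f(av * av) - mu_a^2
  vb <- f(bv * bv) - mu_b^2
  vab <- f(av * bv) - mu_a * mu_b
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  if (is.null(mask)) mean(s) else mean(s[as.vector(mask$labels != 0L)])
}

#' Tissue-wise summary of scanner effects with one-sample tests
#'
#' Samples each subject's individual effect maps within each tissue mask,
#' takes subject-level tissue means as the observations (the subject is the
#' unit of analysis), and tests the additive effects against 0 and the
#' multiplicative effects against 1 with two-sided one-sample t tests (no
#' multiplicity correction). With a single subject, means are reported and
#' the test columns are NA.
#'
#' @param subject_maps list of `spc_effect_maps` (one per subject), or a
#'   single `spc_effect_maps`.
#' @param tissue_masks either one `spc_labels` whose labels (with
#'   `label_names`) define the tissues, or a named list of binary
#'   `spc_labels`.
#' @return `data.frame` with one row per (scanner, tissue):
#'   `mean_gamma`, `t_gamma`, `p_gamma`, `mean_delta`, `t_delta`, `p_delta`,
#'   `n_subjects`.
#' @export
tissue_effect_summary <- function(subject_maps, tissue_masks) {
  if (inherits(subject_maps, "spc_effect_maps"))
    subject_maps <- list(subject_maps)
  masks <- if (is_labels(tissue_masks)) {
    u <- sort(setdiff(unique(as.vector(tissue_masks$labels)), 0L))
    nm <- if (!is.null(tissue_masks$label_names))
      tissue_masks$label_names[as.character(u)] else as.character(u)
    ms <- lapply(u, function(l)
      label_volume(array(as.integer(tissue_masks$labels == l),
                         dim = tissue_masks$shape),
                   spacing = tissue_masks$spacing,
                   space_tag = tissue_masks$space_tag))
    names(ms) <- nm
    ms
  } else tissue_masks
  scanners <- names(subject_maps[[1]]$additive)
  one_test <- function(x, null) {
    if (length(x) < 2L || stats::sd(x) == 0) {
      if (length(x) >= 2L && all(x == null)) return(c(t = 0, p = 1))
      return(c(t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x, mu = null)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  rows <- list()
  for (j in scanners) for (tn in names(masks)) {
    inm <- masks[[tn]]$labels != 0L
    gm <- vapply(subject_maps, function(m) mean(m$additive[[j]]$data[inm]),
                 numeric(1))
    dm <- vapply(subject_maps,
                 function(m) mean(m$multiplicative[[j]]$data[inm]),
                 numeric(1))
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

#' Cross-scanner coefficient of variation of regional volumes
#'
#' For each (subject, region): `CV = sd / mean` over that subject's
#' per-scanner volume estimates (sample-SD convention); region-level summary
#' is the mean CV over subjects.
#'
#' @param volumes_table `data.frame` with columns `subject`, `scanner`,
#'   `region`, `volume` (>= 2 scanners per subject-region; volumes with zero
#'   mean are an error).
#' @return List: `per_subject` (subject, region, cv) and `per_region`
#'   (region, mean_cv, n_subjects).
#' @export
cv_across_scanners <- function(volumes_table) {
  stopifnot(all(c("subject", "scanner", "region", "volume") %in%
                  names(volumes_table)))
  dt <- data.table::as.data.table(volumes_table)
  per <- dt[, {
    if (.N < 2L)
      stop("cv_across_scanners: need >= 2 scanners for subject ",
           subject[1], ", region ", region[1])
    m <- mean(volume)
    if (m == 0)
      stop("cv_across_scanners: zero mean volume for subject ",
           subject[1], ", region ", region[1])
    list(cv = stats::sd(volume) / m)
  }, by = c("subject", "region")]
  reg <- per[, list(mean_cv = mean(cv), n_subjects = .N), by = "region"]
  list(per_subject = as.data.frame(per), per_region = as.data.frame(reg))
}

#' Percent reduction between two coefficient-of-variation estimates
#'
#' @param cv_before,cv_after scalar CVs.
#' @return Percent reduction, `100 * (before - after) / before`.
#' @export
cv_reduction <- function(cv_before, cv_after) {
  if (cv_before == 0) stop("cv_reduction: zero baseline CV")
  100 * (cv_before - cv_after) / cv_before
}

#' Cohen's d effect size
#'
#' `(mean_A - mean_B) / s_pooled`, with the pooled SD weighted by
#' `(n_A - 1, n_B - 1)`. A seeded bootstrap SD of the estimate is available.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param bootstrap number of bootstrap resamples for an SD estimate
#'   (0 = none).
#' @param seed RNG seed used when `bootstrap > 0`.
#' @return Scalar d, with attribute `boot_sd` when bootstrapped.
#' @export
cohens_d <- function(group_a, group_b, bootstrap = 0L, seed = 1L) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b)) return(0)
    stop("cohens_d: zero pooled SD with unequal means")
  }
  d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
  if (bootstrap > 0L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    bs <- replicate(bootstrap, {
      a <- sample(group_a, na, replace = TRUE)
      b <- sample(group_b, nb, replace = TRUE)
      s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
        (na + nb - 2)
      if (s2 == 0) NA_real_ else (mean(a) - mean(b)) / sqrt(s2)
    })
    attr(d, "boot_sd") <- stats::sd(bs, na.rm = TRUE)
  }
  d
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
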