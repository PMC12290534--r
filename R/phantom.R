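# Synthetic matched multi-scanner brain phantoms with known ground-truth
# location/scale scanner effects, optional smooth multiplicative bias
# fields, and additive Gaussian noise, on a 3-tissue (CSF/GM/WM)
# nested-ellipsoid geometry. Every run is fully determined by the spec seed,
# and the images of one subject are perfectly co-registered by construction.

TISSUES <- c("CSF", "GM", "WM")

#' Map inversion-time differences to per-tissue signal shifts
#'
#' A convenience preset for realistic phantoms: longer inversion time tends
#' to reduce CSF signal and increase GM/WM signal, so centered TI (relative
#' to the scanner-mean TI) is mapped to per-tissue standardized shifts with a
#' negative slope for CSF and positive slopes for GM and WM. The mean-TI
#' scanner gets zero shift; equal TIs give all-zero shifts.
#'
#' @param ti_values named numeric vector of inversion times in ms, one per
#'   scanner (all > 0).
#' @param slopes per-tissue shift per ms of centered TI, in SD units
#'   (default `c(CSF = -1, GM = 1, WM = 1) * 1e-3`).
#' @param scales optional named per-scanner multiplicative scale factor
#'   applied to every tissue (default all 1).
#' @return Named list scanner -> `list(shift = c(CSF, GM, WM), scale = ...)`,
#'   the `scanner_effects` slot of [phantom_spec()].
#' @export
ti_contrast_preset <- function(ti_values,
                               slopes = c(CSF = -1, GM = 1, WM = 1) * 1e-3,
                               scales = NULL) {
  stopifnot(all(ti_values > 0), !is.null(names(ti_values)))
  slopes <- slopes[TISSUES]
  ti_c <- ti_values - mean(ti_values)
  out <- lapply(seq_along(ti_values), function(k) {
    sc <- if (is.null(scales)) 1 else scales[[names(ti_values)[k]]]
    list(shift = slopes * ti_c[k],
         scale = stats::setNames(rep(sc, 3L), TISSUES))
  })
  names(out) <- names(ti_values)
  out
}

#' Specification of a synthetic multi-scanner phantom cohort
#'
#' Defaults describe the desk-scale test bed: a 96^3 grid at 1.5 mm, eight
#' subjects, four scanners whose per-tissue shifts follow the
#' inversion-time preset for TIs (600, 1300, 1100, 1200) ms and whose scale
#' factors differ modestly, T1w-ordered tissue means CSF 150 < GM 450 <
#' WM 700 on the normalized 0-1000 scale, additive Gaussian noise of SD 10,
#' and no bias field. `shape_preset = "mni"` switches to a 121x145x121 grid
#' for superpixel-count studies.
#'
#' @param shape integer length-3 grid (default `c(96, 96, 96)`).
#' @param spacing voxel size mm (default 1.5 isotropic).
#' @param n_subjects number of traveling subjects (default 8).
#' @param base_means,base_sds per-tissue intensity mean/SD, named CSF/GM/WM.
#' @param scanner_effects named list scanner -> `list(shift, scale)`, each a
#'   CSF/GM/WM-named vector; shifts are additive in within-tissue SD units,
#'   scales multiply the within-tissue SD. Default: TI preset plus scale
#'   factors `(1.10, 0.90, 1.00, 1.05)`.
#' @param radii outer semi-axis fractions of the half-extent for the
#'   CSF/GM/WM shells (nested, strictly decreasing).
#' @param deform_amplitude per-subject relative jitter of shell radii
#'   (default 0.03) plus a one-voxel center jitter; gives each subject its
#'   own anatomy.
#' @param bias_field NULL (off) or `list(amplitude, width)`: each scanner
#'   gets a smooth multiplicative field `1 + amplitude * exp(-r^2/2 width^2)`
#'   centered at a scanner-specific offset, width in voxels.
#' @param noise_sd additive Gaussian measurement noise SD (default 10).
#' @param seed RNG seed fixing the whole cohort (default 1).
#' @param shape_preset `"desk"` (default) or `"mni"`.
#' @return An object of class `spc_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing = c(1.5, 1.5, 1.5),
                         n_subjects = 8L,
                         base_means = c(CSF = 150, GM = 450, WM = 700),
                         base_sds = c(CSF = 30, GM = 40, WM = 35),
                         scanner_effects = NULL,
                         radii = c(CSF = 0.85, GM = 0.72, WM = 0.50),
                         deform_amplitude = 0.03,
                         bias_field = NULL,
                         noise_sd = 10, seed = 1L,
                         shape_preset = c("desk", "mni")) {
  shape_preset <- match.arg(shape_preset)
  if (shape_preset == "mni") {
    shape <- c(121L, 145L, 121L)
    spacing <- c(1.5, 1.5, 1.5)
  }
  if (is.null(scanner_effects))
    scanner_effects <- ti_contrast_preset(
      c(GE = 600, Philips = 1300, SiemensP = 1100, SiemensT = 1200),
      scales = list(GE = 1.10, Philips = 0.90, SiemensP = 1.00,
                    SiemensT = 1.05))
  base_means <- base_means[TISSUES]
  base_sds <- base_sds[TISSUES]
  if (any(diff(base_means) <= 0))
    stop("phantom_spec: tissue means must be strictly ordered CSF < GM < WM")
  if (any(base_sds <= 0) || noise_sd < 0)
    stop("phantom_spec: base_sds must be > 0 and noise_sd >= 0")
  if (any(diff(radii[TISSUES]) >= 0) || any(radii <= 0) || any(radii > 1))
    stop("phantom_spec: shell radii must be nested (CSF > GM > WM, in (0,1])")
  for (j in names(scanner_effects)) {
    se <- scanner_effects[[j]]
    if (!all(TISSUES %in% names(se$shift)) ||
        !all(TISSUES %in% names(se$scale)))
      stop("phantom_spec: scanner_effects[['", j,
           "']] needs CSF/GM/WM-named shift and scale")
    if (any(se$scale[TISSUES] <= 0))
      stop("phantom_spec: scale factors must be > 0")
  }
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         n_subjects = as.integer(n_subjects), base_means = base_means,
         base_sds = base_sds, scanner_effects = scanner_effects,
         radii = radii[TISSUES], deform_amplitude = deform_amplitude,
         bias_field = bias_field, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "spc_phantom_spec")
}

phantom_labels <- function(spec, radius_jitter, center_jitter) {
  shape <- spec$shape
  half <- (shape - 1) / 2
  ctr <- half + center_jitter
  a_out <- spec$radii[["CSF"]] * half * (1 + radius_jitter)
  xs <- ((seq_len(shape[1]) - 1 - ctr[1]) / a_out[1])^2
  ys <- ((seq_len(shape[2]) - 1 - ctr[2]) / a_out[2])^2
  zs <- ((seq_len(shape[3]) - 1 - ctr[3]) / a_out[3])^2
  rho2 <- outer(outer(xs, ys, `+`), zs, `+`)
  t_gm <- (spec$radii[["GM"]] / spec$radii[["CSF"]])^2
  t_wm <- (spec$radii[["WM"]] / spec$radii[["CSF"]])^2
  lab <- array(0L, dim = shape)
  lab[rho2 <= 1] <- 1L
  lab[rho2 <= t_gm] <- 2L
  lab[rho2 <= t_wm] <- 3L
  if (!any(lab == 3L)) stop("phantom geometry degenerate: empty WM core")
  label_volume(lab, spacing = spec$spacing, space_tag = "phantom-grid",
               label_names = stats::setNames(TISSUES, 1:3))
}

phantom_bias_field <- function(spec, scanner_index) {
  shape <- spec$shape
  bf <- spec$bias_field
  if (is.null(bf) || bf$amplitude == 0) return(NULL)
  half <- (shape - 1) / 2
  # deterministic per-scanner blob center on alternating octants
  sgn <- c(1, -1, 1, -1, 1, -1)[1 + (scanner_index - 1) %% 6]
  off <- half * 0.4 * sgn * c(1, (-1)^scanner_index, 1)
  ctr <- half + off
  w2 <- 2 * bf$width^2
  xs <- (seq_len(shape[1]) - 1 - ctr[1])^2
  ys <- (seq_len(shape[2]) - 1 - ctr[2])^2
  zs <- (seq_len(shape[3]) - 1 - ctr[3])^2
  r2 <- outer(outer(xs, ys, `+`), zs, `+`)
  1 + bf$amplitude * exp(-r2 / w2)
}

#' Generate a matched multi-scanner phantom cohort
#'
#' For each subject a seeded, slightly deformed nested-ellipsoid CSF/GM/WM
#' label map is built; for each scanner `j` and tissue `t`, voxel values are
#' \deqn{Y = (\mu_t + shift_{jt} \sigma_t) + scale_{jt} \sigma_t \eta + \epsilon}
#' all multiplied by the scanner's bias field, with the anatomy term
#' \eqn{\eta \sim N(0,1)} drawn once per voxel per subject (shared across
#' scanners: with null effects and zero noise all scanners are identical)
#' and measurement noise \eqn{\epsilon \sim N(0, noise\_sd^2)} independent
#' per scanner. Background voxels are zero.
#'
#' The ground-truth sidecar includes the programmed (shift, scale) and the
#' standardized effects the per-superpixel model should recover in
#' pure-tissue regions without bias field: with pooled within-scanner
#' variance \eqn{\sigma_{pool,t}^2 = \sigma_t^2 mean_j(scale_{jt}^2) +
#' noise\_sd^2},
#' \eqn{\gamma_{jt} = (shift_{jt} - mean_j shift_{jt}) \sigma_t /
#' \sigma_{pool,t}} and
#' \eqn{\delta_{jt} = \sqrt{scale_{jt}^2 \sigma_t^2 + noise\_sd^2} /
#' \sigma_{pool,t}}.
#'
#' @param spec an [phantom_spec()].
#' @return List with `sets` (per-subject `spc_matched_set`), `truth`: a list
#'   with `labels` (per-subject `spc_labels`), `effects` (`data.frame` of
#'   scanner, tissue, shift, scale, gamma_true, delta_true), `bias_fields`
#'   (per-scanner arrays or NULL), and the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "spc_phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  scanners <- names(spec$scanner_effects)
  nvox <- prod(spec$shape)
  bias <- lapply(seq_along(scanners), function(k)
    phantom_bias_field(spec, k))
  names(bias) <- scanners
  sets <- vector("list", spec$n_subjects)
  labels <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    rj <- stats::runif(3, -spec$deform_amplitude, spec$deform_amplitude)
    cj <- stats::runif(3, -1, 1)
    lab <- phantom_labels(spec, rj, cj)
    labels[[s]] <- lab
    tidx <- as.vector(lab$labels)          # 0..3
    eta <- stats::rnorm(nvox)
    imgs <- list()
    for (j in scanners) {
      se <- spec$scanner_effects[[j]]
      mu <- c(0, spec$base_means + se$shift[TISSUES] * spec$base_sds)
      sc <- c(0, se$scale[TISSUES] * spec$base_sds)
      v <- mu[tidx + 1L] + sc[tidx + 1L] * eta
      if (spec$noise_sd > 0) {
        eps <- stats::rnorm(nvox, sd = spec$noise_sd)
        v <- v + ifelse(tidx > 0L, eps, 0)
      }
      if (!is.null(bias[[j]])) v <- v * as.vector(bias[[j]])
      v[tidx == 0L] <- 0
      imgs[[j]] <- volume(array(v, dim = spec$shape),
                          spacing = spec$spacing, space_tag = "phantom-grid")
    }
    sets[[s]] <- matched_image_set(sprintf("sub-%02d", s), imgs)
  }
  sd_t <- spec$base_sds
  eff <- do.call(rbind, lapply(TISSUES, function(t) {
    shifts <- vapply(scanners, function(j)
      spec$scanner_effects[[j]]$shift[[t]], numeric(1))
    scales <- vapply(scanners, function(j)
      spec$scanner_effects[[j]]$scale[[t]], numeric(1))
    sig_pool <- sqrt(sd_t[[t]]^2 * mean(scales^2) + spec$noise_sd^2)
    data.frame(scanner = scanners, tissue = t, shift = shifts,
               scale = scales,
               gamma_true = (shifts - mean(shifts)) * sd_t[[t]] / sig_pool,
               delta_true = sqrt(scales^2 * sd_t[[t]]^2 + spec$noise_sd^2) /
                 sig_pool,
               row.names = NULL)
  }))
  list(sets = sets,
       truth = list(labels = labels, effects = eff, bias_fields = bias),
       spec = spec)
}
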