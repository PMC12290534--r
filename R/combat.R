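# Per-subject ComBat location-scale fit within superpixels.
#
# Model, per superpixel f, voxel i, scanner j:
#     Y_ijf = m_f + gamma_jf + delta_jf * eps_ijf,   eps ~ N(0, sigma_f^2)
# Standardized Z_ijf = (Y_ijf - m_hat_f) / sigma_hat_f ~ N(gamma_jf, delta_jf^2),
# with priors gamma_jf ~ N(mu_j, tau_j^2), delta_jf^2 ~ InvGamma(lambda_j, theta_j).
# Harmonization back-transform: Y* = sigma_hat_f * (Z - gamma_hat) / delta_hat + m_hat_f.
# The matched traveling-subject design needs no biological covariates, and all
# parameters are estimated separately per subject.

#' Per-feature pooled statistics and raw scanner effects
#'
#' For every superpixel `f`: the grand mean `m_hat_f` over all scanners'
#' voxels, the pooled within-scanner residual SD `sigma_hat_f` (residuals
#' `Y_ijf - Ybar_jf`, denominator `N_f - J`, so standardized data have unit
#' variance within scanner under `delta = 1`), and per scanner the raw
#' standardized location effect `gamma_raw_jf = (Ybar_jf - m_hat_f) /
#' sigma_hat_f` and scale effect `delta2_raw_jf = s2_jf / sigma_hat_f^2`
#' (the sample variance of Z within `(j, f)`, denominator `n_jf - 1`).
#'
#' Degenerate features with pooled SD below `sigma_floor` are floored and
#' flagged, never zero-divided; features whose per-scanner count falls below
#' `min_size` are flagged as unmodeled (possible only on a mask/parcellation
#' mismatch) and excluded from hyperparameter fitting.
#'
#' @param set an `spc_matched_set`.
#' @param parc an `spc_parcellation` on the same grid.
#' @param sigma_floor lower bound for `sigma_hat` on the normalized 0-1000
#'   scale (default 1e-3).
#' @param min_size per-(scanner, feature) observation floor (default 27).
#' @return List with `stats` (class `spc_feature_stats`: `m_hat`,
#'   `sigma_hat`, `n` features-by-scanners count matrix, `sigma_floored`,
#'   `modeled` flags), `gamma_raw` and `delta2_raw` (features-by-scanners
#'   matrices).
#' @export
estimate_feature_stats <- function(set, parc, sigma_floor = 1e-3,
                                   min_size = 27L) {
  stopifnot(inherits(set, "spc_matched_set"),
            inherits(parc, "spc_parcellation"))
  check_same_grid(c(set$images, list(parcellation = parc$labels)))
  lab <- parc$labels$labels
  idx <- which(lab > 0L)
  fvec <- lab[idx]
  J <- length(set$images)
  scanners <- scanners_of(set)
  K <- parc$n_features

  dt <- data.table::rbindlist(lapply(scanners, function(j)
    data.table::data.table(f = fvec, scanner = j,
                           y = set$images[[j]]$data[idx])))
  per_jf <- dt[, list(n = .N, ybar = mean(y),
                      s2 = if (.N > 1L) stats::var(y) else 0),
               by = c("f", "scanner")]
  per_f <- per_jf[, list(
    m_hat = sum(n * ybar) / sum(n),
    rss = sum((n - 1) * s2),
    N = sum(n),
    J_f = .N), by = "f"]
  data.table::setorder(per_f, f)
  sigma2 <- per_f$rss / pmax(per_f$N - per_f$J_f, 1L)
  sigma_hat <- sqrt(sigma2)
  floored <- sigma_hat < sigma_floor
  sigma_hat[floored] <- sigma_floor

  m_hat <- per_f$m_hat
  gamma_raw <- delta2_raw <- nmat <-
    matrix(NA_real_, nrow = K, ncol = J, dimnames = list(NULL, scanners))
  for (j in scanners) {
    pj <- per_jf[per_jf$scanner == j, ]
    data.table::setorder(pj, f)
    gamma_raw[pj$f, j] <- (pj$ybar - m_hat[pj$f]) / sigma_hat[pj$f]
    delta2_raw[pj$f, j] <- pj$s2 / sigma_hat[pj$f]^2
    nmat[pj$f, j] <- pj$n
  }
  modeled <- apply(nmat, 1L, function(r) all(is.finite(r) & r >= min_size))
  stats <- structure(
    list(m_hat = m_hat, sigma_hat = sigma_hat, n = nmat,
         sigma_floored = floored, modeled = modeled,
         scanners = scanners, n_features = K),
    class = "spc_feature_stats")
  list(stats = stats, gamma_raw = gamma_raw, delta2_raw = delta2_raw)
}

#' Method-of-moments empirical-Bayes hyperparameters
#'
#' Per scanner `j`, over modeled features: `mu_j` and `tau2_j` are the sample
#' mean and variance of the raw location effects; for the inverse-gamma scale
#' prior, with `Vbar = mean(delta2_raw)` and `S = var(delta2_raw)`,
#' `lambda = (Vbar^2 + 2 S) / S` and `theta = (Vbar^3 + Vbar S) / S` (the
#' moment inversion of an InvGamma(lambda, theta) with mean Vbar and
#' variance S). This is the standard ComBat construction.
#'
#' @param gamma_raw,delta2_raw features-by-scanners matrices.
#' @param modeled optional logical feature filter.
#' @return An `spc_eb_hyper` object: named numeric vectors `mu`, `tau2`,
#'   `lambda`, `theta` indexed by scanner.
#' @export
fit_eb_hyperparameters <- function(gamma_raw, delta2_raw, modeled = NULL) {
  stopifnot(is.matrix(gamma_raw), identical(dim(gamma_raw), dim(delta2_raw)))
  if (is.null(modeled)) modeled <- rep(TRUE, nrow(gamma_raw))
  keep <- modeled & apply(is.finite(gamma_raw) & is.finite(delta2_raw), 1, all)
  if (sum(keep) < 3L)
    stop("fit_eb_hyperparameters: need >= 3 features with finite raw ",
         "estimates; have ", sum(keep))
  g <- gamma_raw[keep, , drop = FALSE]
  d <- delta2_raw[keep, , drop = FALSE]
  mu <- colMeans(g)
  tau2 <- apply(g, 2, stats::var)
  vbar <- colMeans(d)
  s <- apply(d, 2, stats::var)
  if (any(s == 0))
    stop("fit_eb_hyperparameters: delta2_raw is constant across features ",
         "for scanner(s) ", paste(colnames(d)[s == 0], collapse = ", "),
         "; the inverse-gamma moments are undefined - rerun with ",
         "eb_enabled = FALSE")
  lambda <- (vbar^2 + 2 * s) / s
  theta <- (vbar^3 + vbar * s) / s
  structure(list(mu = mu, tau2 = tau2, lambda = lambda, theta = theta),
            class = "spc_eb_hyper")
}

#' Empirical-Bayes shrinkage of scanner effects
#'
#' Iterates the conditional posterior means of the standard ComBat model to
#' a fixed point, vectorized over features:
#' \deqn{\gamma^* = (n \tau^2 \bar z + \delta^{*2} \mu) / (n \tau^2 + \delta^{*2})}
#' \deqn{\delta^{*2} = (\theta + \tfrac12 \sum_i (Z_i - \gamma^*)^2) / (n/2 + \lambda - 1)}
#' with \eqn{\sum_i (Z_i - \gamma^*)^2 = (n-1) s^2 + n (\bar z - \gamma^*)^2},
#' until the largest absolute update falls below `tol` or `max_iter` is hit
#' (non-convergence is flagged and the last iterate returned).
#'
#' @param zbar per-feature standardized scanner means (`gamma_raw`).
#' @param s2 per-feature standardized sample variances (`delta2_raw`).
#' @param n per-feature observation counts (each >= 2).
#' @param mu,tau2,lambda,theta scalar hyperparameters for this scanner.
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return List `gamma_star`, `delta_star2`, `n_iter`, `converged`.
#' @export
eb_shrink <- function(zbar, s2, n, mu, tau2, lambda, theta,
                      tol = 1e-6, max_iter = 100L) {
  stopifnot(length(zbar) == length(s2), length(zbar) == length(n),
            all(n >= 2))
  g <- zbar
  d2 <- s2
  d2[d2 <= 0] <- theta / (lambda - 1)  # degenerate start: prior mean
  it <- 0L
  conv <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    g_new <- (n * tau2 * zbar + d2 * mu) / (n * tau2 + d2)
    ss <- (n - 1) * s2 + n * (zbar - g_new)^2
    d2_new <- (theta + 0.5 * ss) / (n / 2 + lambda - 1)
    change <- max(abs(g_new - g), abs(d2_new - d2))
    g <- g_new
    d2 <- d2_new
    if (change < tol) { conv <- TRUE; break }
  }
  list(gamma_star = g, delta_star2 = d2, n_iter = it, converged = conv)
}

#' Fit the per-subject superpixel ComBat model
#'
#' Composes [estimate_feature_stats()], [fit_eb_hyperparameters()] and
#' [eb_shrink()] per scanner. With `eb_enabled = FALSE` the raw estimates are
#' copied into the starred fields (no shrinkage); hyperparameters are still
#' reported when estimable. `delta_star` is floored at `delta_floor` (with a
#' flag) so the back-transform can never divide by a vanishing scale.
#'
#' @param set an `spc_matched_set`.
#' @param parc an `spc_parcellation` built from this subject's reference
#'   image.
#' @param eb_enabled apply empirical-Bayes shrinkage (default TRUE).
#' @param sigma_floor,min_size passed to [estimate_feature_stats()].
#' @param delta_floor lower bound on `delta_star` (default 1e-2).
#' @param tol,max_iter passed to [eb_shrink()].
#' @return An `spc_combat_fit`: `subject_id`, `source_hash`, `stats`,
#'   `gamma_raw`, `delta2_raw`, `gamma_star`, `delta_star`, `hyper`,
#'   `eb_enabled`, `delta_floored`, `convergence`.
#' @export
fit_subject <- function(set, parc, eb_enabled = TRUE, sigma_floor = 1e-3,
                        min_size = 27L, delta_floor = 1e-2,
                        tol = 1e-6, max_iter = 100L) {
  est <- estimate_feature_stats(set, parc, sigma_floor = sigma_floor,
                                min_size = min_size)
  scanners <- est$stats$scanners
  gamma_star <- est$gamma_raw
  delta_star2 <- est$delta2_raw
  hyper <- NULL
  convergence <- NULL
  if (eb_enabled) {
    hyper <- fit_eb_hyperparameters(est$gamma_raw, est$delta2_raw,
                                    est$stats$modeled)
    convergence <- list()
    for (j in scanners) {
      ok <- est$stats$modeled & is.finite(est$gamma_raw[, j])
      sh <- eb_shrink(est$gamma_raw[ok, j], est$delta2_raw[ok, j],
                      est$stats$n[ok, j],
                      hyper$mu[[j]], hyper$tau2[[j]],
                      hyper$lambda[[j]], hyper$theta[[j]],
                      tol = tol, max_iter = max_iter)
      gamma_star[ok, j] <- sh$gamma_star
      delta_star2[ok, j] <- sh$delta_star2
      convergence[[j]] <- list(n_iter = sh$n_iter, converged = sh$converged)
    }
  } else {
    hyper <- tryCatch(
      fit_eb_hyperparameters(est$gamma_raw, est$delta2_raw,
                             est$stats$modeled),
      error = function(e) NULL)
  }
  delta_star <- sqrt(pmax(delta_star2, 0))
  delta_floored <- is.finite(delta_star) & delta_star < delta_floor
  delta_star[delta_floored] <- delta_floor
  structure(
    list(subject_id = set$subject_id, source_hash = parc$source_hash,
         stats = est$stats, gamma_raw = est$gamma_raw,
         delta2_raw = est$delta2_raw, gamma_star = gamma_star,
         delta_star = delta_star, hyper = hyper, eb_enabled = eb_enabled,
         delta_floored = delta_floored, convergence = convergence),
    class = "spc_combat_fit")
}

#' Harmonization back-transform for one feature's voxels
#'
#' Applies `Y* = sigma_hat * ((Y - m_hat)/sigma_hat - gamma) / delta + m_hat`
#' elementwise; with `gamma = 0, delta = 1` this is the identity. `delta`
#' below `delta_floor` is floored (with a warning) rather than divided by.
#'
#' @param y numeric vector of intensities.
#' @param m_hat,sigma_hat feature location/scale (`sigma_hat > 0`).
#' @param gamma,delta scanner effect estimates for this feature.
#' @param delta_floor minimum usable `delta` (default 1e-2).
#' @return Harmonized numeric vector.
#' @export
harmonize_voxels <- function(y, m_hat, sigma_hat, gamma, delta,
                             delta_floor = 1e-2) {
  stopifnot(sigma_hat > 0)
  if (delta < delta_floor) {
    warning("harmonize_voxels: delta ", signif(delta, 4),
            " below floor; using ", delta_floor)
    delta <- delta_floor
  }
  z <- (y - m_hat) / sigma_hat
  sigma_hat * (z - gamma) / delta + m_hat
}

#' @export
print.spc_combat_fit <- function(x, ...) {
  cat(sprintf(
    "<spc_combat_fit subject '%s': %d features x %d scanners, EB %s>\n",
    x$subject_id, x$stats$n_features, length(x$stats$scanners),
    if (x$eb_enabled) "on" else "off"))
  invisible(x)
}

#' Serialize / load a subject fit
#'
#' The fit is written as a tabular TSV (one row per feature-scanner pair:
#' counts, pooled moments, raw and starred effects, flags) plus a JSON
#' header carrying the hyperparameters and settings.
#'
#' @param fit an `spc_combat_fit`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The TSV path, invisibly.
#' @export
write_combat_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "spc_combat_fit"))
  scanners <- fit$stats$scanners
  rows <- data.table::rbindlist(lapply(scanners, function(j)
    data.table::data.table(
      feature = seq_len(fit$stats$n_features), scanner = j,
      n = fit$stats$n[, j], m_hat = fit$stats$m_hat,
      sigma_hat = fit$stats$sigma_hat,
      gamma_raw = fit$gamma_raw[, j], delta2_raw = fit$delta2_raw[, j],
      gamma_star = fit$gamma_star[, j], delta_star = fit$delta_star[, j],
      sigma_floored = fit$stats$sigma_floored,
      delta_floored = fit$delta_floored[, j],
      modeled = fit$stats$modeled)))
  tsv <- paste0(prefix, ".tsv")
  data.table::fwrite(rows, tsv, sep = "\t")
  hdr <- list(subject_id = fit$subject_id, source_hash = fit$source_hash,
              eb_enabled = fit$eb_enabled, scanners = scanners,
              hyper = if (!is.null(fit$hyper)) lapply(unclass(fit$hyper),
                                                      as.list),
              convergence = fit$convergence)
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(tsv)
}
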