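# Helpers building miniature matched sets on explicit parcellations, so the
# estimators can be checked against closed forms.

strip_set <- function(values_by_scanner, subject = "s") {
  # one feature holding all voxels of a (n, 1, 1) strip
  n <- length(values_by_scanner[[1]])
  imgs <- lapply(values_by_scanner, function(v)
    volume(array(v, c(n, 1, 1))))
  matched_image_set(subject, imgs)
}

strip_parc <- function(n) {
  parcellation_from_labels(label_volume(array(1L, c(n, 1, 1))),
                           volume(array(0, c(n, 1, 1))))
}

test_that("feature stats match closed forms and flag degenerate variance", {
  # degenerate: zero residual variance is floored and flagged
  set <- strip_set(list(A = rep(10, 3), B = rep(14, 3)))
  est <- estimate_feature_stats(set, strip_parc(3), min_size = 3L)
  expect_equal(est$stats$m_hat, 12)
  expect_true(est$stats$sigma_floored)
  expect_equal(est$stats$sigma_hat, 1e-3)
  expect_equal(unname(est$stats$n[1, ]), c(3, 3))
  # scanner means recoverable from gamma_raw: ybar = m + gamma * sigma
  expect_equal(est$stats$m_hat + est$gamma_raw[1, ] * est$stats$sigma_hat,
               c(A = 10, B = 14))

  # identical images: no scanner effect
  withr::local_seed(3)
  y <- rnorm(40, 500, 20)
  est2 <- estimate_feature_stats(strip_set(list(A = y, B = y, C = y)),
                                 strip_parc(40), min_size = 27L)
  expect_equal(unname(est2$gamma_raw[1, ]), c(0, 0, 0))
  expect_equal(unname(est2$delta2_raw[1, ]), c(1, 1, 1))
})

test_that("raw location effects recover generating moments", {
  withr::local_seed(14)
  n <- 500
  est <- estimate_feature_stats(
    strip_set(list(A = rnorm(n, 490, 10), B = rnorm(n, 510, 10))),
    strip_parc(n), min_size = 27L)
  # oracle: closed-form moments; gamma = -/+ (10 / 10); 3 SE of the
  # mean-difference-based estimate is about 0.095
  expect_equal(unname(est$gamma_raw[1, ]), c(-1, 1), tolerance = 0.1)
  expect_equal(unname(est$delta2_raw[1, ]), c(1, 1), tolerance = 0.15)
})

test_that("raw effects satisfy the scanner-mean bookkeeping identity", {
  ph <- tiny_phantom()
  set <- ph$sets[[1]]
  parc <- slic3d(average_reference(set), head_mask_of(ph$truth$labels[[1]]),
                 n_superpixels = 50)
  est <- estimate_feature_stats(set, parc)
  for (j in est$stats$scanners) {
    ybar <- est$stats$m_hat + est$gamma_raw[, j] * est$stats$sigma_hat
    # recompute scanner means directly per feature
    direct <- vapply(seq_len(parc$n_features), function(f)
      mean(sample_feature(set$images[[j]], parc, f)), numeric(1))
    expect_equal(ybar, direct, tolerance = 1e-10)
  }
})

test_that("moment-matched hyperparameters invert the inverse-gamma moments", {
  # exact construction: delta2_raw with mean 1 and variance 0.5 gives
  # lambda = (1 + 2*0.5)/0.5 = 4, theta = (1 + 0.5)/0.5 = 3, and
  # InvGamma(4, 3) indeed has mean 3/(4-1) = 1, variance 9/(9*2) = 0.5
  n <- 200
  g <- cbind(A = vector_with_moments(n, 0.3, 0.2, seed = 5))
  d <- cbind(A = vector_with_moments(n, 1, sqrt(0.5), seed = 6))
  h <- fit_eb_hyperparameters(g, d)
  expect_equal(unname(h$mu), 0.3, tolerance = 1e-12)
  expect_equal(unname(h$tau2), 0.04, tolerance = 1e-12)
  expect_equal(unname(h$lambda), 4, tolerance = 1e-12)
  expect_equal(unname(h$theta), 3, tolerance = 1e-12)
  ig_mean <- h$theta / (h$lambda - 1)
  ig_var <- h$theta^2 / ((h$lambda - 1)^2 * (h$lambda - 2))
  expect_equal(unname(ig_mean), 1, tolerance = 1e-12)
  expect_equal(unname(ig_var), 0.5, tolerance = 1e-12)

  # sampling behaviour: large draws land within 3 SE of the truth
  withr::local_seed(8)
  gs <- cbind(A = rnorm(5000, 0.3, 0.2))
  ds <- cbind(A = 1 / rgamma(5000, 4, rate = 3))
  hs <- fit_eb_hyperparameters(gs, ds)
  expect_lt(abs(unname(hs$mu) - 0.3), 3 * 0.2 / sqrt(5000))
  expect_lt(abs(unname(hs$tau2) - 0.04), 3 * 0.04 * sqrt(2 / 4999))

  expect_error(fit_eb_hyperparameters(g, cbind(A = rep(1, n))),
               "eb_enabled")
  expect_error(fit_eb_hyperparameters(g[1:2, , drop = FALSE],
                                      d[1:2, , drop = FALSE]), ">= 3")
})

test_that("EB shrinkage solves its fixed-point equations", {
  withr::local_seed(21)
  zbar <- rnorm(50, 0.2, 0.5)
  s2 <- 1 / rgamma(50, 5, rate = 4)
  n <- rep(60, 50)
  mu <- 0.2; tau2 <- 0.25; lambda <- 5; theta <- 4
  sh <- eb_shrink(zbar, s2, n, mu, tau2, lambda, theta, tol = 1e-10)
  expect_true(sh$converged)
  # oracle: direct residual of the two equations on substitution
  g <- sh$gamma_star; d2 <- sh$delta_star2
  r1 <- g - (n * tau2 * zbar + d2 * mu) / (n * tau2 + d2)
  ss <- (n - 1) * s2 + n * (zbar - g)^2
  r2 <- d2 - (theta + 0.5 * ss) / (n / 2 + lambda - 1)
  expect_lt(max(abs(r1)), 1e-6)
  expect_lt(max(abs(r2)), 1e-6)
})

test_that("no-shrinkage limit and shrinkage inequality hold", {
  # tau2 -> infinity: gamma* -> zbar
  sh <- eb_shrink(c(-1, 0.3, 2), c(0.8, 1, 1.4), c(40, 40, 40),
                  mu = 0, tau2 = 1e12, lambda = 4, theta = 3)
  expect_equal(sh$gamma_star, c(-1, 0.3, 2), tolerance = 1e-6)
  # brute-force grid: |gamma* - mu| <= |zbar - mu|
  grid <- expand.grid(zbar = seq(-2, 2, by = 0.5), s2 = c(0.5, 1, 2),
                      n = c(30, 100), mu = c(-0.5, 0, 0.5),
                      tau2 = c(0.05, 0.5))
  sh2 <- with(grid, mapply(function(z, s, nn, m, t2)
    eb_shrink(z, s, nn, m, t2, lambda = 4, theta = 3)$gamma_star,
    zbar, s2, n, mu, tau2))
  expect_true(all(abs(sh2 - grid$mu) <= abs(grid$zbar - grid$mu) + 1e-12))
})

test_that("fit_subject composes the stages and honors the EB toggle", {
  ph <- tiny_phantom()
  set <- ph$sets[[2]]
  parc <- slic3d(average_reference(set), head_mask_of(ph$truth$labels[[2]]),
                 n_superpixels = 60)
  fit <- fit_subject(set, parc)
  fit0 <- fit_subject(set, parc, eb_enabled = FALSE)
  # toggling EB off reproduces the raw estimates exactly
  expect_identical(fit0$gamma_star, fit0$gamma_raw)
  expect_equal(fit0$delta_star^2, fit0$delta2_raw, tolerance = 1e-12)
  # shrinkage reduces the spread of location effects, per scanner
  for (j in fit$stats$scanners)
    expect_lte(var(fit$gamma_star[, j]), var(fit$gamma_raw[, j]))
  expect_true(all(fit$delta_star > 0))
  # convergence bookkeeping
  expect_true(all(vapply(fit$convergence, `[[`, TRUE, "converged")))
})

test_that("near-identical scanners yield near-null starred effects", {
  withr::local_seed(12)
  n <- 200
  base <- rnorm(n, 500, 25)
  set <- strip_set(list(A = base + rnorm(n, 0, 0.5),
                        B = base + rnorm(n, 0, 0.5),
                        C = base + rnorm(n, 0, 0.5)))
  # several features so hyperparameters are estimable
  lab <- array(rep(1:5, each = n / 5), c(n, 1, 1))
  parc <- parcellation_from_labels(label_volume(lab),
                                   volume(array(0, c(n, 1, 1))))
  fit <- fit_subject(set, parc)
  expect_lt(max(abs(fit$gamma_star)), 0.15)
  expect_lt(max(abs(fit$delta_star - 1)), 0.2)
})

test_that("identical scanners give null raw effects and EB degeneracy is caught", {
  withr::local_seed(13)
  y <- rnorm(90, 500, 20)
  set <- strip_set(list(A = y, B = y))
  lab <- array(rep(1:3, each = 30), c(90, 1, 1))
  parc <- parcellation_from_labels(label_volume(lab),
                                   volume(array(0, c(90, 1, 1))))
  fit0 <- fit_subject(set, parc, eb_enabled = FALSE)
  expect_lt(max(abs(fit0$gamma_raw)), 1e-12)
  expect_equal(unname(fit0$delta2_raw), matrix(1, 3, 2), tolerance = 1e-12)
  # a literally constant delta2_raw is a flagged degeneracy of the
  # inverse-gamma moment fit
  expect_error(
    fit_eb_hyperparameters(matrix(rnorm(6), 3), matrix(1, 3, 2)),
    "eb_enabled")
})

test_that("harmonize_voxels implements the printed back-transform", {
  # hand evaluation: m = 500, sigma = 50, gamma = 0.4, delta = 1.25,
  # Y = 600 -> Z = 2 -> Y* = 50 * (2 - 0.4) / 1.25 + 500 = 564
  expect_equal(harmonize_voxels(600, 500, 50, 0.4, 1.25), 564)
  # identity case
  y <- c(480, 500, 523)
  expect_identical(harmonize_voxels(y, 500, 50, 0, 1), y)
  # algebraic special case: Y = m -> Y* = m - sigma * gamma / delta
  expect_equal(harmonize_voxels(500, 500, 50, 0.4, 1.25),
               500 - 50 * 0.4 / 1.25)
  expect_warning(harmonize_voxels(600, 500, 50, 0, 1e-6), "floor")
})

test_that("self-harmonization closes to the null fit", {
  ph <- tiny_phantom()
  set <- ph$sets[[1]]
  parc <- slic3d(average_reference(set), head_mask_of(ph$truth$labels[[1]]),
                 n_superpixels = 60)
  fit0 <- fit_subject(set, parc, eb_enabled = FALSE)
  harm <- lapply(scanners_of(set), function(j)
    harmonize_image(set$images[[j]], j, fit = fit0, parc = parc,
                    mode = "self"))
  names(harm) <- scanners_of(set)
  refit <- fit_subject(matched_image_set("s", harm), parc,
                       eb_enabled = FALSE)
  expect_lt(max(abs(refit$gamma_raw)), 1e-6)
  expect_lt(max(abs(refit$delta2_raw - 1)), 1e-6)
})
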