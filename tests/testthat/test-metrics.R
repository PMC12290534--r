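two_tissue_image <- function(gm_vals, wm_vals) {
  n <- length(gm_vals) + length(wm_vals)
  stopifnot(n %% 4 == 0)
  shape <- c(n / 4, 2, 2)
  img <- volume(array(c(gm_vals, wm_vals), shape))
  gm <- label_volume(array(c(rep(1L, length(gm_vals)),
                             rep(0L, length(wm_vals))), shape))
  wm <- label_volume(array(c(rep(0L, length(gm_vals)),
                             rep(1L, length(wm_vals))), shape))
  list(img = img, gm = gm, wm = wm)
}

test_that("snr matches generating parameters and scaling identities", {
  withr::local_seed(2)
  n <- 1e5
  shape <- c(100, 100, 10)
  img <- volume(array(rnorm(n, 600, 30), shape))
  m <- full_mask(img)
  # oracle: generating parameters, 600/30 = 20 (3 SE ~ 0.14)
  expect_equal(snr(img, m), 20, tolerance = 0.01)
  # literal-variance switch
  expect_equal(snr(img, m, noise = "variance"),
               snr(img, m) / sd(img$data), tolerance = 1e-12)
  # scale invariance in SD mode (algebraic identity)
  img2 <- volume(2 * img$data)
  expect_equal(snr(img2, m), snr(img, m), tolerance = 1e-12)
  expect_error(snr(volume(array(5, c(3, 3, 3))),
                   full_mask(volume(array(5, c(3, 3, 3))))), "zero")
})

test_that("cnr and cjv match hand computations to 1e-9", {
  # exact sample moments by affine rescaling of a fixed draw
  tt3 <- two_tissue_image(vector_with_moments(12, 400, 20, seed = 31),
                          vector_with_moments(12, 600, 20, seed = 32))
  expect_equal(cnr(tt3$img, tt3$gm, tt3$wm), 200 / sqrt(800),
               tolerance = 1e-9)
  expect_equal(cjv(tt3$img, tt3$gm, tt3$wm), 0.2, tolerance = 1e-9)
  # identical distributions: CNR 0
  same <- two_tissue_image(rep(c(380, 400, 420), 4),
                           rep(c(380, 400, 420), 4))
  expect_equal(cnr(same$img, same$gm, same$wm), 0)
  expect_error(cjv(same$img, same$gm, same$wm), "equal")
  # noiseless two-level image: CJV 0
  flat <- two_tissue_image(rep(400, 8), rep(600, 8))
  expect_equal(cjv(flat$img, flat$gm, flat$wm), 0)
  # affine invariance of CNR
  aff <- volume(3 * tt3$img$data + 111)
  expect_equal(cnr(aff, tt3$gm, tt3$wm), cnr(tt3$img, tt3$gm, tt3$wm),
               tolerance = 1e-12)
})

test_that("bias-field modulation strictly increases cjv", {
  withr::local_seed(9)
  shape <- c(16, 16, 16)
  img <- array(rnorm(prod(shape), 400, 15), shape)
  img[, , 9:16] <- rnorm(prod(shape) / 2, 600, 15)
  gm <- label_volume(array(as.integer(slice.index(img, 3) <= 8), shape))
  wm <- label_volume(array(as.integer(slice.index(img, 3) > 8), shape))
  x <- seq(0.85, 1.15, length.out = shape[1])
  bias <- array(rep(x, times = shape[2] * shape[3]), shape)
  expect_gt(cjv(volume(img * bias), gm, wm), cjv(volume(img), gm, wm))
})

test_that("wm2max responds to hyperintense tails and scaling", {
  # exact case: WM median equals the global 95th percentile
  shape <- c(10, 10, 10)
  vals <- c(rep(500, 900), rep(600, 100))
  img <- volume(array(vals, shape))
  wm <- label_volume(array(c(rep(0L, 900), rep(1L, 100)), shape))
  expect_equal(wm2max(img, wm), 1)
  # growing hyperintense tail depresses the ratio
  withr::local_seed(4)
  base <- rnorm(1000, 600, 10)
  mk <- function(tail_frac) {
    v <- base
    v[seq_len(tail_frac * 1000)] <- 1000
    volume(array(v, shape))
  }
  w_all <- label_volume(array(1L, shape))
  v1 <- wm2max(mk(0.01), w_all)
  v3 <- wm2max(mk(0.03), w_all)
  v6 <- wm2max(mk(0.06), w_all)
  expect_lt(v1, 1)
  expect_true(v6 < v3 && v3 < v1)
  # ratio identity under global scaling
  expect_equal(wm2max(volume(5 * mk(0.01)$data), w_all), v1,
               tolerance = 1e-12)
  # wm-denominator switch pins the metric near 1
  expect_gt(wm2max(mk(0.01), w_all, denom = "wm"), 0.95)
})

test_that("ssim matches a brute-force plain-formula implementation", {
  withr::local_seed(10)
  a <- volume(array(runif(512, 0, 1000), c(8, 8, 8)))
  b <- volume(array(a$data + rnorm(512, 0, 60), c(8, 8, 8)))
  expect_equal(ssim(a, b), ssim_bruteforce(a, b), tolerance = 1e-6)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_error(ssim(a, volume(array(0, c(8, 8, 9)))), "mismatch")
  # scale invariance when data_range is matched to the rescaling
  a2 <- volume(2 * a$data)
  b2 <- volume(2 * b$data)
  expect_equal(ssim(a2, b2, data_range = 2000), ssim(a, b),
               tolerance = 1e-9)
})

test_that("tissue_effect_summary reproduces the textbook t statistic", {
  shape <- c(4, 4, 4)
  mk_maps <- function(g, d, subj)
    spcombat:::new_effect_maps(list(A = volume(array(g, shape))),
                               list(A = volume(array(d, shape))),
                               subj, "individual")
  masks <- list(GM = label_volume(array(1L, shape)))
  # subject means {0.1, 0.2, 0.3} vs 0: t = 0.2 / (0.1 / sqrt(3))
  maps <- list(mk_maps(0.1, 1, "s1"), mk_maps(0.2, 1, "s2"),
               mk_maps(0.3, 1, "s3"))
  tab <- tissue_effect_summary(maps, masks)
  expect_equal(tab$t_gamma, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tab$mean_gamma, 0.2)
  # delta all exactly 1 -> t = 0, p = 1; gamma all 0 likewise
  null_maps <- list(mk_maps(0, 1, "s1"), mk_maps(0, 1, "s2"))
  tab0 <- tissue_effect_summary(null_maps, masks)
  expect_equal(tab0$t_gamma, 0)
  expect_equal(tab0$p_gamma, 1)
  expect_equal(tab0$t_delta, 0)
  # single subject: means only
  tab1 <- tissue_effect_summary(maps[[1]], masks)
  expect_true(is.na(tab1$t_gamma))
  expect_equal(tab1$mean_gamma, 0.1)
})

test_that("cv_across_scanners uses the sample-SD convention", {
  tab <- data.frame(subject = "s1", scanner = c("A", "B", "C"),
                    region = "GM", volume = c(90, 100, 110))
  cv <- cv_across_scanners(tab)
  expect_equal(cv$per_subject$cv, 0.1)
  expect_equal(cv$per_region$mean_cv, 0.1)
  same <- data.frame(subject = "s1", scanner = c("A", "B"),
                     region = "GM", volume = c(100, 100))
  expect_equal(cv_across_scanners(same)$per_subject$cv, 0)
  expect_equal(cv_reduction(0.10, 0.06), 40)
  expect_error(cv_across_scanners(
    data.frame(subject = "s", scanner = "A", region = "GM", volume = 1)),
    ">= 2 scanners")
})

test_that("cohens_d matches its hand computation and is antisymmetric", {
  a <- vector_with_moments(9, 12, 2, seed = 1)
  b <- vector_with_moments(9, 10, 2, seed = 2)
  expect_equal(cohens_d(a, b), 1, tolerance = 1e-12)
  expect_equal(cohens_d(b, a), -cohens_d(a, b))
  expect_equal(cohens_d(a, a), 0)
  d <- cohens_d(a, b, bootstrap = 200, seed = 7)
  expect_true(is.finite(attr(d, "boot_sd")) && attr(d, "boot_sd") > 0)
  # bootstrap is seeded: identical reruns
  d2 <- cohens_d(a, b, bootstrap = 200, seed = 7)
  expect_identical(attr(d, "boot_sd"), attr(d2, "boot_sd"))
})
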