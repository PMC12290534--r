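fit_one <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- tiny_phantom()
      fits <- lapply(seq_along(ph$sets), function(k) {
        set <- ph$sets[[k]]
        parc <- slic3d(average_reference(set),
                       head_mask_of(ph$truth$labels[[k]]),
                       n_superpixels = 60)
        list(set = set, parc = parc, fit = fit_subject(set, parc))
      })
      cache <<- list(ph = ph, fits = fits)
    }
    cache
  }
})

test_that("rendered maps are exact per-feature lookups with neutral padding", {
  fx <- fit_one()
  f1 <- fx$fits[[1]]
  maps <- render_maps(f1$fit, f1$parc)
  lab <- f1$parc$labels$labels
  j <- scanners_of(f1$set)[1]
  inm <- lab > 0L
  # oracle: direct table lookup over all in-mask voxels
  expect_identical(maps$additive[[j]]$data[inm],
                   unname(f1$fit$gamma_star[lab[inm], j]))
  expect_identical(maps$multiplicative[[j]]$data[inm],
                   unname(f1$fit$delta_star[lab[inm], j]))
  # neutral outside the mask; delta strictly positive everywhere
  expect_true(all(maps$additive[[j]]$data[!inm] == 0))
  expect_true(all(maps$multiplicative[[j]]$data[!inm] == 1))
  expect_gt(min(maps$multiplicative[[j]]$data), 0)
  # fingerprint mismatch is refused
  other <- fx$fits[[2]]
  expect_error(render_maps(f1$fit, other$parc), "fingerprint")
})

test_that("constant fitted effects render constant maps", {
  fx <- fit_one()
  f1 <- fx$fits[[1]]
  fit <- f1$fit
  fit$gamma_star[] <- 0.2
  maps <- render_maps(fit, f1$parc)
  inm <- f1$parc$labels$labels > 0L
  expect_true(all(maps$additive[[1]]$data[inm] == 0.2))
})

test_that("group averaging is arithmetic for gamma, geometric for delta", {
  fx <- fit_one()
  maps <- lapply(fx$fits, function(f) render_maps(f$fit, f$parc))
  avg <- average_maps(maps)
  j <- names(maps[[1]]$additive)[1]
  expect_equal(avg$additive[[j]]$data,
               (maps[[1]]$additive[[j]]$data + maps[[2]]$additive[[j]]$data +
                  maps[[3]]$additive[[j]]$data) / 3, tolerance = 1e-12)
  # permutation invariance
  avg2 <- average_maps(maps[c(3, 1, 2)])
  expect_equal(avg2$additive[[j]]$data, avg$additive[[j]]$data,
               tolerance = 1e-12)
  # averaging copies of one map returns that map
  same <- average_maps(list(maps[[1]], maps[[1]], maps[[1]]))
  expect_equal(same$multiplicative[[j]]$data,
               maps[[1]]$multiplicative[[j]]$data, tolerance = 1e-12)
})

test_that("delta 0.5 and 2.0 average to 1.0 geometrically, 1.25 arithmetically", {
  shape <- c(3, 3, 3)
  mk <- function(delta, subj) {
    g <- volume(array(0, shape))
    d <- volume(array(delta, shape))
    spcombat:::new_effect_maps(list(A = g), list(A = d), subj, "individual")
  }
  geo <- average_maps(list(mk(0.5, "s1"), mk(2, "s2")))
  expect_equal(unique(as.vector(geo$multiplicative$A$data)), 1)
  ari <- average_maps(list(mk(0.5, "s1"), mk(2, "s2")),
                      delta_mean = "arithmetic")
  expect_equal(unique(as.vector(ari$multiplicative$A$data)), 1.25)
})

test_that("leave-one-out provenance never contains the held-out subject", {
  fx <- fit_one()
  maps <- lapply(fx$fits, function(f) render_maps(f$fit, f$parc))
  subjects <- vapply(maps, function(m) m$provenance, character(1))
  for (s in subjects) {
    loo <- average_maps(maps, exclude_subject = s)
    expect_false(s %in% loo$provenance)
    expect_identical(loo$mode, "group_loo")
    expect_length(loo$provenance, length(maps) - 1L)
  }
  expect_error(average_maps(maps[1:2], exclude_subject = subjects[1]),
               "after exclusion")
})

test_that("neutral maps leave the image exactly unchanged", {
  fx <- fit_one()
  f1 <- fx$fits[[1]]
  shape <- f1$set$images[[1]]$shape
  sp <- f1$set$images[[1]]$spacing
  tag <- f1$set$images[[1]]$space_tag
  neutral <- spcombat:::new_effect_maps(
    list(A = volume(array(0, shape), sp, tag)),
    list(A = volume(array(1, shape), sp, tag)), "none", "group")
  names(neutral$additive) <- names(neutral$multiplicative) <-
    scanners_of(f1$set)[1]
  j <- scanners_of(f1$set)[1]
  out <- harmonize_image(f1$set$images[[j]], j, maps = neutral,
                         fit = f1$fit, parc = f1$parc, mode = "map")
  expect_identical(out$data, f1$set$images[[j]]$data)
  expect_error(harmonize_image(f1$set$images[[j]], "nope", maps = neutral,
                               fit = f1$fit, parc = f1$parc, mode = "map"),
               "missing from maps")
})

test_that("map-mode harmonization with LOO phantom maps removes most of a programmed shift", {
  # one scanner shifted in WM; other subjects provide the group maps
  eff <- list(
    A = list(shift = c(CSF = 0, GM = 0, WM = 0.5),
             scale = c(CSF = 1, GM = 1, WM = 1)),
    B = list(shift = c(CSF = 0, GM = 0, WM = 0),
             scale = c(CSF = 1, GM = 1, WM = 1)),
    C = list(shift = c(CSF = 0, GM = 0, WM = 0),
             scale = c(CSF = 1, GM = 1, WM = 1)))
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), n_subjects = 4,
                                  scanner_effects = eff, noise_sd = 5,
                                  seed = 31))
  objs <- lapply(seq_along(ph$sets), function(k) {
    set <- ph$sets[[k]]
    parc <- slic3d(average_reference(set),
                   head_mask_of(ph$truth$labels[[k]]), n_superpixels = 80)
    fit <- fit_subject(set, parc, eb_enabled = FALSE)
    list(set = set, parc = parc, fit = fit,
         maps = render_maps(fit, parc))
  })
  maps <- lapply(objs, `[[`, "maps")
  k <- 1L
  loo <- average_maps(maps, exclude_subject = ph$sets[[k]]$subject_id)
  harm <- lapply(scanners_of(ph$sets[[k]]), function(j)
    harmonize_image(ph$sets[[k]]$images[[j]], j, maps = loo,
                    fit = objs[[k]]$fit, parc = objs[[k]]$parc,
                    mode = "map"))
  names(harm) <- scanners_of(ph$sets[[k]])
  refit <- fit_subject(matched_image_set("h", harm), objs[[k]]$parc,
                       eb_enabled = FALSE)
  res_maps <- render_maps(refit, objs[[k]]$parc)
  wm <- tissue_masks_of(ph$truth$labels[[k]])$WM
  inm <- wm$labels != 0L
  raw_wm <- mean(objs[[k]]$maps$additive$A$data[inm])
  res_wm <- mean(res_maps$additive$A$data[inm])
  expect_gt(abs(raw_wm), 0.3)   # the programmed effect was there
  expect_lt(abs(res_wm), 0.1)   # and the LOO maps removed it
})

test_that("residual re-estimation on identical images is null", {
  withr::local_seed(44)
  shape <- c(12, 12, 12)
  base <- array(rnorm(prod(shape), 500, 40), shape)
  imgs <- list(A = volume(base), B = volume(base))
  set <- matched_image_set("s", imgs)
  lab <- array(rep(1:4, each = prod(shape) / 4), shape)
  parc <- parcellation_from_labels(label_volume(lab),
                                   average_reference(set))
  res <- reestimate_residuals(list(set), list(parc))
  m <- res$subject_maps[[1]]
  inm <- parc$labels$labels > 0L
  expect_lt(max(abs(m$additive$A$data[inm])), 1e-10)
  expect_lt(max(abs(m$multiplicative$A$data[inm] - 1)), 1e-10)
})

test_that("effect maps write as NIfTI pairs and round-trip", {
  fx <- fit_one()
  maps <- render_maps(fx$fits[[1]]$fit, fx$fits[[1]]$parc)
  dir <- withr::local_tempdir()
  paths <- write_effect_maps(maps, dir)
  expect_true(all(file.exists(file.path(
    dir, c("gamma_GE.nii.gz", "delta_GE.nii.gz")))))
  g <- read_volume(file.path(dir, "gamma_GE.nii.gz"))
  expect_equal(g$data, maps$additive$GE$data, tolerance = 1e-5)
})
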