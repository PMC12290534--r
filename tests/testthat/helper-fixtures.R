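# Shared fixtures and independent oracles. All fixtures are generated in
# code; nothing is loaded from disk.

rand_volume <- function(shape = c(6, 5, 4), spacing = c(1, 1, 1),
                        tag = "test-grid", seed = 42) {
  withr::with_seed(seed,
    volume(array(rnorm(prod(shape), 500, 60), shape), spacing = spacing,
           space_tag = tag))
}

full_mask <- function(vol) {
  label_volume(array(1L, dim = vol$shape), spacing = vol$spacing,
               space_tag = vol$space_tag)
}

# small phantom cohort shared by several test files (cached per session)
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_phantom(phantom_spec(shape = c(40, 40, 40),
                                          n_subjects = 3, seed = 11))
    cache
  }
})

head_mask_of <- function(lab)
  label_volume(array(as.integer(lab$labels > 0L), dim = lab$shape),
               spacing = lab$spacing, space_tag = lab$space_tag)

tissue_masks_of <- function(lab) spcombat:::tissue_masks_from_labels(lab)

# --- independent oracles ---------------------------------------------------

# plain-formula SSIM: per-voxel Gaussian-weighted local moments evaluated by
# explicit window loops (no separable shortcuts), mirror boundary
ssim_bruteforce <- function(a, b, window = 7L, sigma = 1.5,
                            data_range = 1000) {
  half <- window %/% 2L
  k1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  w3 <- outer(outer(k1, k1), k1)  # separable Gaussian as an explicit 3D stencil
  mir <- function(i, n) {
    p <- 2 * n - 2
    i <- abs(i) %% p
    ifelse(i < n, i, p - i) + 1L
  }
  da <- a$data
  db <- b$data
  dm <- dim(da)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  out <- array(NA_real_, dm)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    xs <- mir((x - 1) + (-half:half), dm[1])
    ys <- mir((y - 1) + (-half:half), dm[2])
    zs <- mir((z - 1) + (-half:half), dm[3])
    wa <- da[xs, ys, zs]
    wb <- db[xs, ys, zs]
    mu_a <- sum(w3 * wa); mu_b <- sum(w3 * wb)
    va <- sum(w3 * wa^2) - mu_a^2
    vb <- sum(w3 * wb^2) - mu_b^2
    vab <- sum(w3 * wa * wb) - mu_a * mu_b
    out[x, y, z] <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  }
  mean(out)
}

# exact sample mean/SD construction: affinely rescale a fixed draw
vector_with_moments <- function(n, mean, sd, seed = 1) {
  x <- withr::with_seed(seed, rnorm(n))
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}
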