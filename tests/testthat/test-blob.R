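# blob_features: LoG scale space, automatic scale selection, detection,
# per-region descriptors

test_that("scale_ladder enforces its invariants", {
  s <- scale_ladder()
  expect_length(s, 10L)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) > 0))
  expect_true(all(s[-1] / s[-10] <= 2))
  expect_error(scale_ladder(n_scales = 2), "at least 3")
})

test_that("LoG responses vanish on constants and scale linearly", {
  g <- vol_grid(c(24, 24, 24))
  lad <- scale_ladder(n_scales = 6)
  const <- pet_volume(array(4, dim = c(24, 24, 24)), g)
  expect_lt(max(abs(log_scale_space(const, lad))), 1e-8)
  set.seed(5)
  x <- array(rnorm(24^3), dim = c(24, 24, 24))
  s1 <- log_scale_space(pet_volume(x, g), lad)
  s3 <- log_scale_space(pet_volume(3 * x, g), lad)
  expect_lt(max(abs(s3 - 3 * s1)), 1e-8)
  expect_error(log_scale_space(const, scale_ladder(sigma0 = 4)),
               "exceeds a third")
})

test_that("automatic scale selection finds sigma0 * sqrt(2/3)", {
  # closed form: |response| at the centre of a Gaussian bump of width s0
  # is proportional to sigma^2 (s0^2 + sigma^2)^(-5/2), maximized at
  # sigma = s0 * sqrt(2/3); the detector must pick the nearest ladder
  # scale (within one ladder step)
  g <- vol_grid(c(48, 48, 48))
  lad <- scale_ladder()
  for (s0 in c(2, 4)) {
    bump <- add_bump(array(0, dim = c(48, 48, 48)), c(24, 24, 24), s0, 10)
    st <- log_scale_space(pet_volume(bump, g), lad)
    best <- lad[which.max(abs(st[24, 24, 24, ]))]
    target <- s0 * sqrt(2 / 3)
    nearest <- lad[which.min(abs(lad - target))]
    expect_equal(best, nearest)
    # scale-normalized response at a bright bump is negative
    expect_lt(st[24, 24, 24, which.max(abs(st[24, 24, 24, ]))], 0)
  }
  # scale covariance: doubling the bump width moves the detected scale
  # by a factor ~2 (within one ladder step either side)
  b2 <- add_bump(array(0, dim = c(48, 48, 48)), c(24, 24, 24), 2, 10)
  b4 <- add_bump(array(0, dim = c(48, 48, 48)), c(24, 24, 24), 4, 10)
  d2 <- lad[which.max(abs(log_scale_space(pet_volume(b2, g), lad)[24, 24, 24, ]))]
  d4 <- lad[which.max(abs(log_scale_space(pet_volume(b4, g), lad)[24, 24, 24, ]))]
  ratio <- d4 / d2
  expect_gt(ratio, 2 / 2^(1 / 3) - 1e-9)
  expect_lt(ratio, 2 * 2^(1 / 3) + 1e-9)
})

test_that("detect_blobs recovers planted bumps and nothing on zero input", {
  lab <- array(0L, dim = c(40, 40, 40))
  lab[5:36, 5:36, 5:36] <- 1L
  atlas <- label_volume(lab, vol_grid(c(40, 40, 40)))
  msk <- region_mask(atlas, 1L)
  lad <- scale_ladder(n_scales = 8)

  zero <- pet_volume(array(0, dim = c(40, 40, 40)), vol_grid(c(40, 40, 40)))
  expect_equal(nrow(detect_blobs(log_scale_space(zero, lad), msk)), 0L)

  one <- add_bump(array(0, dim = c(40, 40, 40)), c(20, 20, 20), 2.5, 10)
  st <- log_scale_space(pet_volume(one, vol_grid(c(40, 40, 40))), lad)
  b1 <- detect_blobs(st, msk)
  b1b <- b1[b1$polarity == "bright", ]
  expect_equal(nrow(b1b), 1L)
  expect_lte(max(abs(c(b1b$x, b1b$y, b1b$z) - 20)), 1)

  two <- add_bump(one, c(20, 20, 20) + c(16, 0, 0), 2.5, 10)
  st2 <- log_scale_space(pet_volume(two, vol_grid(c(40, 40, 40))), lad)
  b2 <- detect_blobs(st2, msk)
  expect_equal(nrow(b2[b2$polarity == "bright", ]), 2L)
  # sorted by |response| descending
  expect_true(all(diff(abs(b2$response)) <= 1e-12))
})

test_that("detection is invariant to intensity shifts", {
  lab <- array(0L, dim = c(32, 32, 32))
  lab[3:30, 3:30, 3:30] <- 1L
  atlas <- label_volume(lab, vol_grid(c(32, 32, 32)))
  msk <- region_mask(atlas, 1L)
  lad <- scale_ladder(n_scales = 7)
  set.seed(9)
  x <- add_bump(array(rnorm(32^3, 0, 0.5), dim = c(32, 32, 32)),
                c(16, 16, 16), 3, 10)
  g <- vol_grid(c(32, 32, 32))
  b0 <- detect_blobs(log_scale_space(pet_volume(x, g), lad), msk)
  b1 <- detect_blobs(log_scale_space(pet_volume(x + 100, g), lad), msk)
  expect_equal(b0[, c("x", "y", "z", "scale_index")],
               b1[, c("x", "y", "z", "scale_index")])
  expect_equal(b0$response, b1$response, tolerance = 1e-8)
})

test_that("per-region features are complete, deterministic and sane", {
  sim <- small_sim()
  const <- pet_volume(array(2.5, dim = sim$atlas$grid$shape),
                      sim$atlas$grid)
  lad <- small_ladder()
  ft <- extract_region_features(const, sim$atlas, sim$registry, lad)
  expect_equal(dim(ft), c(116L, 8L))
  expect_true(all(ft[, "blob_count"] == 0))
  expect_true(all(ft[, "region_mean_uptake"] == 2.5))
  expect_true(all(is.finite(ft)))

  v <- cohort_volume(sim$cohort, 8)  # an MCI subject
  f1 <- extract_region_features(v, sim$atlas, sim$registry, lad)
  f2 <- extract_region_features(v, sim$atlas, sim$registry, lad)
  expect_identical(f1, f2)
  expect_identical(rownames(f1), as.character(1:116))
})

test_that("affected regions carry more blob signal in MCI than paired NC", {
  sim <- small_sim()
  prof <- small_profile()
  lad <- small_ladder()
  rid <- planted_region_ids(sim$registry)
  counts <- sapply(1:5, function(s) {
    mci <- simulate_subject(sim$atlas, sim$registry, prof, "MCI",
                            seed = 400L + s)
    nc <- simulate_subject(sim$atlas, sim$registry, prof, "NC",
                           seed = 400L + s)
    fm <- extract_region_features(mci, sim$atlas, sim$registry, lad)
    fn <- extract_region_features(nc, sim$atlas, sim$registry, lad)
    c(mci = mean(fm[as.character(rid), "max_abs_response"]),
      nc = mean(fn[as.character(rid), "max_abs_response"]))
  })
  expect_gt(mean(counts["mci", ]), mean(counts["nc", ]))
})
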