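# synthetic_phantom: registry composition, atlas partition, seeded
# cohort generation and the planted group effect

test_that("registry has 116 regions with the standard composition", {
  reg <- aal_region_registry()
  expect_equal(nrow(reg), 116L)
  expect_identical(reg$region_id, 1:116)
  expect_equal(as.vector(table(reg$compartment)[
    c("cerebral-L", "cerebral-R", "cerebellar-L", "cerebellar-R",
      "vermis")]), c(45L, 45L, 9L, 9L, 8L))
  expect_true(all(simulation_profile()$affected_regions %in% reg$name))
})

test_that("phantom atlas partitions the brain mask into 116 parcels", {
  sim <- small_sim()
  labs <- sim$atlas$labels
  inside <- labs > 0L
  sizes <- table(labs[inside])
  expect_equal(length(sizes), 116L)
  expect_identical(sort(as.integer(names(sizes))), 1:116)
  # every brain voxel carries exactly one label; outside is 0
  expect_identical(sum(sizes), sum(inside))
  # region_mask union = labeled voxels, pairwise disjoint
  all_idx <- unlist(lapply(1:116, function(r)
    region_mask(sim$atlas, r)$voxel_indices))
  expect_identical(sort(all_idx), which(inside))
  expect_false(anyDuplicated(all_idx) > 0)
})

test_that("atlas construction is deterministic and errors on tiny grids", {
  a1 <- build_phantom_atlas(c(32, 32, 32))
  a2 <- build_phantom_atlas(c(32, 32, 32))
  expect_identical(a1$atlas$labels, a2$atlas$labels)
  expect_error(build_phantom_atlas(c(16, 32, 32)), ">= 32")
  expect_error(build_phantom_atlas(c(32, 32, 32), n_regions = 5000L),
               "cannot host")
})

test_that("degenerate profile (no noise, no deposits) gives identical groups", {
  sim <- small_sim()
  prof <- small_profile(noise_sd = 0, blob_amplitude = 0,
                        bias_amplitude = 0)
  nc <- simulate_subject(sim$atlas, sim$registry, prof, "NC", seed = 1L)
  mci <- simulate_subject(sim$atlas, sim$registry, prof, "MCI", seed = 1L)
  expect_identical(nc$values, mci$values)
  expect_true(all(nc$values[sim$atlas$labels == 0L] == 0))
  expect_true(all(nc$values[sim$atlas$labels > 0L] ==
                    prof$background_level))
})

test_that("MCI deposits raise mean uptake in affected regions only there", {
  sim <- small_sim()
  prof <- small_profile()
  nc <- simulate_subject(sim$atlas, sim$registry, prof, "NC", seed = 5L)
  mci <- simulate_subject(sim$atlas, sim$registry, prof, "MCI", seed = 5L)
  rid <- match("Cingulum_Post_L", sim$registry$name)
  msk <- region_mask(sim$atlas, rid)
  expect_gt(region_mean_uptake(mci, msk), region_mean_uptake(nc, msk))
  # deposits are confined to affected regions: everywhere else identical
  affected <- match(prof$affected_regions, sim$registry$name)
  other <- !(sim$atlas$labels %in% affected)
  expect_identical(mci$values[other], nc$values[other])
  # outside the brain mask both are exactly zero
  expect_true(all(mci$values[sim$atlas$labels == 0L] == 0))
})

test_that("cohorts are seed-deterministic and sized by the profile", {
  prof <- simulation_profile(n_nc = 1L, n_mci = 0L,
                             grid_shape = c(32L, 32L, 32L), seed = 3L)
  one <- simulate_cohort(prof)
  expect_length(one$cohort, 1L)
  expect_equal(as.character(one$cohort$group), "NC")

  p42a <- small_profile(n_nc = 2L, n_mci = 2L)
  p42b <- small_profile(n_nc = 2L, n_mci = 2L)
  p43 <- small_profile(n_nc = 2L, n_mci = 2L, seed = 43L)
  va <- cohort_volume(simulate_cohort(p42a)$cohort, 4)
  vb <- cohort_volume(simulate_cohort(p42b)$cohort, 4)
  vc <- cohort_volume(simulate_cohort(p43)$cohort, 4)
  expect_identical(va$values, vb$values)
  expect_false(identical(va$values, vc$values))
})

test_that("group mean difference grows monotonically with amplitude", {
  sim <- small_sim()
  rid <- match("Vermis_8", sim$registry$name)
  msk <- region_mask(sim$atlas, rid)
  diffs <- sapply(c(0, 2, 4), function(fac) {
    mean(sapply(1:10, function(s) {
      prof <- small_profile(amplitude_factor = fac)
      mci <- simulate_subject(sim$atlas, sim$registry, prof, "MCI",
                              seed = 200L + s)
      nc <- simulate_subject(sim$atlas, sim$registry, prof, "NC",
                             seed = 200L + s)
      region_mean_uptake(mci, msk) - region_mean_uptake(nc, msk)
    }))
  })
  expect_true(all(diff(diffs) > 0))
  expect_lt(abs(diffs[1]), 1e-9)  # same seed, amplitude 0: exact pairing
})

test_that("placement fails gracefully when a region cannot host deposits", {
  sim <- small_sim()
  prof <- small_profile(blobs_per_region = 10000L)
  expect_error(
    simulate_subject(sim$atlas, sim$registry, prof, "MCI", seed = 1L),
    "cannot place")
})
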