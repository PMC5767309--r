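# volumes_io: grid model, NIfTI round trips, manifest handling

test_that("vol_grid validates shape, voxel size and affine", {
  expect_error(vol_grid(c(8, 8)), "3 positive integers")
  expect_error(vol_grid(c(8, 8, 8), voxel_size = c(1, -1, 1)),
               "positive reals")
  expect_error(vol_grid(c(8, 8, 8), affine = matrix(0, 4, 4)),
               "invertible")
  g <- vol_grid(c(16, 16, 8), voxel_size = c(2, 2, 3))
  expect_equal(g$voxel_size, c(2, 2, 3))
  # voxel size is recovered from the affine's column norms
  g2 <- vol_grid(c(16, 16, 8), affine = g$affine)
  expect_equal(g2$voxel_size, c(2, 2, 3), tolerance = 1e-12)
})

test_that("grid congruence is exact on shape and tolerant on affine", {
  g <- vol_grid(c(16, 16, 16), voxel_size = c(2, 2, 2))
  expect_true(check_grid_congruent(g, g))
  shifted <- g$affine
  shifted[1, 4] <- shifted[1, 4] + 2
  expect_false(check_grid_congruent(
    g, vol_grid(c(16, 16, 16), affine = shifted), tol = 1e-3))
  expect_false(check_grid_congruent(g, vol_grid(c(16, 16, 8))))
})

test_that("NIfTI write/read round-trips shape, affine and values", {
  g <- vol_grid(c(12, 10, 8), voxel_size = c(1.5, 2, 2.5))
  set.seed(11)
  v <- pet_volume(array(rnorm(12 * 10 * 8, 100, 10), dim = c(12, 10, 8)), g)
  for (ext in c("nii", "nii.gz")) {
    p <- file.path(withr::local_tempdir(), paste0("x.", ext))
    write_volume(v, p)
    r <- read_volume(p)
    expect_identical(r$grid$shape, g$shape)
    expect_lt(max(abs(r$grid$affine - g$affine)), 1e-6)
    expect_lt(max(abs(r$values - v$values)), 1e-3)  # float32 storage
  }
})

test_that("gzip path carries gzip magic bytes, plain path does not", {
  g <- vol_grid(c(8, 8, 8))
  v <- pet_volume(array(0, dim = c(8, 8, 8)), g)
  d <- withr::local_tempdir()
  write_volume(v, file.path(d, "x.nii.gz"))
  write_volume(v, file.path(d, "x.nii"))
  gz <- readBin(file.path(d, "x.nii.gz"), "raw", 2)
  expect_identical(gz, as.raw(c(0x1f, 0x8b)))
  plain <- readBin(file.path(d, "x.nii"), "raw", 4)
  expect_identical(readBin(plain, "integer", 1, 4), 348L)
})

test_that("label volumes round-trip through NIfTI as integers", {
  sim <- small_sim()
  p <- file.path(withr::local_tempdir(), "atlas.nii.gz")
  write_volume(sim$atlas, p)
  back <- read_atlas(p)
  expect_identical(back$labels, sim$atlas$labels)
  expect_lt(max(abs(back$grid$affine - sim$atlas$grid$affine)), 1e-6)
})

test_that("read_volume rejects 4D files and non-finite voxels", {
  d <- withr::local_tempdir()
  g <- vol_grid(c(8, 8, 8))
  p <- file.path(d, "x.nii")
  write_volume(pet_volume(array(1, dim = c(8, 8, 8)), g), p)
  # patch the header into a 4D image with 2 frames
  con <- file(p, "r+b")
  seek(con, 40, rw = "write")
  writeBin(as.integer(c(4L, 8L, 8L, 8L, 2L)), con, size = 2L,
           endian = "little")
  close(con)
  expect_error(read_volume(p), "expected a 3D volume")

  p2 <- file.path(d, "nan.nii")
  write_volume(pet_volume(array(1, dim = c(8, 8, 8)), g), p2)
  con <- file(p2, "r+b")
  seek(con, 352, rw = "write")
  writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_volume(p2), "3 non-finite voxel")

  expect_error(read_volume(file.path(d, "nope.nii")), "not found")
})

test_that("manifests round-trip and normalize group case", {
  d <- withr::local_tempdir()
  writeLines(c("subject_id\tgroup\tvolume_path",
               "s1\tnc\ta.nii", "s2\tMci\tb.nii", "s3\tNC\tc.nii"),
             file.path(d, "m.tsv"))
  co <- read_manifest(file.path(d, "m.tsv"))
  expect_length(co, 3L)
  expect_equal(as.character(co$group), c("NC", "MCI", "NC"))

  p2 <- file.path(d, "m2.tsv")
  write_manifest(co, p2)
  back <- read_manifest(p2)
  expect_identical(back$subject_id, co$subject_id)
  expect_identical(back$group, co$group)

  writeLines(c("subject_id\tgroup\tvolume_path",
               "s1\tNC\ta.nii", "s1\tMCI\tb.nii"), file.path(d, "dup.tsv"))
  expect_error(read_manifest(file.path(d, "dup.tsv")), "duplicate")
  writeLines(c("subject_id\tgroup\tvolume_path", "s1\tAD\ta.nii"),
             file.path(d, "bad.tsv"))
  expect_error(read_manifest(file.path(d, "bad.tsv")), "unknown group")
})

test_that("a written cohort reads back with identical grouping", {
  d <- withr::local_tempdir()
  prof <- simulation_profile(n_nc = 2L, n_mci = 3L,
                             grid_shape = c(32L, 32L, 32L), seed = 7L)
  simulate_cohort(prof, dir = d)
  co <- read_manifest(file.path(d, "manifest.tsv"))
  expect_length(co, 5L)
  expect_equal(sum(co$group == "NC"), 2L)
  v <- cohort_volume(co, 1)
  expect_identical(v$grid$shape, c(32L, 32L, 32L))
})
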