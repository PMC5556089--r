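test_that("mm/voxel conversions follow the affine with half-away rounding", {
  g <- volume_grid(c(5, 5, 5), affine = diag(4))     # identity affine
  expect_equal(mm_to_voxel(g, c(0, 0, 0)), c(1L, 1L, 1L))  # 0-based origin
  # 2-mm isotropic with an origin shift: hand-computable index
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-8, -8, -8)
  g2 <- volume_grid(c(9, 9, 9), affine = aff)
  expect_equal(mm_to_voxel(g2, c(0, 0, 0)), c(5L, 5L, 5L))
  # fractional indices (5.5, 2.5, 4.5) all round away from zero
  expect_equal(mm_to_voxel(g2, c(3, -3, 1)), c(7L, 4L, 6L))
  # voxel -> mm -> voxel round trip is the identity
  for (v in list(c(1, 1, 1), c(3, 7, 2), c(9, 9, 9))) {
    expect_equal(mm_to_voxel(g2, voxel_to_mm(g2, v)), as.integer(v))
  }
  expect_error(mm_to_voxel(g2, c(100, 0, 0)), "outside")
})

test_that("sphere membership matches brute-force enumeration", {
  g <- volume_grid(c(11, 11, 11), voxel_size_mm = 2)
  sph <- make_sphere(g, c(0, 0, 0), 10)
  # oracle: exhaustive distance check over all voxels
  cnt <- 0L
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    mm <- voxel_to_mm(g, c(i, j, k))
    if (sqrt(sum(mm^2)) <= 10) cnt <- cnt + 1L
  }
  expect_equal(nrow(sph), cnt)
  expect_true(all(sph$dist_mm <= 10))
  # radius below half the voxel size: exactly the centre voxel
  expect_equal(nrow(make_sphere(g, c(0, 0, 0), 0.9)), 1)
  # translation equivariance: shifting volume and centre together
  g_shift <- volume_grid(c(11, 11, 11), voxel_size_mm = 2,
                         origin_mm = c(14, -6, 2))
  sph2 <- make_sphere(g_shift, c(14, -6, 2), 10)
  expect_equal(nrow(sph2), nrow(sph))
  expect_equal(sph2$i, sph$i)
  expect_error(make_sphere(g, c(200, 0, 0), 5), "no voxel")
})

test_that("NIfTI volumes round-trip bit-identically", {
  tmp <- withr::local_tempfile(fileext = ".nii")
  g <- volume_grid(c(6, 5, 4), voxel_size_mm = 3, origin_mm = c(1, -2, 7))
  withr::with_seed(1, {
    vol_i <- array(sample(-500:500, 120, replace = TRUE), c(6, 5, 4))
    write_nifti(vol_i, tmp, grid = g, datatype = "int16")
    back <- read_nifti(tmp)
    expect_equal(as.vector(back), as.vector(vol_i))
    expect_equal(attr(back, "grid")$affine, g$affine, tolerance = 1e-6)

    vol_f <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
    write_nifti(vol_f, tmp, grid = g, datatype = "float32", tr_s = 2.5)
    back_f <- read_nifti(tmp)
    expect_equal(as.vector(back_f), as.vector(vol_f), tolerance = 1e-6)
    expect_equal(attr(back_f, "tr_s"), 2.5, tolerance = 1e-7)

    write_nifti(vol_f, tmp, grid = g, datatype = "float64")
    expect_identical(as.vector(read_nifti(tmp)), as.vector(vol_f))
  })
  expect_error({
    writeBin(as.raw(1:100), tmp)
    read_nifti(tmp)
  }, "malformed")
})

test_that("our NIfTI writer is readable by an independent implementation", {
  # nibabel (Python) as external oracle for the header layout
  py <- Sys.which("python")
  has_nibabel <- nzchar(py) &&
    system2(py, c("-c", "'import nibabel'"), stdout = FALSE, stderr = FALSE) == 0
  skip_if(!has_nibabel, "python/nibabel unavailable")
  tmp <- withr::local_tempfile(fileext = ".nii")
  g <- volume_grid(c(4, 4, 4), voxel_size_mm = 2, origin_mm = c(1, 2, 3))
  vol <- array(seq_len(64), c(4, 4, 4))
  write_nifti(vol, tmp, grid = g, datatype = "float32")
  out <- system2(py, c("-c", shQuote(paste0(
    "import nibabel as nib; img = nib.load('", tmp, "'); ",
    "print(img.shape); print(img.get_fdata().ravel(order='F')[:4]); ",
    "print(img.affine[0,0], img.affine[0,3])"))), stdout = TRUE)
  expect_match(out[1], "\\(4, 4, 4\\)")
  expect_match(out[2], "1\\.\\s*2\\.\\s*3\\.\\s*4\\.")
  expect_match(out[3], "^2\\.0 -2\\.0")
})

test_that("events tables round-trip with order and types preserved", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  d <- generate_design(seed = 5)
  d$rating <- round(stats::runif(nrow(d), 1, 9), 3)
  write_events(d, tmp)
  back <- read_events(tmp)
  expect_equal(back$onset_s, d$onset_s)
  expect_equal(back$price, d$price)
  expect_equal(back$wine, d$wine)
  expect_equal(back$rating, d$rating)
  expect_equal(back$trial, d$trial)
})

test_that("motion traces and manifests round-trip", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  m <- matrix(rnorm(60), 10, 6)
  write_motion(m, tmp)
  expect_equal(unname(read_motion(tmp)), m, tolerance = 1e-12)
  tmp2 <- withr::local_tempfile(fileext = ".json")
  x <- list(seed = 3L, thresholds = list(p = 0.001, k = 5),
            rois = list(vmPFC = c(-2, 48, -16)))
  write_manifest(x, tmp2)
  back <- read_manifest(tmp2)
  expect_equal(back$seed, 3)
  expect_equal(back$thresholds$p, 0.001)
  expect_equal(unlist(back$rois$vmPFC), c(-2, 48, -16))
})
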