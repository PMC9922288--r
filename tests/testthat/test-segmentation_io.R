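# rasterize an ellipsoid (semi-axes abc, mm) into an image volume
rasterize_ellipsoid <- function(abc, spacing, pad = 3, inside = 400,
                                outside = -50) {
  g <- lapply(1:3, function(d) seq(-abc[d] - pad, abc[d] + pad, by = spacing))
  arr <- array(outside, vapply(g, length, 0L))
  for (k in seq_along(g[[3]])) {
    r2 <- outer((g[[1]] / abc[1])^2, (g[[2]] / abc[2])^2, "+") +
      (g[[3]][k] / abc[3])^2
    arr[, , k][r2 <= 1] <- inside
  }
  image_volume(arr, spacing = rep(spacing, 3),
               origin = vapply(g, min, 0))
}

test_that("threshold segmentation: mask, component filter, errors", {
  uni <- image_volume(array(300, c(4, 4, 4)))
  expect_true(all(threshold_blood_pool(uni)))

  img <- rasterize_ellipsoid(c(10, 8, 6), 0.5)
  mask <- threshold_blood_pool(img)
  v_mask <- sum(mask) * 0.5^3
  v_true <- 4 / 3 * pi * prod(c(10, 8, 6))
  expect_lt(abs(v_mask - v_true) / v_true, 0.02)

  # two blobs: only the larger survives the component filter
  a <- array(-100, c(20, 20, 20))
  a[2:4, 2:4, 2:4] <- 400
  a[8:18, 8:18, 8:18] <- 400
  two <- image_volume(a)
  expect_equal(sum(threshold_blood_pool(two)), 11^3)
  expect_equal(sum(threshold_blood_pool(two, largest_component = FALSE)),
               11^3 + 3^3)

  dark <- image_volume(array(-100, c(3, 3, 3)))
  expect_error(threshold_blood_pool(dark), "no blood pool")
})

test_that("mask_to_surface: closed, oriented, volume-faithful", {
  img <- rasterize_ellipsoid(c(10, 10, 10), 0.5)
  mask <- threshold_blood_pool(img)
  m <- mask_to_surface(mask, img$spacing, img$origin)
  expect_length(boundary_loops(m), 0)
  expect_gt(cardiotrack:::signed_volume_mm3(m$vertices, m$faces), 0)
  v_true <- 4 / 3 * pi * 1000 / 1000
  expect_lt(abs(enclosed_volume(m) - v_true) / v_true, 0.03)
  # divergence-theorem volume agrees with voxel counting at 0.5 mm
  v_count <- sum(mask) * 0.5^3 / 1000
  expect_lt(abs(enclosed_volume(m) - v_count) / v_count, 0.02)

  single <- mask_to_surface(array(1L, c(1, 1, 1)), c(1, 1, 1))
  expect_length(boundary_loops(single), 0)
  expect_lte(abs(enclosed_volume(single) - 0.001), 0.0005)
})

test_that("threshold -> surface -> volume error decreases with voxel size", {
  v_true <- 4 / 3 * pi * prod(c(9, 7, 6))
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    img <- rasterize_ellipsoid(c(9, 7, 6), sp)
    m <- mask_to_surface(threshold_blood_pool(img), img$spacing, img$origin)
    abs(enclosed_volume(m) * 1000 - v_true) / v_true
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("mesh formats round-trip losslessly with labels", {
  ph <- generate_phantom_cycle(coarse_phantom_spec())
  src <- ph$source
  for (ext in c("ply", "vtk", "vtp")) {
    p <- file.path(tempdir(), paste0("mesh_rt.", ext))
    write_mesh(src, p)
    r <- read_mesh(p)
    expect_identical(r$vertices, src$vertices, label = ext)
    expect_identical(r$faces, src$faces, label = ext)
    expect_identical(r$labels, src$labels, label = ext)
  }
  # STL: geometry-only; labels refused
  p <- file.path(tempdir(), "mesh_rt.stl")
  expect_error(write_mesh(src, p), "STL cannot carry")
  ball <- icosphere(5, 2)
  write_mesh(ball, p)
  r <- read_mesh(p)
  expect_equal(enclosed_volume(r), enclosed_volume(ball))
  expect_error(write_mesh(ball, file.path(tempdir(), "m.obj")), "unsupported")
})

test_that("image formats round-trip (float32 storage)", {
  set.seed(2)
  iv <- image_volume(array(rnorm(6 * 5 * 4, sd = 100), c(6, 5, 4)),
                     c(0.5, 0.6, 0.7), c(1, 2, 3))
  for (ext in c("nii", "mha", "mhd")) {
    p <- file.path(tempdir(), paste0("img_rt.", ext))
    write_image(iv, p)
    r <- read_image(p)
    expect_equal(dim(r$voxels), dim(iv$voxels), label = ext)
    expect_lt(max(abs(r$voxels - iv$voxels)), 1e-4)
    expect_equal(r$spacing, iv$spacing, tolerance = 1e-6)
    expect_equal(r$origin, iv$origin, tolerance = 1e-6)
  }
  expect_error(read_image("foo.dcm"), "unsupported image format")
})

test_that("curves and metrics round-trip through CSV at full precision", {
  mv <- synthetic_mv_curve()
  p <- file.path(tempdir(), "mv.csv")
  write_curve(mv, p)
  r <- read_curve(p)
  expect_identical(r$time_s, mv$time)
  expect_identical(r$flow_ml_per_s, mv$flow)

  met <- flow_metrics(mv)
  pm <- file.path(tempdir(), "met.csv")
  write_metrics(met, pm)
  rm <- read.csv(pm)
  expect_setequal(rm$metric, names(unlist(met)))
  expect_equal(rm$value[rm$metric == "e_peak"], met$e_peak)
})
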