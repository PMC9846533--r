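# The synthetic-data generator: ground-truth consistency, determinism,
# distortion regimes, and safety of the truth warp.

test_that("fiducials and landmarks are exactly consistent with the truth warp", {
  ph <- ph64()
  expect_points_equal(transform_point(ph$truth, ph$fiducials$fixed$points),
                      ph$fiducials$moving$points, 1e-9)
  expect_points_equal(transform_point(ph$truth, ph$landmarks$fixed$points),
                      ph$landmarks$moving$points, 1e-9)
})

test_that("undistorted phantoms differ only by contrast and noise", {
  ph0 <- fixture("ph32_none", function()
    make_phantom(32, 0.05, seed = 2, distortion = "none",
                 n_fiducials = 25))
  expect_equal(fiducial_l2(ph0$fiducials)$l2, 0)
  # pure scale: every fiducial satisfies the scaling about the center
  phs <- fixture("ph32_scale", function()
    make_phantom(32, 0.05, seed = 2, distortion = "scale",
                 n_fiducials = 25))
  ctr <- (dim(phs$fixed$data) - 1) * phs$fixed$spacing / 2
  want <- sweep(sweep(phs$fiducials$fixed$points, 2, ctr) * 1.2, 2, ctr,
                "+")
  expect_points_equal(phs$fiducials$moving$points, want, 1e-9)
})

test_that("same seed reproduces the bundle bitwise; different seeds differ", {
  a <- make_phantom(32, 0.05, seed = 5, distortion = "none",
                    n_fiducials = 22)
  b <- make_phantom(32, 0.05, seed = 5, distortion = "none",
                    n_fiducials = 22)
  c <- make_phantom(32, 0.05, seed = 6, distortion = "none",
                    n_fiducials = 22)
  expect_identical(a$fixed$data, b$fixed$data)
  expect_identical(a$moving$data, b$moving$data)
  expect_identical(a$fiducials$moving$points, b$fiducials$moving$points)
  expect_false(identical(a$moving$data, c$moving$data))
})

test_that("the truth warp is safely diffeomorphic and expansive in-mask", {
  ph <- ph64()
  bumps <- ph$truth$stages$bumps
  jd <- jacobian_determinant(render_field(bumps, ph$fixed))
  expect_gt(min(jd$data[ph$mask$data > 0.5]), 0.2)
  # swelling: moving anatomy volume exceeds fixed anatomy volume
  vf <- sum(ph$mask$data > 0.5) * prod(ph$fixed$spacing)
  vm <- sum(ph$moving$data > 0.05) * prod(ph$moving$spacing)
  expect_gt(vm, vf)
  # zero-amplitude truth spec is the identity
  t0 <- make_truth_warp(list(center = c(1, 1, 1)))
  p <- matrix(runif(30, 0, 3), 10, 3)
  expect_points_equal(transform_point(t0, p), p, 1e-12)
  # a single bump's field equals its amplitude at the bump center
  t1 <- make_truth_warp(list(center = c(1, 1, 1), bumps = list(
    list(center = c(1.2, 1, 1), sigma = 0.4, amp = c(0.1, 0, 0)))))
  expect_points_equal(transform_point(t1, c(1.2, 1, 1)),
                      c(1.3, 1, 1), 1e-12)
})

test_that("the two modalities are cross-contrast yet structurally related", {
  ph <- ph64()
  mov_on_fixed <- resample(ph$moving, ph$fixed, ph$truth)
  msk <- as.vector(ph$mask$data) > 0.5
  cc <- cross_correlation(ph$fixed, mov_on_fixed, mask = msk)
  lcc <- local_cc(ph$fixed, mov_on_fixed, 4, mask = msk)$mean
  mi <- mutual_information(ph$fixed, mov_on_fixed, mask = msk)
  expect_lt(abs(cc), 0.5)    # global correlation is weak (inverted regions)
  expect_gt(lcc, 0.3)        # local structure still corresponds
  expect_gt(mi, 0.2)         # intensities predict each other regionally
  # tear option removes anterior tissue from the moving volume
  pht <- make_phantom(48, 0.05, seed = 3, distortion = "none",
                      tear = TRUE, n_fiducials = 22)
  ph_nt <- make_phantom(48, 0.05, seed = 3, distortion = "none",
                        n_fiducials = 22)
  expect_lt(sum(pht$moving$data > 0.05), sum(ph_nt$moving$data > 0.05))
})

test_that("label volumes and masks agree with the anatomy", {
  ph <- ph64()
  lt <- ph$labels_fixed$label_table
  expect_setequal(lt$group, c("OB", "CB", "BS", "C"))
  # every labelled voxel lies in (slightly dilated) tissue
  lab_vox <- ph$labels_fixed$data > 0
  expect_gt(mean(ph$mask$data[lab_vox] > 0.2), 0.98)
})
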