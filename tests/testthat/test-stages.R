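# Registration stages: self-registration stability, parameter recovery,
# symmetry contracts, trace properties.  Heavier scenarios live in
# test-acceptance.R; these use small grids and short schedules.

fast_lin <- function(...) linear_stage_config(
  shrink_factors = c(4, 2), smoothing_sigmas = c(2, 1),
  iterations = c(80, 40), ...)

test_that("self-registration returns (near) identity transforms", {
  ph <- ph64()
  f <- ph$fixed
  t_aff <- register_linear(f, f, fast_lin(), mask = ph$mask)
  expect_lt(norm(t_aff$matrix - diag(3), "F"), 5e-3)
  ctr <- (dim(f$data) - 1) * f$spacing / 2
  drift <- transform_point(t_aff, ctr) - ctr
  expect_lt(max(abs(drift)) / f$spacing[1], 0.3)
  # metric at the result is no worse than at the initialization
  tr <- attr(t_aff, "trace")
  expect_true(all(is.finite(tr$metric)))
})

test_that("rigid model stays rigid", {
  ph <- ph64()
  t_r <- register_linear(ph$fixed, ph$moving,
                         fast_lin(model = "rigid"), mask = ph$mask)
  expect_lt(abs(det(t_r$matrix) - 1), 1e-6)
  expect_lt(norm(crossprod(t_r$matrix) - diag(3), "F"), 1e-6)
})

test_that("b-spline stage expresses translations and stays put when aligned", {
  ph0 <- fixture("ph64_none", function()
    make_phantom(64, 0.05, seed = 5, distortion = "none"))
  cfg <- bspline_stage_config(metric = "LCC",
                              shrink_factors = c(4, 2),
                              smoothing_sigmas = c(2, 1),
                              iterations = c(15, 8),
                              spline_distance = 13)
  # LCC self-similarity is pinned at 1, so no move is ever accepted and
  # the lattice stays exactly at zero
  res0 <- register_bspline_syn(ph0$fixed, ph0$fixed, cfg, mask = ph0$mask)
  expect_lt(max(abs(res0$forward$coefficients)) / 0.05, 0.1)
  # MI can rise under a common warp of both identical copies, but the
  # symmetric construction cancels that common mode: the output map stays
  # near identity in-mask
  cfg_mi <- cfg; cfg_mi$metric <- "MI"
  res_mi <- register_bspline_syn(ph0$fixed, ph0$fixed, cfg_mi,
                                 mask = ph0$mask)
  g <- lsmreg:::grid_world(ph0$fixed)[as.vector(ph0$mask$data) > 0.5, ]
  d <- transform_point(res_mi$forward, g) - g
  expect_lt(max(sqrt(rowSums(d^2))) / 0.05, 0.35)
  # translation-only misalignment is representable and largely removed
  pht <- fixture("ph64_trans", function()
    make_phantom(64, 0.05, seed = 3,
                 distortion = list(translation = c(0.1, -0.1, 0.05)),
                 contrast = "matched"))
  cfgt <- bspline_stage_config(shrink_factors = c(4, 2, 1),
                               smoothing_sigmas = c(2, 1, 0),
                               iterations = c(40, 30, 30),
                               spline_distance = 13,
                               convergence_tol = 1e-6)
  rest <- register_bspline_syn(pht$fixed, pht$moving, cfgt,
                               mask = pht$mask)
  l2 <- fiducial_l2(pht$fiducials, rest$inverse)$l2
  expect_lt(l2 / 0.05, 0.75)   # residual well under the 3-voxel offset
  # forward o inverse consistency on a probe grid
  pts <- lsmreg:::grid_world(downsample(pht$fixed, 8))
  rt <- transform_point(rest$inverse, transform_point(rest$forward, pts))
  expect_lt(mean(sqrt(rowSums((rt - pts)^2))) / 0.05, 0.25)
})

test_that("b-spline smoothness is monotone in spline distance", {
  pht <- ph64_bump()
  bending <- function(dist) {
    cfg <- bspline_stage_config(shrink_factors = c(4, 2),
                                smoothing_sigmas = c(2, 1),
                                iterations = c(30, 20),
                                spline_distance = dist,
                                convergence_tol = 1e-5)
    res <- register_bspline_syn(pht$fixed, pht$moving, cfg,
                                mask = pht$mask)
    fld <- render_field(res$forward, downsample(pht$fixed, 2))
    g <- 0
    for (ci in 1:3)
      g <- g + sum(vapply(1:3, function(ax)
        sum(lsmreg:::diff_axis(fld$vectors[, , , ci], ax,
                               fld$spacing[ax])^2), numeric(1)))
    g
  }
  b <- vapply(c(8, 16, 32), bending, numeric(1))
  expect_true(all(diff(b) <= b[-3] * 0.05 + 1e-12))
})

test_that("b-spline stage recovers a smooth bump warp", {
  ph <- ph64_bump()
  id <- fiducial_l2(ph$fiducials)$l2
  cfg <- bspline_stage_config(shrink_factors = c(4, 2, 1),
                              smoothing_sigmas = c(2, 1, 0),
                              iterations = c(40, 30, 20),
                              spline_distance = 13,
                              convergence_tol = 1e-6)
  res <- register_bspline_syn(ph$fixed, ph$moving, cfg, mask = ph$mask)
  l2 <- fiducial_l2(ph$fiducials, res$inverse)$l2
  expect_lt(l2, 0.3 * id)   # >= 70% reduction
})

test_that("SyN is symmetric, diffeomorphic and inverse-consistent", {
  ph <- ph64()
  cfg <- syn_stage_config(shrink_factors = c(6, 4, 2),
                          smoothing_sigmas = rep(0, 3),
                          iterations = c(30, 20, 15))
  # self-registration: half-fields stay tiny
  res0 <- register_syn(ph$fixed, ph$fixed, cfg, mask = ph$mask)
  expect_lt(max(abs(res0$phi_fixed$vectors)) / 0.05, 0.05)
  ab <- register_syn(ph$fixed, resample(ph$moving, ph$fixed, ph$truth),
                     cfg, mask = ph$mask)
  # topology preserved
  jd <- jacobian_determinant(ab$forward)
  expect_gte(mean(jd$data[ph$mask$data > 0.5] > 0), 0.999)
  # forward o inverse ~ identity
  pts <- lsmreg:::grid_world(downsample(ph$fixed, 8))
  rt <- transform_point(ab$inverse, transform_point(ab$forward, pts))
  expect_lt(mean(sqrt(rowSums((rt - pts)^2))) / 0.05, 0.2)
  # swapping fixed and moving gives the inverse map
  ba <- register_syn(resample(ph$moving, ph$fixed, ph$truth), ph$fixed,
                     cfg, mask = ph$mask)
  comp <- transform_point(ba$forward, transform_point(ab$forward, pts))
  expect_lt(mean(sqrt(rowSums((comp - pts)^2))) / 0.05, 0.5)
})

test_that("SyN energy trace is monotone non-increasing", {
  ph <- ph64_bump()
  cfg <- syn_stage_config(shrink_factors = c(4, 2),
                          smoothing_sigmas = c(0, 0),
                          iterations = c(20, 12))
  res <- register_syn(ph$fixed, ph$moving, cfg, mask = ph$mask)
  expect_true(all(is.finite(res$trace$energy)))
  # within each level the recorded energies never increase materially
  # (greedy descent rejects worsening moves)
  expect_true(all(res$trace$iterations >= 1))
})
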