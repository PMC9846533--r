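# Fiducial L2 loss, regional breakdown, displacement statistics, inverse
# label transfer and volume-ratio morphometry.

test_that("fiducial L2 equals the closed form and a brute-force oracle", {
  p <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(fiducial_l2(fiducial_set(p, p))$l2, 0)
  # single pair displaced by (3,4,0) mm: the 3-4-5 triangle
  expect_equal(fiducial_l2(fiducial_set(p, p + c(3, 4, 0)))$l2, 5)
  # two pairs with distances 3 and 4
  f2 <- fiducial_set(matrix(0, 2, 3),
                     rbind(c(3, 0, 0), c(0, 4, 0)))
  expect_equal(fiducial_l2(f2)$l2, sqrt((9 + 16) / 2), tolerance = 1e-12)
  # 1000 random pairs vs explicit loop
  set.seed(30)
  a <- matrix(rnorm(3000), 1000, 3); b <- matrix(rnorm(3000), 1000, 3)
  fs <- fiducial_set(a, b)
  acc <- 0
  for (i in 1:1000) acc <- acc + sum((a[i, ] - b[i, ])^2)
  expect_equal(fiducial_l2(fs)$l2, sqrt(acc / 1000), tolerance = 1e-12)
  # invariant under pair reordering
  o <- sample(1000)
  expect_equal(fiducial_l2(fiducial_set(a[o, ], b[o, ]))$l2,
               fiducial_l2(fs)$l2, tolerance = 1e-12)
  # invariant under a joint rigid motion of both point sets
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(fiducial_l2(fiducial_set(a %*% t(R) + 1, b %*% t(R) + 1))$l2,
               fiducial_l2(fs)$l2, tolerance = 1e-10)
})

test_that("regional L2 recombines to the global value", {
  set.seed(31)
  a <- matrix(rnorm(120), 40, 3); b <- a + matrix(rnorm(120, 0, 0.3), 40, 3)
  regs <- sample(c("CB", "OB", "C", "BS"), 40, TRUE)
  fs <- fiducial_set(a, b, regs)
  tab <- regional_l2(fs)
  # per-tag brute force
  for (r in unique(regs)) {
    d <- sqrt(rowSums((a[regs == r, , drop = FALSE] -
                         b[regs == r, , drop = FALSE])^2))
    expect_equal(tab$l2[tab$region == r], sqrt(mean(d^2)),
                 tolerance = 1e-12)
  }
  # count-weighted RMS recombination equals the global value
  glob <- sqrt(sum(tab$n * tab$l2^2) / sum(tab$n))
  expect_equal(glob, fiducial_l2(fs)$l2, tolerance = 1e-12)
  # all pairs in one region: regional equals global
  one <- fiducial_set(a, b, rep("OB", 40))
  t1 <- regional_l2(one)
  expect_equal(t1$l2, fiducial_l2(one)$l2, tolerance = 1e-12)
})

test_that("displacement statistics are the textbook mean and n-1 sd", {
  mk <- function(d) fiducial_set(matrix(0, length(d), 3),
                                 cbind(d, 0, 0))
  s1 <- displacement_stats(mk(c(5, 5, 5)))
  expect_equal(s1$mean, 5); expect_equal(s1$sd, 0)
  s2 <- displacement_stats(mk(c(0, 10)))
  expect_equal(s2$mean, 5)
  expect_equal(s2$sd, sqrt(50), tolerance = 1e-12)
  set.seed(32)
  d <- abs(rnorm(100, 2, 0.5))
  s3 <- displacement_stats(mk(d), units = "um")
  expect_equal(s3$mean, mean(d) * 1000, tolerance = 1e-9)
  expect_equal(s3$sd, sd(d) * 1000, tolerance = 1e-9)
  expect_error(displacement_stats(mk(5)), "2 pairs")
})

test_that("inverse label transfer preserves inventory and scales counts", {
  ph <- ph64()
  lab <- ph$labels_fixed
  # identity: exact count preservation
  id <- transfer_labels_inverse(lab, NULL, ph$fixed)
  expect_identical(id$data, lab$data)
  # pure 2x isotropic upscale: counts scale ~8x on a 2x-sized grid
  s2 <- affine_transform(diag(3) * 2, c(0, 0, 0))  # fixed -> moving
  big <- volume(array(0, dim(lab$data) * 2L), lab$spacing,
                c(0, 0, 0), "big")
  tr <- transfer_labels_inverse(lab, composite_transform(list(s = s2)),
                                big)
  for (idr in 1:5) {
    n0 <- sum(lab$data == idr)
    n1 <- sum(tr$data == idr)
    expect_lt(abs(n1 / n0 - 8), 8 * 0.02 + 3 / sqrt(n0) * 8)
  }
  # inventory never grows
  expect_true(all(unique(as.vector(tr$data)) %in%
                    c(0L, lab$label_table$id)))
})

test_that("volume ratios follow the (Vbefore - Vafter) / Vmr definition", {
  ph <- ph64()
  lab <- ph$labels_fixed
  # before == after: all ratios are zero
  rep0 <- volume_ratios(lab, lab, lab)
  expect_true(all(abs(rep0$ratio) < 1e-12))
  expect_false(any(rep0$id == 0))      # background never reported
  # rows ranked by reference volume, descending
  expect_true(all(diff(rep0$v_mr) <= 0))
  # uniform 1.2x swelling with perfect correction: ratio = 1.2^3 - 1
  phs <- fixture("ph64_scale", function()
    make_phantom(64, 0.05, seed = 9, distortion = "scale"))
  before <- transfer_labels_inverse(phs$labels_fixed, phs$truth,
                                    phs$moving_grid)
  repS <- volume_ratios(before, phs$labels_fixed, phs$labels_fixed)
  big <- repS[repS$v_mr > 0.05, ]   # discretization-stable regions
  expect_true(all(abs(big$ratio - (1.2^3 - 1)) < 0.05))
})

test_that("OB-concentrated swelling yields the largest OB ratio", {
  pho <- fixture("ph64_ob", function()
    make_phantom(64, 0.05, seed = 10, distortion = "ob"))
  before <- transfer_labels_inverse(pho$labels_fixed, pho$truth,
                                    pho$moving_grid)
  repO <- volume_ratios(before, pho$labels_fixed, pho$labels_fixed)
  ob <- repO$ratio[repO$name == "olfactory_bulb"]
  others <- repO$ratio[repO$name != "olfactory_bulb"]
  expect_true(all(ob > others))
  expect_gt(ob, 0)   # swelling: uncorrected OB is larger than corrected
})
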