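# Volume/transform data model: point mapping, resampling, composition,
# field inversion, pyramid primitives, Jacobians.

test_that("affine and composite point mapping obey the stated conventions", {
  expect_equal(transform_point(affine_transform(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(transform_point(affine_transform(diag(c(2, 2, 2))),
                               c(1, 0, 0)), c(2, 0, 0))
  a <- affine_transform(diag(c(2, 1, 0.5)), c(0.3, -0.2, 1))
  b <- affine_transform(matrix(c(1, 0.1, 0, 0, 1, 0, 0, 0, 1), 3, 3),
                        c(-1, 0, 2))
  set.seed(1)
  p <- matrix(rnorm(150), 50, 3)
  expect_points_equal(transform_point(compose_transforms(a, b), p),
                      transform_point(b, transform_point(a, p)), 1e-12)
  # composition associativity on points
  cc <- affine_transform(diag(3), c(5, 5, 5))
  t1 <- compose_transforms(compose_transforms(a, b), cc)
  t2 <- compose_transforms(a, compose_transforms(b, cc))
  expect_points_equal(transform_point(t1, p), transform_point(t2, p), 1e-10)
  # translate(+d) then translate(-d) is the identity
  d <- c(0.7, -0.3, 0.1)
  tt <- compose_transforms(affine_transform(diag(3), d),
                           affine_transform(diag(3), -d))
  expect_points_equal(transform_point(tt, p), p, 1e-12)
})

test_that("B-spline evaluation matches a dense basis-summation oracle", {
  ref <- volume(array(0, c(20, 20, 20)), 0.15)
  bs <- bspline_grid(ref, 0.5)
  set.seed(2)
  bs$coefficients[] <- rnorm(length(bs$coefficients)) * 0.05
  pts <- matrix(runif(300, 0.3, 2.5), 100, 3)
  got <- transform_point(bs, pts) - pts
  # brute force: sum every control point's tensor-product cubic basis
  bf1 <- function(x) {
    ax <- abs(x)
    ifelse(ax < 1, (4 - 6 * ax^2 + 3 * ax^3) / 6,
           ifelse(ax < 2, (2 - ax)^3 / 6, 0))
  }
  nc <- dim(bs$coefficients)[1:3]
  want <- matrix(0, nrow(pts), 3)
  for (n in seq_len(nrow(pts))) {
    u <- (pts[n, ] - bs$grid_origin) / bs$grid_spacing
    for (i in 0:(nc[1] - 1)) for (j in 0:(nc[2] - 1))
      for (k in 0:(nc[3] - 1)) {
        w <- bf1(u[1] - i) * bf1(u[2] - j) * bf1(u[3] - k)
        if (w != 0) want[n, ] <- want[n, ] + w * bs$coefficients[i + 1,
                                                                j + 1,
                                                                k + 1, ]
      }
  }
  expect_lt(max(abs(got - want)), 1e-9)
  # partition of unity: displacement of a constant lattice is constant
  bs$coefficients[] <- 0
  bs$coefficients[, , , 1] <- 0.25
  disp <- transform_point(bs, pts) - pts
  expect_lt(max(abs(disp[, 1] - 0.25)), 1e-12)
  expect_lt(max(abs(disp[, 2:3])), 1e-12)
})

test_that("resampling is exact for identity and voxel shifts, accurate for smooth warps", {
  set.seed(3)
  v <- volume(array(rnorm(32^3), c(32, 32, 32)), 0.1)
  expect_identical(resample(v, v)$data, v$data)
  # one-voxel translation shifts content and back-fills background
  t1 <- affine_transform(diag(3), c(0.1, 0, 0))
  r <- resample(v, v, t1)
  expect_identical(r$data[1:31, , ], v$data[2:32, , ])
  expect_true(all(r$data[32, , ] == 0))
  # random smooth warp vs an independent per-point interpolation oracle
  f <- smooth_random_field(c(32, 32, 32), 0.1, amp = 0.12)
  rw <- resample(v, v, f)
  idx <- cbind(sample(0:31, 200, TRUE), sample(0:31, 200, TRUE),
               sample(0:31, 200, TRUE))
  pts <- voxel_to_world(v, idx) + 0  # voxel centers
  mapped <- transform_point(f, pts)
  oracle <- vapply(seq_len(nrow(mapped)), function(i) {
    vox <- (mapped[i, ] - v$origin) / v$spacing
    if (any(vox < 0) || any(vox > 31)) return(0)
    i0 <- pmin(floor(vox), 30); fr <- vox - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * v$data[i0[1] + dx + 1, i0[2] + dy + 1,
                              i0[3] + dz + 1]
    }
    acc
  }, numeric(1))
  got <- rw$data[idx + 1]
  rng <- diff(range(v$data))
  expect_lt(mean(abs(got - oracle)) / rng, 1e-6)
})

test_that("label resampling is nearest-neighbor only and preserves inventory", {
  lab <- label_volume(array(sample(0:3, 16^3, TRUE), c(16, 16, 16)), 0.2)
  expect_error(resample(lab, lab, interp = "linear"), "nearest")
  r <- resample(lab, lab, affine_transform(diag(3), c(0.2, 0, 0)),
                interp = "nearest")
  expect_true(all(r$data %in% 0:3))
})

test_that("field inversion satisfies the fixed-point contract", {
  d <- c(20, 20, 20)
  zero <- displacement_field(array(0, c(d, 3)), 0.1)
  expect_equal(invert_field(zero)$vectors, zero$vectors)
  cv <- array(0, c(d, 3)); cv[, , , 2] <- 0.25
  cf <- displacement_field(cv, 0.1)
  ci <- invert_field(cf)
  expect_lt(max(abs(ci$vectors[, , , 2] + 0.25)), 1e-9)
  # smooth sinusoidal field of ~2 voxel amplitude inverts below 0.05 voxel
  xs <- (seq_len(d[1]) - 1) * 0.1
  sv <- array(0, c(d, 3))
  sv[, , , 1] <- array(0.2 * sin(2 * pi * xs / 1.9), d)
  sf <- displacement_field(sv, 0.1)
  si <- invert_field(sf, iters = 30, tol = 1e-4)
  expect_lt(attr(si, "residual"), 0.05 * 0.1)
})

test_that("round trip through a smooth warp and its inverse recovers the interior", {
  set.seed(8)
  v <- gaussian_smooth(volume(array(rnorm(32^3), c(32, 32, 32)), 0.1), 1.5)
  f <- smooth_random_field(c(32, 32, 32), 0.1, amp = 0.25, seed = 5)
  fi <- invert_field(f, iters = 40, tol = 1e-4)
  there <- resample(v, v, f)
  back <- resample(there, v, fi)
  core <- 6:27
  err <- abs(back$data[core, core, core] - v$data[core, core, core])
  expect_lt(mean(err) / diff(range(v$data)), 0.02)
})

test_that("smoothing and downsampling follow the schedule semantics", {
  v <- volume(array(5, c(16, 16, 16)), 0.1)
  expect_lt(max(abs(gaussian_smooth(v, 2)$data - 5)), 1e-10)
  set.seed(4)
  w <- volume(array(rnorm(64^3), c(64, 64, 64)), 0.05)
  expect_identical(downsample(w, 1)$data, w$data)
  d4 <- downsample(w, 4)
  expect_equal(dim(d4$data), c(16L, 16L, 16L))
  expect_equal(d4$spacing, rep(0.2, 3))
  expect_error(downsample(volume(array(0, c(4, 4, 4))), 5), "exceeds")
  # downsample -> upsample of a band-limited volume matches the
  # anti-alias-blurred original
  g <- lsmreg:::grid_world(w)
  wb <- volume(array(sin(2 * pi * g[, 1] / 2.4) *
                       cos(2 * pi * g[, 2] / 2.8), dim(w$data)), 0.05)
  ds <- downsample(wb, 2)             # anti-alias sigma 1 voxel
  us <- resample(ds, wb)
  ref <- gaussian_smooth(wb, 1)
  core <- 5:60
  rel <- sqrt(mean((us$data[core, core, core] -
                      ref$data[core, core, core])^2)) /
    sd(as.vector(ref$data[core, core, core]))
  expect_lt(rel, 0.015)
})

test_that("jacobian determinant matches closed forms and an oracle", {
  d <- c(12, 12, 12)
  expect_equal(max(abs(jacobian_determinant(
    displacement_field(array(0, c(d, 3)), 0.1))$data - 1)), 0)
  # uniform scale s per axis: field u = (s-1) x, det = s^3 in the interior
  s <- 1.15
  g <- lsmreg:::grid_world(volume(array(0, d), 0.1))
  vec <- array((s - 1) * g, c(d, 3))
  jd <- jacobian_determinant(displacement_field(vec, 0.1))
  expect_lt(max(abs(jd$data[2:11, 2:11, 2:11] - s^3)), 1e-8)
  # random smooth field vs independent finite-difference oracle
  f <- smooth_random_field(c(12, 12, 12), 0.1, amp = 0.08, seed = 12)
  jd2 <- jacobian_determinant(f)
  i <- c(5, 6, 7)
  J <- diag(3)
  for (ci in 1:3) for (ax in 1:3) {
    ip <- i; im <- i; ip[ax] <- ip[ax] + 1; im[ax] <- im[ax] - 1
    J[ci, ax] <- J[ci, ax] +
      (f$vectors[ip[1], ip[2], ip[3], ci] -
         f$vectors[im[1], im[2], im[3], ci]) / (2 * 0.1)
  }
  expect_lt(abs(det(J) - jd2$data[i[1], i[2], i[3]]), 1e-8)
})

test_that("world/voxel coordinate round trips are exact", {
  v <- volume(array(0, c(10, 12, 14)), c(0.11, 0.07, 0.05),
              c(-1, 0.5, 2))
  idx <- cbind(0:9, 1:10, 2:11)
  expect_points_equal(world_to_voxel(v, voxel_to_world(v, idx)), idx,
                      1e-9)
})
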