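# Similarity metrics: identities, oracle agreement, invariances, and the
# analytic gradients driving the registration stages.

test_that("mutual information obeys its information-theoretic identities", {
  a <- array(rep(c(0, 1), each = 256), c(8, 8, 8))
  v <- volume(a)
  # MI(F,F) = H(F) = ln 2 for a two-valued half/half image with 2 bins
  expect_equal(mutual_information(v, v, bins = 2, clip = NULL), log(2),
               tolerance = 1e-12)
  # statistically independent images: MI -> 0
  set.seed(10)
  f <- volume(array(rnorm(64^3), c(64, 64, 64)))
  m <- volume(array(rnorm(64^3), c(64, 64, 64)))
  expect_lt(mutual_information(f, m), 0.02)
  # symmetry and non-negativity up to Parzen spreading
  set.seed(11)
  x <- volume(array(runif(16^3), c(16, 16, 16)))
  y <- volume(array(runif(16^3) + 0.3 * x$data, c(16, 16, 16)))
  expect_equal(mutual_information(x, y), mutual_information(y, x),
               tolerance = 1e-12)
  mi <- mutual_information(x, y)
  hx <- -sum(prop.table(table(cut(as.vector(x$data), 32))) *
               log(pmax(prop.table(table(cut(as.vector(x$data), 32))),
                        1e-300)))
  expect_gte(mi, 0 - 1e-6)
  expect_lte(mi, hx + 1e-3)
  # constant image degenerates with a warning
  expect_warning(mi0 <- mutual_information(volume(array(1, c(8, 8, 8))),
                                           volume(array(runif(512),
                                                        c(8, 8, 8)))),
                 "constant")
  expect_equal(mi0, 0)
})

test_that("the Parzen joint histogram equals a double-loop oracle", {
  set.seed(12)
  ff <- array(runif(128), c(8, 8, 2))
  mm <- array(runif(128), c(8, 8, 2))
  bins <- 4
  jh <- joint_histogram(ff, mm, bins, clip = NULL)
  bco <- function(x) (x - min(x)) / (max(x) - min(x)) * (bins - 1)
  bf <- bco(as.vector(ff)); bm <- bco(as.vector(mm))
  cnt <- matrix(0, bins, bins)
  for (k in seq_along(bf)) {
    i0 <- min(floor(bf[k]), bins - 2); fi <- bf[k] - i0
    j0 <- min(floor(bm[k]), bins - 2); fj <- bm[k] - j0
    for (di in 0:1) for (dj in 0:1)
      cnt[i0 + di + 1, j0 + dj + 1] <- cnt[i0 + di + 1, j0 + dj + 1] +
        (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
  }
  expect_lt(max(abs(jh$counts - cnt)), 1e-12)
  expect_equal(rowSums(jh$counts), jh$marginal_f)
  expect_equal(colSums(jh$counts), jh$marginal_m)
  expect_equal(sum(jh$counts), jh$n)
})

test_that("cross-correlation matches the closed form and its invariances", {
  set.seed(13)
  f <- volume(array(rnorm(16^3), c(16, 16, 16)))
  expect_equal(cross_correlation(f, f), 1)
  expect_equal(cross_correlation(f, volume(-f$data + 3)), -1)
  m <- volume(array(rnorm(16^3), c(16, 16, 16)))
  # textbook Pearson oracle
  fv <- as.vector(f$data); mv <- as.vector(m$data)
  want <- sum((fv - mean(fv)) * (mv - mean(mv))) /
    sqrt(sum((fv - mean(fv))^2) * sum((mv - mean(mv))^2))
  expect_equal(cross_correlation(f, m), want, tolerance = 1e-12)
  # affine intensity invariance: CC(f, a m + b) = sign(a) CC(f, m)
  expect_equal(cross_correlation(f, volume(2.5 * m$data + 1)),
               cross_correlation(f, m), tolerance = 1e-12)
  expect_equal(cross_correlation(f, volume(-0.5 * m$data + 2)),
               -cross_correlation(f, m), tolerance = 1e-12)
  expect_error(cross_correlation(f, volume(array(1, c(16, 16, 16)))),
               "variance")
})

test_that("windowed local correlation equals a sliding-window oracle", {
  set.seed(14)
  ft <- array(rnorm(16^3), c(16, 16, 16))
  mt <- ft + array(rnorm(16^3), c(16, 16, 16)) * 0.5
  lc <- local_cc(volume(ft), volume(mt), radius = 2)
  for (rep in 1:15) {
    i <- sample(3:14, 1); j <- sample(3:14, 1); k <- sample(3:14, 1)
    wf <- as.vector(ft[(i - 2):(i + 2), (j - 2):(j + 2), (k - 2):(k + 2)])
    wm <- as.vector(mt[(i - 2):(i + 2), (j - 2):(j + 2), (k - 2):(k + 2)])
    expect_equal(lc$map$data[i, j, k], cor(wf, wm), tolerance = 1e-8)
  }
  expect_equal(local_cc(volume(ft), volume(ft), 3)$mean, 1)
  # globally inverted contrast: signed mean LCC is -1
  expect_equal(local_cc(volume(ft), volume(-ft + 2), 3)$mean, -1)
})

test_that("metric gradients align with finite differences and geometry", {
  set.seed(15)
  f <- volume(array(runif(512), c(8, 8, 8)), 0.1)
  # identical images: gradient vanishes
  g0 <- metric_gradient("MSE", f, f)
  expect_lt(max(abs(g0$vectors)), 1e-8)
  # single off-center bump: force points toward alignment
  fb <- volume(array(0, c(9, 9, 9)), 0.1)
  fb$data[5, 5, 5] <- 1
  mb <- volume(array(0, c(9, 9, 9)), 0.1)
  mb$data[6, 5, 5] <- 1   # moving bump offset by +1 voxel in x
  gb <- metric_gradient("MSE", fb, mb)
  # at the fixed bump the pull must be toward +x (sample there)
  expect_gt(gb$vectors[5, 5, 5, 1], 0)
  # MI gradient vs central finite differences of MI under intensity
  # perturbation (cosine similarity)
  m <- volume(array(runif(512), c(8, 8, 8)), 0.1)
  jd <- lsmreg:::metric_intensity_derivative("MI", f$data, m$data,
                                             bins = 8)
  mi0 <- mutual_information(f, m, 8)
  eps <- 1e-4
  idx <- seq(1, 512, by = 8)
  fd <- vapply(idx, function(k) {
    md <- m$data; md[k] <- md[k] + eps
    (mutual_information(f, volume(md, 0.1), 8) - mi0) / eps
  }, numeric(1))
  cs <- sum(fd * jd[idx]) / sqrt(sum(fd^2) * sum(jd[idx]^2))
  expect_gt(cs, 0.99)
})

test_that("MI is invariant to monotone relabeling preserving bin occupancy", {
  set.seed(16)
  x <- array(sample(0:3, 16^3, TRUE), c(16, 16, 16))
  y <- array(sample(0:3, 16^3, TRUE) + 0.5 * x, c(16, 16, 16))
  mi1 <- mutual_information(volume(x), volume(y), bins = 8, clip = NULL)
  # strictly monotone remap of x that keeps values on the same bin centers
  x2 <- 2 * x + 1
  mi2 <- mutual_information(volume(x2), volume(y), bins = 8, clip = NULL)
  expect_equal(mi1, mi2, tolerance = 1e-12)
})
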