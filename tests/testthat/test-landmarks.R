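# Landmark initialization: affine and TPS fits against closed-form
# oracles, and the initialization contract on phantoms.

test_that("affine landmark fit is exact on affine-generated pairs", {
  th <- 15 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  A <- 1.3 * R; tr <- c(0.3, -0.2, 0.1)
  set.seed(20)
  fx <- matrix(runif(60, 0, 5), 20, 3)
  mv <- fx %*% t(A) + matrix(tr, 20, 3, byrow = TRUE)
  fit <- fit_affine_landmarks(landmark_pairs(fx, mv))
  expect_lt(norm(fit$matrix - A, "F"), 1e-9)
  expect_lt(max(abs(fit$translation - tr)), 1e-9)
  expect_lt(attr(fit, "rms"), 1e-9)
  # identical point sets give the identity
  fid <- fit_affine_landmarks(landmark_pairs(fx, fx))
  expect_lt(norm(fid$matrix - diag(3), "F"), 1e-10)
  # noisy pairs match the closed-form normal-equations oracle
  mvn <- mv + matrix(rnorm(60, 0, 0.05), 20, 3)
  fitn <- fit_affine_landmarks(landmark_pairs(fx, mvn))
  X <- cbind(fx, 1)
  beta <- solve(crossprod(X), crossprod(X, mvn))
  expect_lt(norm(fitn$matrix - t(beta[1:3, ]), "F"), 1e-10)
  expect_lt(max(abs(fitn$translation - beta[4, ])), 1e-10)
  # coplanar configurations are rejected with a geometry diagnosis
  cop <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(fit_affine_landmarks(landmark_pairs(cop, cop)),
               "coplanar|collinear")
})

test_that("thin-plate-spline fit interpolates, degenerates to affine, and matches the kernel oracle", {
  set.seed(21)
  fx <- matrix(runif(36, 0, 5), 12, 3)
  mv <- fx + matrix(rnorm(36, 0, 0.3), 12, 3)
  lp <- landmark_pairs(fx, mv)
  tps <- fit_tps_landmarks(lp, 0)
  expect_points_equal(transform_point(tps, fx), mv, 1e-6)
  # pure translation gives a constant displacement everywhere
  tr <- c(1, 2, 3)
  tpt <- fit_tps_landmarks(landmark_pairs(fx, sweep(fx, 2, -tr)), 0)
  probe <- matrix(runif(60, 0, 5), 20, 3)
  expect_points_equal(transform_point(tpt, probe) - probe,
                      matrix(tr, 20, 3, byrow = TRUE), 1e-8)
  # lambda -> infinity approaches the least-squares affine
  tpsL <- fit_tps_landmarks(lp, 1e7)
  aff <- fit_affine_landmarks(lp)
  expect_points_equal(transform_point(tpsL, probe),
                      transform_point(aff, probe), 1e-3)
  # off-landmark values match a direct radial-basis summation
  sol_oracle <- function(p) {
    U <- sqrt(rowSums(sweep(fx, 2, p)^2))
    p + c(1, p) %*% tps$affine + colSums(tps$weights * U)
  }
  for (i in 1:10)
    expect_points_equal(transform_point(tps, probe[i, ]),
                        drop(sol_oracle(probe[i, ])), 1e-8)
  # duplicate fixed points are rejected
  expect_error(fit_tps_landmarks(landmark_pairs(fx[c(1, 1, 2:11), ],
                                                mv)), "duplicate")
})

test_that("landmark initialization reduces the fiducial loss on a distorted phantom", {
  ph <- ph64()
  ini <- initialize_landmarks(ph$moving, ph$fixed, ph$landmarks)
  expect_lt(ini$rms_after, ini$rms_before)
  l2_pre <- fiducial_l2(ph$fiducials)$l2
  inv <- invert_affine(ini$transform$stages$init)
  l2_post <- fiducial_l2(ph$fiducials, inv)$l2
  expect_lt(l2_post, l2_pre)
  # exact landmarks + affine-dominated truth: post-init error is small
  expect_lt(l2_post, 0.5 * l2_pre)
  # initialized volume lives on the fixed grid
  expect_equal(dim(ini$volume$data), dim(ph$fixed$data))
})

test_that("adding a consistent pair never degrades the affine fit", {
  set.seed(22)
  fx <- matrix(runif(45, 0, 5), 15, 3)
  A <- diag(c(1.2, 0.9, 1.1))
  mv <- fx %*% t(A)
  fit1 <- fit_affine_landmarks(landmark_pairs(fx, mv))
  extra <- matrix(runif(3, 0, 5), 1, 3)
  fit2 <- fit_affine_landmarks(landmark_pairs(rbind(fx, extra),
                                              rbind(mv, extra %*% t(A))))
  expect_lte(attr(fit2, "rms"), attr(fit1, "rms") + 1e-10)
})
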