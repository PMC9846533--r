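# Shared fixtures, built lazily and cached for the whole test run.
# Heavy objects (phantoms, pipeline runs) are computed once; every test
# that needs them pulls from this cache.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small dual-contrast phantom with the default (affine + OB/BS bumps)
# distortion
ph64 <- function() fixture("ph64", function()
  make_phantom(64, 0.05, seed = 7, distortion = "default"))

# matched-contrast phantom warped by a single smooth bump (B-spline stage
# recovery scenario)
ph64_bump <- function() fixture("ph64_bump", function()
  make_phantom(64, 0.05, seed = 4,
               distortion = list(bumps = list(list(
                 center = c(1.6, 1.6, 1.6), sigma = 1.0,
                 amp = c(0.15, 0.08, -0.05)))),
               contrast = "matched"))

# full-size phantom under the study conditions: 40%-class distortion
# concentrated on the OB/BS analogs, landmarks placed with reader jitter
ph96 <- function() fixture("ph96", function()
  make_phantom(96, 0.05, seed = 11, distortion = "default",
               landmark_jitter = 0.1))

# the full staged pipeline (landmark init + affine + b-spline SyN + SyN)
# on the 96^3 phantom; reused by several acceptance checks
crit_pipeline <- function() fixture("crit_pipeline", function()
  run_pipeline(ph96()$fixed, ph96()$moving, ph96()$landmarks, "p1_02",
               mask = ph96()$mask))

# random smooth displacement field on a small grid
smooth_random_field <- function(dims = c(16, 16, 16), spacing = 0.1,
                                amp = 0.15, seed = 99, sigma = 2) {
  set.seed(seed)
  vec <- array(rnorm(prod(dims) * 3), c(dims, 3))
  for (ci in 1:3)
    vec[, , , ci] <- lsmreg:::smooth_array(vec[, , , ci], sigma)
  vec <- vec / max(abs(vec)) * amp
  displacement_field(vec, rep(spacing, 3), c(0, 0, 0))
}

expect_points_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
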