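test_that("the threshold update matches case-wise evaluation", {
  # printed cases
  expect_equal(threshold_update(c(0, 0), rho = -0.1, grad = c(1, 0),
                                lam = 0.05, theta = 0.3), c(0.015, 0))
  expect_equal(threshold_update(c(0.3, -0.2), rho = 0, grad = c(1, 0)),
               c(0.3, -0.2))
  expect_equal(threshold_update(c(0.3, -0.2), rho = 5, grad = c(0, 0)),
               c(0.3, -0.2))
  # randomised scalar instances against an independent piecewise oracle
  oracle <- function(U, rho, grad, lam, theta) {
    g2 <- grad[1]^2 + grad[2]^2
    if (g2 == 0) return(U)
    lim <- lam * theta * g2
    if (rho < -lim) return(U + lam * theta * grad)
    if (rho > lim) return(U - lam * theta * grad)
    U - (rho / g2) * grad
  }
  set.seed(42)
  for (i in 1:200) {
    U <- rnorm(2); rho <- rnorm(1, sd = 2)
    grad <- if (i %% 17 == 0) c(0, 0) else rnorm(2)
    lam <- runif(1, 0.01, 0.5); theta <- runif(1, 0.05, 1)
    expect_equal(threshold_update(U, rho, grad, lam, theta),
                 oracle(U, rho, grad, lam, theta), tolerance = 1e-12)
  }
})

test_that("identical frames give (numerically) zero flow", {
  tex <- smooth_texture(64, seed = 7)
  fl <- compute_tvl1_flow(tex, tex)
  expect_lt(max(abs(fl$u)), 0.05)
  expect_lt(max(abs(fl$v)), 0.05)
})

test_that("known integer shifts are recovered to sub-pixel accuracy", {
  tex <- smooth_texture(64, seed = 7)
  fl <- compute_tvl1_flow(tex, cshift(tex, 2))
  expect_gte(median(central(fl$u)), 1.8)
  expect_lte(median(central(fl$u)), 2.2)
  expect_gte(median(central(fl$v)), -0.2)
  expect_lte(median(central(fl$v)), 0.2)
  for (s in 1:3) {
    fls <- compute_tvl1_flow(tex, cshift(tex, s))
    epe <- mean(sqrt((central(fls$u) - s)^2 + central(fls$v)^2))
    expect_lt(epe, 0.5)
  }
})

test_that("swapping the frames approximately negates the flow", {
  tex <- smooth_texture(64, seed = 9)
  sh <- cshift(tex, 2)
  fwd <- compute_tvl1_flow(tex, sh)
  bwd <- compute_tvl1_flow(sh, tex)
  expect_lt(mean(abs(central(fwd$u) + central(bwd$u))), 0.3)
  expect_lt(mean(abs(central(fwd$v) + central(bwd$v))), 0.3)
})

test_that("the inner alternation descends the surrogate energy", {
  tex <- smooth_texture(16, seed = 3)
  e <- tvl1_energy_trace(tex, cshift(tex, 1), n_outer = 20, n_dual = 40)
  # monotone descent up to the limit cycle of the inexact TV proximal step
  expect_true(all(diff(e) <= 1e-4 * abs(e[1])))
  expect_lt(e[20], 0.6 * e[1])
})

test_that("solver input contracts are enforced", {
  tex <- smooth_texture(16, seed = 3)
  expect_error(compute_tvl1_flow(tex, tex[1:8, ]), "shape")
  bad <- tex; bad[1, 1] <- NaN
  expect_error(compute_tvl1_flow(tex, bad), "finite")
  expect_error(tvl1_params(eta = 1.5), "eta")
  expect_error(tvl1_params(lam = -1), "> 0")
})

test_that("the colour wheel encodes direction as hue and magnitude as
           saturation", {
  z <- flow_field(matrix(0, 8, 8), matrix(0, 8, 8))
  white <- flow_to_feature_map(z, max_mag = 1)
  expect_equal(max(abs(white - 1)), 0, tolerance = 1e-12) # zero flow -> white
  m <- 0.8
  right <- flow_to_feature_map(flow_field(matrix(m, 4, 4), matrix(0, 4, 4)),
                               max_mag = 1)
  left <- flow_to_feature_map(flow_field(matrix(-m, 4, 4), matrix(0, 4, 4)),
                              max_mag = 1)
  # hue 0 (red) vs hue 180 deg (cyan) at saturation m
  expect_equal(right[1, 1, ], c(1, 1 - m, 1 - m), tolerance = 1e-9)
  expect_equal(left[1, 1, ], c(1 - m, 1, 1), tolerance = 1e-9)
  # doubling max_mag halves the saturation (1 - min channel)
  half <- flow_to_feature_map(flow_field(matrix(m, 4, 4), matrix(0, 4, 4)),
                              max_mag = 2)
  sat <- function(px) 1 - min(px)
  expect_equal(sat(half[1, 1, ]), sat(right[1, 1, ]) / 2, tolerance = 1e-9)
  expect_error(flow_to_feature_map(z, max_mag = -1), "positive")
})

test_that("flow fields round-trip through the .flo format", {
  set.seed(5)
  fl <- flow_field(matrix(rnorm(12 * 10), 12, 10),
                   matrix(rnorm(12 * 10), 12, 10))
  f <- withr::local_tempfile(fileext = ".flo")
  write_flo(fl, f)
  back <- read_flo(f)
  expect_equal(back$u, fl$u, tolerance = 1e-6)
  expect_equal(back$v, fl$v, tolerance = 1e-6)
})
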