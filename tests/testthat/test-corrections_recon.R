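test_that("TEW trapezoid estimator matches hand-evaluated values", {
  w <- get_windows("I131")  # W_L = 22, W_P = 72, W_U = 22
  s <- tew_estimate(matrix(100, 1, 1), matrix(22, 1, 1), matrix(22, 1, 1), w)
  expect_equal(s[1, 1], (22 / 22 + 22 / 22) * 72 / 2)  # = 72

  z <- tew_estimate(matrix(5, 2, 3), matrix(0, 2, 3), matrix(0, 2, 3), w)
  expect_true(all(z == 0))

  # quebec dialect: 21-keV scatter windows enter the widths
  q <- get_windows("Lu177", "quebec")
  sq <- tew_estimate(matrix(0, 1, 1), matrix(21, 1, 1), matrix(21, 1, 1), q)
  expect_equal(sq[1, 1], (21 / 21 + 21 / 21) * 42 / 2)

  expect_error(tew_estimate(matrix(0, 2, 2), matrix(0, 2, 3),
                            matrix(0, 2, 2), w), "identical shapes")
  expect_error(tew_estimate(matrix(-1, 2, 2), matrix(0, 2, 2),
                            matrix(0, 2, 2), w), "negative")
})

test_that("projector conserves counts without attenuation and attenuates centered sources correctly", {
  g <- fx_small_geometry(n = 32, n_angles = 12)
  img <- array(0, dim = c(32, 32, 32))
  set.seed(4)
  img[10:22, 10:22, 10:22] <- runif(13^3)

  # zero image -> zero projections
  p0 <- forward_project(array(0, dim = dim(img)), g$map, g$angles)
  expect_true(all(p0 == 0))

  # mu = 0: per-angle projection total equals image total
  map0 <- g$map; map0$mu[] <- 0
  # count conservation holds to the bilinear-interpolation accuracy
  p <- forward_project(img, map0, g$angles)
  expect_equal(apply(p, 3, sum), rep(sum(img), 12), tolerance = 1e-3)

  # unit source at the center of a water cylinder: attenuated by the
  # central chord at every angle
  ph <- make_configuration("D", "Lu177")
  m <- make_attenuation_map(ph)
  src <- array(0, dim = c(64, 64, 64))
  src[32:33, 32:33, 32] <- 0.25
  ang <- seq(0, 2 * pi, length.out = 13)[1:12]
  pc <- forward_project(src, m, ang)
  expect_equal(mean(apply(pc, 3, sum)),
               exp(-mu_linear("water", 208) * 10), tolerance = 0.04)

  expect_error(forward_project(img, g$map, numeric(0)), "empty")
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- fx_small_geometry(n = 32, n_angles = 8)
  set.seed(11)
  x <- array(runif(32^3), dim = c(32, 32, 32))
  y <- array(runif(32 * 32 * 8), dim = c(32, 32, 8))
  lhs <- sum(forward_project(x, g$map, g$angles) * y)
  rhs <- sum(x * back_project(y, g$map, g$angles))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  b0 <- back_project(array(0, dim = c(32, 32, 8)), g$map, g$angles)
  expect_true(all(b0 == 0))

  # uniform projections, mu = 0: flat interior proportional to n_angles
  map0 <- g$map; map0$mu[] <- 0
  b1 <- back_project(array(1, dim = c(32, 32, 8)), map0, g$angles)
  interior <- b1[10:22, 10:22, 10:22]
  expect_equal(mean(interior), 8, tolerance = 0.01)
  # the scatter-adjoint carries a zero-mean interpolation texture; the
  # locally averaged field is flat at the angular sampling density
  box <- array(0, dim = c(11, 11, 11))
  for (i in 1:11) for (j in 1:11) for (k in 1:11)
    box[i, j, k] <- mean(interior[i:(i + 2), j:(j + 2), k:(k + 2)])
  expect_lt(max(abs(box - 8)), 0.25)  # few-percent residual texture
})

test_that("MLEM scalar fixed points are reached", {
  one <- function(v) array(v, dim = c(1, 1, 1))
  map1 <- structure(list(mu = one(0), voxel_size = 9.58, energy = 208,
                         grid_shape = 1), class = "attenuation_map")
  # y = 50, s = 0: fixed point after a single iteration
  r <- osem(one(50), NULL, map1, angles = 0, iterations = 1, subsets = 1)
  expect_equal(r$image[1, 1, 1], 50, tolerance = 1e-9)
  # y = 50, s = 20: converges to y - s = 30
  r2 <- osem(one(50), one(20), map1, angles = 0, iterations = 400,
             subsets = 1)
  expect_equal(r2$image[1, 1, 1], 30, tolerance = 1e-3)
})

test_that("OSEM recovers total counts from noiseless matched projections", {
  g <- fx_small_geometry(n = 32, n_angles = 10)
  x_true <- array(0, dim = c(32, 32, 32))
  ctr <- (1:32) - 16.5
  r2 <- outer(outer(ctr^2, ctr^2, `+`), ctr^2, `+`)
  x_true[r2 <= 4^2] <- 2
  y <- forward_project(x_true, g$map, g$angles)
  s_true <- 0.2 * y + 0.05 * mean(y)  # known additive scatter
  rec <- osem(y + s_true, s_true, g$map, g$angles, iterations = 20,
              subsets = 5)
  expect_equal(sum(rec$image), sum(x_true), tolerance = 0.01)
  expect_true(all(rec$image >= 0))

  # noiseless totals stable under the subset decomposition
  rec2 <- osem(y + s_true, s_true, g$map, g$angles, iterations = 50,
               subsets = 2)
  expect_equal(sum(rec2$image), sum(rec$image), tolerance = 0.005)

  expect_error(osem(y, NULL, g$map, g$angles, iterations = 2, subsets = 7),
               "divide")
  bad <- array(0, dim = c(32, 32, 9))
  expect_error(osem(bad, NULL, g$map, g$angles, 1, 1), "match")
})

test_that("Poisson log-likelihood is non-decreasing over full EM iterations", {
  g <- fx_small_geometry(n = 16, n_angles = 6)
  map <- g$map
  map$mu <- map$mu[1:16, 1:16, 1:16, drop = FALSE] * 0 + 0.05
  dim(map$mu) <- c(16, 16, 16)
  map$grid_shape <- 16
  x_true <- array(0, dim = c(16, 16, 16)); x_true[6:10, 6:10, 6:10] <- 5
  lam <- forward_project(x_true, map, g$angles)
  set.seed(5)
  y <- array(rpois(length(lam), lam), dim = dim(lam))
  rec <- osem(y, NULL, map, g$angles, iterations = 8, subsets = 1,
              track_loglik = TRUE)
  expect_true(all(diff(rec$loglik) > -1e-6))
})

test_that("recon defaults follow the per-isotope protocol", {
  expect_equal(recon_defaults("I131"), list(iterations = 35, subsets = 6))
  expect_equal(recon_defaults("Lu177"), list(iterations = 6, subsets = 10))
  expect_equal(recon_defaults("Re188"), list(iterations = 6, subsets = 10))
  expect_equal(recon_defaults("Lu177", "quebec")$subsets, 12)
})
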