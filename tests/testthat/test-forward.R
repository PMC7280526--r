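test_that("zero data give the zero state and constant data a steady state", {
  m <- tiny_annulus()
  ctx <- fem_context(m)
  grid <- time_grid(2, 24)
  nb <- length(ctx$bvert)
  D <- region_adc(GM = 0.47, WM = 0.40)

  g0 <- boundary_control(matrix(0, nb, grid$k + 1), grid)
  s0 <- solve_diffusion(m, D, g0, grid, ctx = ctx)
  expect_identical(max(abs(s0$values)), 0)

  gc <- boundary_control(matrix(0.7, nb, grid$k + 1), grid)
  sc <- solve_diffusion(m, D, gc, grid, u0 = rep(0.7, ctx$nv), ctx = ctx)
  expect_lt(max(abs(sc$values - 0.7)), 1e-10)
})

test_that("all-Neumann runs conserve total mass to near machine precision", {
  m <- tiny_annulus()
  m$dirichlet_tags <- character(0)
  ctx <- fem_context(m)
  grid <- time_grid(2, 24)
  u0 <- 0.5 + m$vertices[, 1]^2 / 2000
  for (th in c(1, 0.5)) {
    s <- solve_diffusion(m, region_adc(GM = 0.47, WM = 0.40), NULL, grid,
                         u0 = u0, theta = th, ctx = ctx)
    mass <- as.numeric(rep(1, ctx$nv) %*% (ctx$M %*% s$values))
    expect_lt(max(abs(mass - mass[1])) / abs(mass[1]), 1e-10)
  }
})

test_that("slab solution converges to the erfc profile at first order in dt", {
  # semi-infinite slab: u(x, t) = erfc(x / (2 sqrt(D t))), Dirichlet u = 1 at
  # x = 0 switched on at t = 0; domain long enough that the far end is dark
  m <- build_rectangle_mesh(40, 3, 160, 4, dirichlet_tags = "RED_SAS")
  ctx <- fem_context(m)
  D <- region_adc(GM = 1)
  T_final <- 4
  x <- m$vertices[, 1]
  # erfc(z) = 2 * pnorm(-z * sqrt(2)) with z = x / (2 sqrt(D T))
  exact <- 2 * stats::pnorm(-sqrt(2) * x / (2 * sqrt(1 * T_final)))
  errs <- sapply(c(16, 32, 64), function(k) {
    grid <- time_grid(T_final / k, T_final)
    g <- boundary_control(matrix(1, length(ctx$bvert), grid$k + 1), grid)
    s <- solve_diffusion(m, D, g, grid, ctx = ctx)
    d <- s$values[, grid$k + 1] - exact
    sqrt(as.numeric(d %*% (ctx$M %*% d)))
  })
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.8 & orders < 1.3))
})

test_that("lumped-mass stepping satisfies the discrete maximum principle", {
  m <- build_rectangle_mesh(20, 10, 40, 20,
                            dirichlet_tags = c("RED_SAS", "BLUE_VENTRICLE"))
  ctx <- fem_context(m)
  grid <- time_grid(1, 12)
  nb <- length(ctx$bvert)
  gmax <- 1.3
  g <- boundary_control(
    matrix(rep(gmax * grid$times / 12, each = nb), nb, grid$k + 1), grid)
  s <- solve_diffusion(m, region_adc(GM = 0.5), g, grid, lump = TRUE,
                       ctx = ctx)
  expect_gte(min(s$values), -1e-10)
  expect_lte(max(s$values), gmax + 1e-10)
})

test_that("observation times snap to nearest nodes and collisions are rejected", {
  m <- tiny_annulus()
  ctx <- fem_context(m)
  grid <- time_grid(1, 24)
  nb <- length(ctx$bvert)
  g <- boundary_control(matrix(0.1, nb, grid$k + 1), grid)
  s <- solve_diffusion(m, region_adc(GM = 0.5, WM = 0.4), g, grid, ctx = ctx)

  r <- restrict_to_observation_times(s, c(0, 24))
  expect_equal(r$times, c(0, 24))

  r2 <- restrict_to_observation_times(s, 2.1)
  expect_equal(r2$times, 2)
  expect_equal(attr(r2, "snap_log")$distance, 0.1)

  # 23.4 -> 23 and 23.6 -> 24 are distinct; on a longer grid 23.6 and 24.4
  # both snap to 24 and collide
  expect_silent(restrict_to_observation_times(s, c(23.4, 23.6)))
  g26 <- time_grid(1, 26)
  s26 <- solve_diffusion(m, region_adc(GM = 0.5, WM = 0.4),
                         boundary_control(matrix(0.1, nb, g26$k + 1), g26),
                         g26, ctx = ctx)
  expect_error(restrict_to_observation_times(s26, c(23.6, 24.4)),
               "same grid node")
  expect_error(restrict_to_observation_times(s, 25), "outside")
})

test_that("invalid solver inputs are rejected", {
  m <- tiny_annulus()
  ctx <- fem_context(m)
  grid <- time_grid(2, 24)
  expect_error(region_adc(GM = -1, WM = 0.4), "positive")
  expect_error(solve_diffusion(m, region_adc(GM = 0.5, WM = 0.4), NULL, grid,
                               ctx = ctx), "Dirichlet")
  g_bad <- matrix(0, 3, grid$k + 1)
  expect_error(solve_diffusion(m, region_adc(GM = 0.5, WM = 0.4), g_bad, grid,
                               ctx = ctx), "one row per")
})
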