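make_setup <- function(resolution = 8, k = 10) {
  m <- tiny_annulus(resolution)
  ctx <- fem_context(m)
  grid <- time_grid(24 / k, 24)
  D_true <- region_adc(GM = 0.468, WM = 0.396)
  gt <- generate_ground_truth(m, D_true, boundary_profile_spec(),
                              schedule = seq(0, 24, 4.8), grid, ctx = ctx)
  list(m = m, ctx = ctx, grid = grid, D_true = D_true, obs = gt$obs)
}

test_that("the facet-wise gamma field follows the red/blue scaling exactly", {
  m <- tiny_annulus()
  w <- gamma_field(1.0, m)
  expect_identical(sort(unique(w)), c(0.01, 1.0))
  expect_true(all(w[m$facet_tags == "RED_SAS"] == 1.0))
  expect_true(all(w[m$facet_tags == "BLUE_VENTRICLE"] == 0.01))
  expect_identical(gamma_field(0, m), rep(0, nrow(m$facets)))
  expect_identical(gamma_field(10, m), 10 * w)   # homogeneity
})

test_that("objective components have the exact analytic values and null spaces", {
  s <- make_setup()
  nb <- length(s$ctx$bvert)
  k <- s$grid$k

  # states equal to observations with g = 0 give an exactly zero objective
  g0 <- matrix(0, nb, k + 1)
  obs0 <- observation_series(s$grid$times,
                             matrix(0, s$ctx$nv, k + 1))
  o <- objective(s$m, s$D_true, g0, obs0, regularization_params(0, 0, 0),
                 s$grid, ctx = s$ctx)
  expect_identical(o$value, 0)

  # constant-in-space-and-time g: alpha term = (alpha/2) c^2 |boundary| T
  cc <- 0.8
  gc <- matrix(cc, nb, k + 1)
  alpha <- 0.123
  o2 <- objective(s$m, s$D_true, gc, s$obs,
                  regularization_params(alpha, 0, 0), s$grid, ctx = s$ctx)
  M_b <- boundary_measure(s$m, s$m$dirichlet_tags)
  expect_equal(unname(o2$components["alpha_term"]),
               alpha / 2 * cc^2 * M_b * 24, tolerance = 1e-12)
  # g constant in time: beta term exactly zero; constant per tagged patch:
  # gamma term zero to assembly rounding (boundary stiffness rows sum to
  # zero only up to floating-point cancellation)
  o3 <- objective(s$m, s$D_true, gc, s$obs,
                  regularization_params(0, 5, 3), s$grid, ctx = s$ctx)
  expect_identical(unname(o3$components["beta_term"]), 0)
  expect_lt(abs(unname(o3$components["gamma_term"])), 1e-12)

  # doubling alpha doubles its component and leaves the others unchanged
  o4 <- objective(s$m, s$D_true, gc, s$obs,
                  regularization_params(2 * alpha, 0, 0), s$grid, ctx = s$ctx)
  expect_equal(unname(o4$components["alpha_term"]),
               2 * unname(o2$components["alpha_term"]), tolerance = 1e-12)
  expect_equal(unname(o4$components["misfit"]),
               unname(o2$components["misfit"]), tolerance = 1e-12)

  # total equals the sum of components
  expect_equal(o2$value, sum(o2$components), tolerance = 1e-12)
  expect_true(all(o3$components >= -1e-12))
})

test_that("adjoint gradients pass the Taylor remainder test at order two", {
  s <- make_setup()
  set.seed(101)
  nb <- length(s$ctx$bvert)
  k <- s$grid$k
  reg <- regularization_params(1e-4, 1e-2, 0.5)
  g <- matrix(runif(nb * (k + 1)), nb, k + 1)
  g[, 1] <- s$obs$values[s$ctx$bvert, 1]
  D <- region_adc(GM = 0.3, WM = 0.5)
  for (th in c(1, 0.5)) {
    res <- gradient(s$m, D, g, s$obs, reg, s$grid, ctx = s$ctx, theta = th)
    dD <- c(GM = 0.05, WM = -0.03)
    dg <- matrix(rnorm(nb * k), nb, k)
    dirder <- sum(res$grad_D[names(dD)] * dD) + sum(res$grad_g * dg)
    hs <- 10^c(-2, -3, -4)
    rem <- vapply(hs, function(h) {
      D2 <- region_adc(GM = D[["GM"]] + h * dD[["GM"]],
                       WM = D[["WM"]] + h * dD[["WM"]])
      g2 <- g
      g2[, -1] <- g[, -1] + h * dg
      abs(objective(s$m, D2, g2, s$obs, reg, s$grid, ctx = s$ctx,
                    theta = th)$value - res$value - h * dirder)
    }, numeric(1))
    orders <- -diff(log10(rem))
    expect_true(all(orders > 1.8 & orders < 2.2))
  }
})

test_that("dJ/dD matches central finite differences on a coarse mesh", {
  s <- make_setup()
  set.seed(7)
  nb <- length(s$ctx$bvert)
  g <- matrix(runif(nb * (s$grid$k + 1)), nb, s$grid$k + 1)
  reg <- regularization_params(1e-4, 1e-2, 0)
  D <- region_adc(GM = 0.3, WM = 0.5)
  res <- gradient(s$m, D, g, s$obs, reg, s$grid, ctx = s$ctx)
  h <- 1e-5
  for (lb in c("GM", "WM")) {
    Dp <- D; Dp[[lb]] <- D[[lb]] + h
    Dm <- D; Dm[[lb]] <- D[[lb]] - h
    fd <- (objective(s$m, Dp, g, s$obs, reg, s$grid, ctx = s$ctx)$value -
             objective(s$m, Dm, g, s$obs, reg, s$grid, ctx = s$ctx)$value) /
      (2 * h)
    expect_lt(abs(fd - res$grad_D[[lb]]) / abs(fd), 1e-5)
  }
})

test_that("the gradient vanishes at an exact fit with zero regularization", {
  m <- tiny_annulus()
  ctx <- fem_context(m)
  grid <- time_grid(2.4, 24)
  D_true <- region_adc(GM = 0.468, WM = 0.396)
  obs <- crime_observations(m, D_true, grid, ctx)
  g_true <- glymadc:::.control_from_profile(m, boundary_profile_spec(), grid)
  res <- gradient(m, D_true, unclass(g_true), obs,
                  regularization_params(0, 0, 0), grid, ctx = ctx)
  expect_lt(max(abs(res$grad_D)), 1e-8)
  expect_lt(max(abs(res$grad_g)), 1e-8)
})

test_that("the estimator recovers the true ADC from self-consistent data", {
  m <- tiny_annulus(6)
  ctx <- fem_context(m)
  grid <- time_grid(2.4, 24)
  D_true <- region_adc(GM = 0.468, WM = 0.396)
  obs <- crime_observations(m, D_true, grid, ctx)
  fit <- estimate_adc(obs, m, regularization_params(1e-8, 1e-8, 0), grid,
                      opt_config = list(maxit = 800, factr = 1e3),
                      ctx = ctx, u0 = numeric(ctx$nv))
  err <- 100 * abs(fit$adc - unclass(D_true)[names(fit$adc)]) /
    unclass(D_true)[names(fit$adc)]
  expect_lt(max(err), 1)
  # accepted-iterate history is non-increasing by contract
  expect_true(all(diff(fit$objective_history) <= 0))
  expect_identical(names(fit$adc), c("GM", "WM"))
})

test_that("stronger alpha shrinks the control and stronger beta smooths it", {
  m <- tiny_annulus(8)
  ctx <- fem_context(m)
  grid <- time_grid(4.8, 24)
  D_true <- region_adc(GM = 0.468, WM = 0.396)
  obs <- crime_observations(m, D_true, grid, ctx)
  u0 <- numeric(ctx$nv)

  gnorm <- vapply(c(1e-4, 1e-1, 10), function(a) {
    fit <- estimate_adc(obs, m, regularization_params(a, 1e-4, 0), grid,
                        opt_config = list(maxit = 300), ctx = ctx, u0 = u0)
    sqrt(sum(unclass(fit$g_opt)^2))
  }, numeric(1))
  expect_true(all(diff(gnorm) < 0))

  tvar <- vapply(c(1e-3, 1, 100), function(b) {
    fit <- estimate_adc(obs, m, regularization_params(1e-6, b, 0), grid,
                        opt_config = list(maxit = 300), ctx = ctx, u0 = u0)
    g <- unclass(fit$g_opt)
    sum(abs(g[, -1] - g[, -ncol(g)]))
  }, numeric(1))
  expect_true(all(diff(tvar) < 0))
})

test_that("degenerate estimation inputs are rejected", {
  m <- tiny_annulus()
  ctx <- fem_context(m)
  grid <- time_grid(2.4, 24)
  obs0 <- observation_series(grid$times, matrix(0, ctx$nv, grid$k + 1))
  expect_error(
    estimate_adc(obs0, m, regularization_params(0, 0, 0), grid, ctx = ctx),
    "unidentifiable")
  expect_error(regularization_params(-1, 0, 0), "non-negative")
})
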