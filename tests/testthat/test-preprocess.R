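test_that("the signal model round-trips concentrations and is monotone", {
  n <- 12
  set.seed(3)
  c_true <- array(runif(n^3, 0, 1.5), c(n, n, n))
  T10 <- array(1400, c(n, n, n))
  t1map <- voxel_image(T10)
  TR <- 5.1; fa <- 8; r1 <- 5

  spgr <- glymadc:::.spgr_signal
  T1c <- 1 / (1 / T10 + r1 * c_true / 1000)     # relaxivity in 1/s -> 1/ms
  signal <- voxel_image(spgr(T1c, TR, fa))
  baseline <- voxel_image(spgr(T10, TR, fa))

  conc <- signal_to_concentration(signal, baseline, t1map,
                                  r1 = r1, TR = TR, flip_deg = fa)
  expect_identical(conc$units, "mM")
  expect_identical(attr(conc, "n_masked"), 0L)
  expect_lt(max(abs(conc$data - c_true)), 1e-6)

  # signal = baseline everywhere -> zero concentration
  conc0 <- signal_to_concentration(baseline, baseline, t1map,
                                   r1 = r1, TR = TR, flip_deg = fa)
  expect_lt(max(abs(conc0$data)), 1e-10)

  # concentration is monotone non-decreasing in signal ratio at fixed T1
  ratios <- seq(1, 1.6, by = 0.1)
  cs <- vapply(ratios, function(rt) {
    s <- voxel_image(array(rt * spgr(1400, TR, fa), c(2, 2, 2)))
    b <- voxel_image(array(spgr(1400, TR, fa), c(2, 2, 2)))
    signal_to_concentration(s, b, voxel_image(array(1400, c(2, 2, 2))),
                            r1 = r1, TR = TR, flip_deg = fa)$data[1]
  }, numeric(1))
  expect_true(all(diff(cs) >= 0))
})

test_that("trilinear sampling reproduces linear fields and rejects outside vertices", {
  img <- synth_image(15, spacing = 1, origin = -4,
                     f = function(x, y, z) 0.2 + 0.03 * x - 0.01 * y + 0.02 * z)
  m <- build_rectangle_mesh(5, 5, 5, 5)
  vals <- sample_to_mesh(img, m, mode = "trilinear")
  exact <- 0.2 + 0.03 * m$vertices[, 1] - 0.01 * m$vertices[, 2]
  expect_lt(max(abs(vals - exact)), 1e-10)

  # constant image -> constant field, both modes
  imgc <- synth_image(15, f = function(x, y, z) 0.7 + 0 * x)
  expect_identical(unique(sample_to_mesh(imgc, m, "nearest")), 0.7)
  expect_lt(max(abs(sample_to_mesh(imgc, m, "trilinear") - 0.7)), 1e-12)

  m_out <- m
  m_out$vertices[1, ] <- c(-10, -10)
  expect_error(sample_to_mesh(img, m_out), "outside")
})

test_that("CSF projection averages the labeled neighborhood and falls back safely", {
  n <- 15
  lab <- array(0L, c(n, n, n))
  img <- synth_image(n, f = function(x, y, z) 0.5 + 0 * x, labels = lab)
  m <- build_rectangle_mesh(5, 5, 5, 5,
                            dirichlet_tags = c("RED_SAS", "BLUE_VENTRICLE"))

  # all voxels CSF at 0.5 -> every Dirichlet vertex gets exactly 0.5
  img$labels[] <- 1L
  v <- csf_projection(img, m)
  expect_identical(unique(v), 0.5)

  # hand-built neighborhood: exactly three CSF voxels valued 0.1, 0.2, 0.3
  img2 <- synth_image(n, f = function(x, y, z) 9 + 0 * x,
                      labels = array(0L, c(n, n, n)))
  # vertex (0, 0, 0) maps to voxel index (4, 4, 4) (0-based)
  img2$data[5, 5, 5] <- 0.1; img2$labels[5, 5, 5] <- 1L
  img2$data[6, 5, 5] <- 0.2; img2$labels[6, 5, 5] <- 1L
  img2$data[5, 7, 5] <- 0.3; img2$labels[5, 7, 5] <- 1L
  bv <- dirichlet_vertices(m)
  corner <- which(rowSums(abs(m$vertices[bv, , drop = FALSE])) == 0)
  v2 <- suppressWarnings(csf_projection(img2, m))
  expect_equal(v2[corner], 0.2, tolerance = 1e-12)

  # zero CSF voxels anywhere: fallback to sampled values with a warning
  img3 <- synth_image(n, f = function(x, y, z) 0.9 + 0 * x,
                      labels = array(0L, c(n, n, n)))
  expect_warning(v3 <- csf_projection(img3, m), "no CSF voxel")
  expect_identical(unique(v3), 0.9)
  expect_length(attr(v3, "fallback_vertices"), length(bv))
})

test_that("Gaussian smoothing is exact on constants, normalized and kernel-correct", {
  imgc <- synth_image(15, f = function(x, y, z) 1.2 + 0 * x)
  sm <- gaussian_smooth(imgc, sigma_mm = 1.5)
  expect_lt(max(abs(sm$data - 1.2)), 1e-12)

  # unit spike far from the edges: center value = product of the three 1D
  # central weights; total sum preserved
  n <- 21
  spike <- array(0, c(n, n, n))
  spike[11, 11, 11] <- 1
  img <- voxel_image(spike)
  sm2 <- gaussian_smooth(img, sigma_mm = 1.5)
  k1 <- exp(-((-6:6)^2) / (2 * 1.5^2))
  k1 <- k1 / sum(k1)
  expect_equal(sm2$data[11, 11, 11], k1[7]^3, tolerance = 1e-12)
  expect_lt(abs(sum(sm2$data) - 1), 1e-6)
})

test_that("a synthetic image pipeline ends within 2% of the known field", {
  # known concentration -> signal -> inverted -> sampled to mesh
  spgr <- glymadc:::.spgr_signal
  f <- function(x, y, z) 0.3 + 0.05 * x + 0.02 * y
  cimg <- synth_image(15, f = f)
  T10 <- array(1400, c(15, 15, 15))
  sig <- voxel_image(spgr(1 / (1 / T10 + 5 * cimg$data / 1000), 5.1, 8),
                     affine = cimg$affine)
  base <- voxel_image(spgr(T10, 5.1, 8), affine = cimg$affine)
  conc <- signal_to_concentration(sig, base, voxel_image(T10))
  m <- build_rectangle_mesh(6, 6, 8, 8)
  vals <- sample_to_mesh(conc, m)
  exact <- f(m$vertices[, 1], m$vertices[, 2], 0)
  expect_lt(sqrt(sum((vals - exact)^2) / sum(exact^2)), 0.02)
})
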