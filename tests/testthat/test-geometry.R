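test_that("concentric geometries satisfy the labeling and tagging invariants", {
  m <- build_synthetic_geometry(2, c(50, 45, 35, 10), resolution = 2,
                                mode = "three_domain")
  # every cell labeled, labels partition the cells
  expect_length(m$cell_labels, nrow(m$cells))
  expect_true(all(m$cell_labels %in% c("CSF", "GM", "WM")))
  expect_setequal(unique(m$cell_labels), c("CSF", "GM", "WM"))
  # every exterior facet tagged, tags partition the exterior measure
  expect_length(m$facet_tags, nrow(m$facets))
  total <- boundary_measure(m)
  tagged <- boundary_measure(m, "RED_SAS") +
    boundary_measure(m, "BLUE_VENTRICLE")
  expect_lt(abs(tagged - total) / total, 1e-10)
  # Dirichlet facets only on the outermost CSF surface in three-domain mode
  expect_identical(m$dirichlet_tags, "RED_SAS")
  f <- m$facets
  r_cent <- sqrt(rowSums(((m$vertices[f[, 1], ] + m$vertices[f[, 2], ]) / 2)^2))
  expect_true(all(r_cent[m$facet_tags == "RED_SAS"] > 49))
  expect_true(all(r_cent[m$facet_tags == "BLUE_VENTRICLE"] < 11))
})

test_that("two-domain annulus areas match the analytic shell areas", {
  m <- build_synthetic_geometry(2, c(45, 35, 10), resolution = 2,
                                mode = "two_domain")
  expect_false(any(m$cell_labels == "CSF"))
  expect_lt(abs(subdomain_measure(m, "GM") - pi * (45^2 - 35^2)) /
              (pi * (45^2 - 35^2)), 0.02)
  expect_lt(abs(subdomain_measure(m, "WM") - pi * (35^2 - 10^2)) /
              (pi * (35^2 - 10^2)), 0.02)
  # both surfaces Dirichlet in two-domain mode; inner circle all BLUE
  expect_setequal(m$dirichlet_tags, c("RED_SAS", "BLUE_VENTRICLE"))
  expect_lt(abs(boundary_measure(m, "BLUE_VENTRICLE") - 2 * pi * 10) /
              (2 * pi * 10), 0.02)
})

test_that("refining the resolution moves shell measures toward the analytic value", {
  coarse <- build_synthetic_geometry(2, c(45, 35, 10), 4, "two_domain")
  fine <- build_synthetic_geometry(2, c(45, 35, 10), 2, "two_domain")
  exact <- pi * (45^2 - 35^2)
  expect_lt(abs(subdomain_measure(fine, "GM") - exact),
            abs(subdomain_measure(coarse, "GM") - exact))
})

test_that("degenerate and invalid geometry requests are rejected", {
  expect_error(build_synthetic_geometry(2, c(35, 45, 10), 2, "two_domain"),
               "decreasing")
  expect_error(build_synthetic_geometry(2, c(45, 35, 10), -1, "two_domain"),
               "positive")
  expect_error(build_synthetic_geometry(2, c(45, 35, 10), 2, "three_domain"),
               "4 radii")
  # in 2D the 16-sector angular floor keeps even coarse annuli above the
  # cell threshold; a very coarse 3D shell does trip the degeneracy guard
  expect_error(build_synthetic_geometry(3, c(20, 16, 12, 6), 25,
                                        "three_domain"),
               "degenerate")
})

test_that("3D shell meshes satisfy the same invariants", {
  m <- build_synthetic_geometry(3, c(20, 16, 12, 6), resolution = 3,
                                mode = "three_domain")
  expect_gte(nrow(m$cells), 50)
  expect_setequal(unique(m$cell_labels), c("CSF", "GM", "WM"))
  total <- boundary_measure(m)
  tagged <- boundary_measure(m, c("RED_SAS", "BLUE_VENTRICLE"))
  expect_lt(abs(tagged - total) / total, 1e-10)
  # cell volumes positive and sum close to the shell volume (staircase)
  vol <- sum(glymadc:::cell_measures(m))
  exact <- 4 / 3 * pi * (20^3 - 6^3)
  expect_lt(abs(vol - exact) / exact, 0.15)
})

test_that("MSH round trip preserves vertices, cells, labels and tags", {
  m <- tiny_annulus(6)
  path <- tempfile(fileext = ".msh")
  write_msh(m, path)
  m2 <- read_msh(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 0)
  expect_identical(unname(m2$cells), unname(m$cells))
  expect_identical(m2$cell_labels, m$cell_labels)
  expect_identical(unname(m2$facets), unname(m$facets))
  expect_identical(m2$facet_tags, m$facet_tags)
})
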