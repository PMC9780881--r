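test_that("standard scaffold has 24 carbonyls in 6 rings spanning ~1.5 nm", {
  g <- filter_geometry()
  expect_equal(nrow(g$carbons), 24)
  expect_equal(g$n_rings * g$n_strands, 24)
  expect_equal(length(unique(g$carbons[, "z"])), 6)
  ext <- diff(range(g$carbons[, "z"]))
  expect_lt(abs(ext - 1500) / 1500, 0.1)
})

test_that("scaffold is four-fold symmetric, also when staggered", {
  for (stag in c(FALSE, TRUE)) {
    g <- filter_geometry(stagger = stag)
    xy <- g$carbons
    rot <- cbind(-xy[, 2], xy[, 1], xy[, 3])
    ord <- function(m) m[order(round(m[, 3]), round(m[, 1], 6),
                               round(m[, 2], 6)), ]
    expect_equal(ord(rot), ord(xy), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("rest orientations point at the pore axis", {
  g <- filter_geometry()
  o <- g$carbons + 123 * g$rest_orientations
  expect_equal(sqrt(o[, 1]^2 + o[, 2]^2), rep(g$ring_radius - 123, 24))
  expect_equal(rowSums(g$rest_orientations^2), rep(1, 24))
})

test_that("building twice with the same parameters is bit-identical", {
  expect_identical(filter_geometry(length_fraction = 0.97),
                   filter_geometry(length_fraction = 0.97))
})

test_that("length scaling is linear in z about the midpoint, radius fixed", {
  g <- filter_geometry()
  s <- scale_filter_length(g, 0.92)
  expect_equal(s$carbons[, "z"], 0.92 * g$carbons[, "z"])
  expect_equal(s$carbons[, "x"], g$carbons[, "x"])
  expect_equal(s$ring_radius, g$ring_radius)
  expect_equal(s$rest_orientations, g$rest_orientations)
  # inter-ring spacing scales
  expect_equal(s$site_spacing, 0.92 * g$site_spacing)
  # identity and inverse composition
  expect_equal(scale_filter_length(g, 1), g)
  gg <- scale_filter_length(scale_filter_length(g, 1.10), 1 / 1.10)
  expect_equal(gg$carbons, g$carbons, tolerance = 1e-12)
})

test_that("sites are ordered cage centers with ~300 pm spacing", {
  g <- filter_geometry()
  sp <- site_positions(g)
  expect_equal(sp$site, c("S_cav", "S4", "S3", "S2", "S1", "S0"))
  expect_true(all(diff(sp$z_pm) > 0))
  expect_equal(diff(sp$z_pm), rep(300, 5))
  # cage centers sit midway between adjacent oxygen rings
  zr <- sort(unique(g$carbons[, "z"]))
  expect_equal(sp$z_pm[2:6], (head(zr, -1) + tail(zr, -1)) / 2)
  # S_cav lies below the lowest ring
  expect_lt(sp$z_pm[1], min(zr))
  # spacing scales with the geometry
  s10 <- site_positions(scale_filter_length(g, 1.10))
  expect_equal(diff(s10$z_pm), rep(330, 5))
})

test_that("parameter errors are raised for nonsense geometry", {
  expect_error(filter_geometry(ring_radius = -1), "ring_radius")
  expect_error(filter_geometry(ring_spacing = 0), "ring_spacing")
  expect_error(filter_geometry(length_fraction = 0.3), "length_fraction")
  g <- filter_geometry()
  expect_error(scale_filter_length(g, 2.5), "fraction")
  expect_error(scale_filter_length(g, 0.4), "fraction")
})
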