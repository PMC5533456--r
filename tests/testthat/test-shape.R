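ngon <- function(r, k = 64) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(r * cos(th), r * sin(th))
}

test_that("cylinder volume matches the closed form", {
  z <- seq(0, 1, length.out = 11)
  st <- polygon_stack_of_revolution("cyl", "apical", function(z) 1, z,
                                    k = 512)
  m <- measure_stack(st)
  expect_equal(m$volume_um3, pi, tolerance = 1e-4)
  expect_equal(m$max_circumference_um, 2 * pi, tolerance = 1e-4)
})

test_that("single-slice stacks use the nominal interval", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  m <- measure_stack(contour_stack("sq", "apical", 0, list(sq)))
  expect_equal(m$volume_um3, 0.27)
  expect_equal(m$max_circumference_um, 4)
  expect_equal(m$height_um, 0.27)
  m2 <- measure_stack(contour_stack("sq", "apical", 0, list(sq)),
                      height = "extent")
  expect_equal(m2$height_um, 0)
})

test_that("height is z extent plus one interval by default", {
  sq <- matrix(c(0, 0, 2, 0, 2, 2, 0, 2), ncol = 2, byrow = TRUE)
  st <- contour_stack("h", "basolateral", seq(0, 4.7, by = 0.47),
                      rep(list(sq), 11))
  m <- measure_stack(st)
  expect_equal(m$height_um, 4.7 + 0.47)
  expect_equal(measure_stack(st, height = "extent")$height_um, 4.7)
})

test_that("cone volume is within 0.1% of the closed form and the voxel oracle", {
  r0 <- 1; h <- 1
  z <- seq(0, h, length.out = 101)
  cone <- polygon_stack_of_revolution("cone", "apical",
                                      function(z) r0 * (1 - z / h), z,
                                      k = 256)
  v <- measure_stack(cone)$volume_um3
  v_closed <- pi * r0^2 * h / 3
  expect_lt(abs(v - v_closed) / v_closed, 0.001)
  v_voxel <- oracle_voxel_volume(function(z) r0 * (1 - z / h), 0, h, r0,
                                 g = 0.004)
  expect_lt(abs(v - v_voxel) / v_voxel, 0.001)
})

test_that("hemisphere volume converges to the voxel oracle with slice count", {
  r0 <- 1
  r_of_z <- function(z) sqrt(pmax(r0^2 - z^2, 0))
  v_closed <- 2 / 3 * pi * r0^3
  errs <- sapply(c(11, 31, 101), function(n) {
    z <- seq(0, r0 * 0.9999, length.out = n)
    st <- polygon_stack_of_revolution("hemi", "basolateral", r_of_z, z,
                                      k = 256)
    abs(measure_stack(st)$volume_um3 - v_closed) / v_closed
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.001)
  v_voxel <- oracle_voxel_volume(r_of_z, 0, r0, r0, g = 0.004)
  z <- seq(0, r0 * 0.9999, length.out = 101)
  st <- polygon_stack_of_revolution("hemi", "basolateral", r_of_z, z, k = 256)
  expect_lt(abs(measure_stack(st)$volume_um3 - v_voxel) / v_voxel, 0.001)
})

test_that("volume is rigid-invariant and scales cubically", {
  set.seed(17)
  poly <- ngon(1) * runif(64, 0.9, 1.1)
  z <- seq(0, 2, by = 0.27)
  st <- contour_stack("c", "apical", z, rep(list(poly), length(z)))
  v <- measure_stack(st)$volume_um3
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- contour_stack("c", "apical", z,
                         rep(list(sweep(poly %*% R, 2, c(-3, 8))), length(z)))
  expect_equal(measure_stack(moved)$volume_um3, v)
  c3 <- 1.7
  scaled <- contour_stack("c", "apical", z * c3,
                          rep(list(poly * c3), length(z)))
  expect_equal(measure_stack(scaled)$volume_um3, c3^3 * v)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(contour_stack("bad", "apical", 0,
                             list(matrix(c(0, 0, 1, 1), 2))), "degenerate")
  bowtie <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(contour_stack("bad", "apical", 0, list(bowtie)),
               "self-intersecting")
  expect_error(contour_stack("bad", "apical", c(0, 0),
                             rep(list(ngon(1)), 2)), "strictly increasing")
})

test_that("volume ratios report 100% for identical groups and split by domain", {
  gen <- generate_contour_stacks(synth_config(seed = 14), 4, 4)
  meas <- measure_stacks(gen$stacks)
  self_ratio <- volume_ratio(meas, meas)
  expect_equal(self_ratio$ratio_percent, c(100, 100))
  isf <- grepl("^fold_", meas$cell_id)
  vr <- volume_ratio(meas[isf, ], meas[!isf, ])
  expect_equal(vr$ratio_percent[vr$domain == "apical"], 20, tolerance = 1e-9)
  expect_equal(vr$ratio_percent[vr$domain == "basolateral"], 50,
               tolerance = 1e-9)
  expect_error(volume_ratio(meas[0, ], meas), "non-empty")
})

test_that("positive fractions are simple ratios with validation", {
  expect_equal(positive_fraction(55, 100), 0.55)
  expect_equal(positive_fraction(0, 8), 0)
  expect_equal(positive_fraction(8, 8), 1)
  expect_error(positive_fraction(9, 8), "0..n_total")
  expect_error(positive_fraction(1, 0), ">= 1")
})

test_that("group comparisons route to the appropriate test families", {
  # literally identical groups: t statistic 0, p = 1
  x <- c(rnorm(50, 10, 1))
  same <- group_compare(c(x, x), rep(c("a", "b"), each = 50), "two-sample")
  expect_gt(same$p_value, 0.9)
  # 3-sd shift at n = 20 is highly significant
  set.seed(23)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 3, 1)
  shift <- group_compare(c(a, b), rep(c("a", "b"), each = 20), "two-sample")
  expect_lt(shift$p_value, 0.001)
  # one-vs-control on 3 groups gives exactly 2 adjusted p-values
  g3 <- data.frame(v = rnorm(30), g = rep(c("ctrl", "kd1", "kd2"), each = 10))
  dn <- group_compare(g3$v, g3$g, "one-vs-control", control = "ctrl")
  expect_equal(nrow(dn), 2)
  # all-pairs on 3 groups gives 3 comparisons
  tk <- group_compare(g3$v, g3$g, "all-pairs")
  expect_equal(nrow(tk), 3)
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), ">= 2 observations")
})
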