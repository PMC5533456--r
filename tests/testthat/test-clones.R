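straight_fold <- function() fold_line(cbind(c(0, 0), c(-10, 10)))

test_that("side calls follow the signed distance to the polyline", {
  f <- straight_fold()  # segment pointing +y: left of it is x < 0
  expect_equal(side_of_fold(c(-3, 0), f), "A-side")
  expect_equal(side_of_fold(c(3, 0), f), "B-side")
  expect_equal(side_of_fold(c(0, 0), f), "on-line")
  expect_equal(side_of_fold(c(0.1, 0), f), "on-line")  # inside 0.25 um tol
  expect_equal(signed_distance(c(-3, 0), f), 3)
})

test_that("closed folds call inside as A-side", {
  ring <- fold_line(cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)), closed = TRUE)
  expect_equal(side_of_fold(c(0, 0), ring), "A-side")
  expect_equal(side_of_fold(c(9, 0), ring), "B-side")
  expect_equal(signed_distance(c(0, 0), ring), 5)
  expect_equal(signed_distance(c(9, 0), ring), -4)
})

test_that("signed distance agrees with a brute-force nearest-segment oracle", {
  set.seed(11)
  x <- seq(-40, 40, by = 10)
  f <- fold_line(cbind(x, 8 * sin(x / 25)))
  pts <- cbind(runif(1000, -50, 50), runif(1000, -30, 30))
  got <- signed_distance(pts, f)
  want <- apply(pts, 1, oracle_signed_distance, vertices = f$vertices)
  expect_equal(got, want)
})

test_that("fold validation rejects degenerate and self-intersecting polylines", {
  expect_error(fold_line(matrix(1:2, ncol = 2)), ">= 2 rows")
  expect_error(fold_line(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))),
               "self-intersect")
})

test_that("clone scoring is restricted only when strictly one-sided", {
  f <- straight_fold()
  one_sided <- clone("a", "m-L2", data.frame(x = runif(10, -8, -2),
                                             y = runif(10, -5, 5)))
  expect_equal(score_clone(one_sided, f), "restricted")
  mixed <- clone("b", "m-L2", data.frame(x = c(runif(9, -8, -2), 3),
                                         y = runif(10, -5, 5)))
  expect_equal(score_clone(mixed, f), "crossed")
  single <- clone("c", "e-L3", data.frame(x = 4, y = 0))
  expect_equal(score_clone(single, f), "restricted")
  ambiguous <- clone("d", "e-L3", data.frame(x = c(-3, 0.05), y = c(0, 0)))
  expect_error(score_clone(ambiguous, f), "ambiguous")
})

test_that("clone calls are invariant to cell order and rigid motion", {
  set.seed(3)
  gen <- generate_clones(synth_config(seed = 3), "l-L2", 12, 5)
  rot <- function(m, th, shift) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sweep(m %*% t(R), 2, -shift)
  }
  th <- 0.7; shift <- c(12, -5)
  fold_r <- fold_line(rot(gen$fold$vertices, th, shift))
  for (cl in gen$clones) {
    base <- score_clone(cl, gen$fold)
    perm <- clone(cl$clone_id, cl$stage,
                  cl$cells[sample(nrow(cl$cells)), ])
    expect_equal(score_clone(perm, gen$fold), base)
    moved <- clone(cl$clone_id, cl$stage, {
      m <- rot(as.matrix(cl$cells[, c("x", "y")]), th, shift)
      data.frame(x = m[, 1], y = m[, 2])
    })
    expect_equal(score_clone(moved, fold_r), base)
  }
})

test_that("restriction fractions reproduce the printed stage percentages", {
  mk <- function(k, n) c(rep("restricted", k), rep("crossed", n - k))
  expect_equal(restriction_fraction(mk(1, 34))$percent, 2.94)
  expect_equal(restriction_fraction(mk(7, 37))$percent, 18.92)
  expect_equal(restriction_fraction(mk(30, 35))$percent, 85.71)
  expect_equal(restriction_fraction(mk(0, 12))$percent, 0)
  expect_error(restriction_fraction(character(0)), "no clones")
})

test_that("restriction fraction is monotone in flipping crossed to restricted", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    calls <- sample(c("restricted", "crossed"), n, replace = TRUE)
    base <- restriction_fraction(calls)$percent
    j <- which(calls == "crossed")
    if (length(j)) {
      calls[j[1]] <- "restricted"
      expect_gte(restriction_fraction(calls)$percent, base)
    }
  }
})

test_that("penetrance and pooled rates match the printed worked fractions", {
  expect_equal(penetrance(21, 22)$percent, 95.5)
  expect_equal(penetrance(21, 22)$fraction, "21/22")
  expect_equal(penetrance(24, 24)$percent, 100.0)
  expect_equal(penetrance(0, 5)$percent, 0.0)
  expect_equal(pooled_rate(c(7, 13), c(108, 202)), 6)
  expect_equal(pooled_rate(c(0, 0), c(10, 10)), 0)
  expect_equal(pooled_rate(5, 10), 50)
})

test_that("half-up rounding drives the printed precision conventions", {
  expect_equal(round_half_up(2.945, 2), 2.95)
  expect_equal(round_half_up(95.45, 1), 95.5)
  expect_equal(round_half_up(6.5, 0), 7)
  expect_equal(round_half_up(-2.5, 0), -3)
})

test_that("mixing calls require a side labeling and detect misplaced cells", {
  f <- straight_fold()  # Dll field on A-side (x < 0)
  ok <- data.frame(x = c(-5, -4, 4, 5), y = 0,
                   label = c("Dll", "Dll", "Lim1", "Lim1"))
  expect_false(mixing_call(ok, f, dll_side = "A-side"))
  mixed <- rbind(ok, data.frame(x = -3, y = 1, label = "Lim1"))
  expect_true(mixing_call(mixed, f, dll_side = "A-side"))
  expect_error(mixing_call(ok, f), "fold side")
  expect_error(mixing_call(ok[0, ], f, dll_side = "A-side"), "empty disc")
})
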