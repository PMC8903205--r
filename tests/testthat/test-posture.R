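cfg <- vp_config()

test_that("strain balance is zero at rest and hits the calibration anchors", {
  expect_equal(compute_strain(activation_state(), cfg), 0, tolerance = 1e-8)
  eps_ct <- compute_strain(activation_state(aCT = 1), cfg)
  expect_equal(eps_ct, 0.1875, tolerance = 1e-6)
  expect_equal(cfg$L0_cm * (1 + eps_ct), 1.9, tolerance = 1e-4)
  eps_ta <- compute_strain(activation_state(aTA = 1), cfg)
  expect_equal(eps_ta, -0.375, tolerance = 1e-6)
  expect_equal(cfg$L0_cm * (1 + eps_ta), 1.0, tolerance = 1e-4)
})

test_that("strain balance signals when the bracket excludes the root", {
  tight <- vp_config(eps_bracket = c(-0.05, 0.05))
  expect_error(compute_strain(activation_state(aCT = 1), tight),
               "no root in bracket")
})

test_that("strain is monotone in CT (up) and TA (down) over an 11x11 grid", {
  lv <- seq(0, 1, by = 0.1)
  eps <- outer(lv, lv, Vectorize(function(ct, ta)
    compute_strain(activation_state(aCT = ct, aTA = ta), cfg)))
  # rows: aCT varies; columns: aTA varies
  expect_true(all(apply(eps, 2, diff) > 0))
  expect_true(all(apply(eps, 1, diff) < 0))
  expect_true(all(eps >= -0.5 & eps <= 0.5))
})

test_that("fold length rises with CT with saturating increments, falls with TA", {
  lv <- seq(0, 1, by = 0.25)
  L_ct <- vapply(lv, function(ct)
    cfg$L0_cm * (1 + compute_strain(activation_state(aCT = ct), cfg)),
    numeric(1))
  expect_true(all(diff(L_ct) > 0))
  expect_true(all(diff(diff(L_ct)) < 0))   # sub-linear growth
  L_ta <- vapply(lv, function(ta)
    cfg$L0_cm * (1 + compute_strain(activation_state(aTA = ta), cfg)),
    numeric(1))
  expect_true(all(diff(L_ta) < 0))
})

test_that("posturing rules reproduce the empirical formulas exactly", {
  g1 <- apply_posture_rules(0, 1, 0.05, cfg)
  expect_equal(g1$L, 1.6)
  expect_equal(g1$T, 0.7)
  expect_equal(g1$xi01, 0.05)   # max(0, .) zeroed at full TA
  expect_equal(g1$xib, 0)

  g2 <- apply_posture_rules(0, 0, 0.05, cfg)
  expect_equal(g2$xi01, 0.12)
  expect_equal(g2$xib, 0.035)

  g3 <- apply_posture_rules(0.1875, 0, 0.05, cfg)
  expect_equal(g3$L, 1.9)
  expect_equal(g3$T, 0.7 / 1.1875)
  expect_error(apply_posture_rules(-1, 0, 0.05, cfg), "strain")
})

test_that("length-thickness product is invariant (isovolume)", {
  for (eps in seq(-0.4, 0.4, by = 0.1)) {
    g <- apply_posture_rules(eps, 0.3, 0.04, cfg)
    expect_equal(g$L * g$T, cfg$L0_cm * cfg$T0_cm, tolerance = 1e-12)
  }
})

test_that("adduction rule: rest width, near-closure, monotone decrease", {
  expect_equal(compute_adduction(activation_state(), cfg), cfg$xi02_rest_cm)
  full <- compute_adduction(activation_state(aLC = 1, aIA = 1), cfg)
  expect_lt(full, 0.005)
  expect_gte(full, 0)
  lv <- seq(0, 1, by = 0.1)
  x_lc <- vapply(lv, function(a)
    compute_adduction(activation_state(aLC = a, aIA = a), cfg), numeric(1))
  expect_true(all(diff(x_lc) < 0))
  x_ta <- vapply(lv, function(a)
    compute_adduction(activation_state(aTA = a), cfg), numeric(1))
  expect_true(all(diff(x_ta) <= 0))
})

test_that("adduction lands in (0, 0.05] cm over the constraint-rule range", {
  g <- sweep_grid(5)
  xi <- vapply(seq_len(nrow(g)), function(i)
    compute_adduction(grid_activation(g$aCT_pct[i], g$aTA_pct[i]), cfg),
    numeric(1))
  expect_true(all(xi > 0))
  expect_true(all(xi <= 0.05))
})

test_that("medial surface matches the half-width formula pointwise", {
  geom <- apply_posture_rules(0, 0, 0.05, cfg)  # xi01=0.12, xib=0.035
  # zero width at the far end for every z
  far <- medial_surface(geom, geom$L, seq(0, geom$T, length.out = 7))
  expect_true(all(abs(far$xi0) < 1e-14))
  # end-point values at y = 0
  expect_equal(medial_surface(geom, 0, geom$T)$xi0, geom$xi02)
  expect_equal(medial_surface(geom, 0, 0)$xi0, geom$xi01)
  # direct substitution mid-surface (bracket term vanishes at z = T/2)
  expect_equal(medial_surface(geom, 0.8, 0.35)$xi0, 0.025)
  expect_error(medial_surface(geom, -0.1, 0), "y samples")
  expect_error(medial_surface(geom, 0, geom$T + 1), "z samples")
})

test_that("half-width field is affine in y and quadratic in z", {
  geom <- compute_posture(grid_activation(35, 15), cfg)
  ys <- seq(0, geom$L, length.out = 9)
  zs <- seq(0, geom$T, length.out = 9)
  grid <- medial_surface(geom, ys, zs)
  m <- matrix(grid$xi0, nrow = length(ys), byrow = TRUE)
  # second differences vanish along y (affine)
  expect_true(all(abs(apply(m, 2, function(col) diff(diff(col)))) < 1e-12))
  # third differences vanish along z (quadratic)
  d3 <- apply(m, 1, function(row) diff(diff(diff(row))))
  expect_true(all(abs(d3) < 1e-12))
  # max over z at y = 0 sits at a boundary or the parabola vertex
  f <- function(z) medial_surface(geom, 0, z)$xi0
  zfine <- seq(0, geom$T, length.out = 401)
  zmax <- zfine[which.max(f(zfine))]
  a <- geom$xi01 - geom$xi02
  b <- 4 * geom$xib
  z_vertex <- geom$T * (a + b) / (2 * b)  # stationary point of the quadratic
  expect_true(min(abs(zmax - c(0, geom$T, z_vertex))) < geom$T / 200)
})

test_that("activation state validates its inputs", {
  expect_error(activation_state(aCT = 1.2), "aCT")
  expect_error(activation_state(PL = -1), "PL")
  expect_silent(activation_state(aCT = 1, aTA = 0, PL = 4.3))
})
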