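cfg <- vp_config()
act <- grid_activation(20, 20)
geom <- compute_posture(act, cfg)
mesh <- build_mesh(geom, cfg)

test_that("mesh has the prescribed slice, node and element counts", {
  expect_equal(mesh$n_slices, 15L)
  expect_equal(mesh$nodes_per_slice, 77L)
  expect_equal(nrow(mesh$nodes), 15L * 77L)
  expect_equal(nrow(mesh$elements), 15L * 120L)
  expect_equal(sum(mesh$elements$slice == 8), 120L)
  expect_error(build_mesh(structure(list(L = 1.6, T = -1, xi01 = 0, xi02 = 0,
                                         xib = 0, epsilon = 0),
                                    class = "postural_geometry"), cfg),
               "degenerate")
})

test_that("medial column sits on the half-width surface, zero at the far end", {
  med <- mesh$nodes[mesh$nodes$j == 0, ]
  expect_equal(med$x,
               xi0_eval(med$y, med$z, geom), tolerance = 1e-12)
  far <- med[med$slice == 15, ]
  expect_true(all(abs(far$x) < 1e-12))
})

test_that("anterior, posterior and lateral boundaries are fixed; surfaces free", {
  nd <- mesh$nodes
  expect_true(all(nd$fixed[nd$j == 10]))
  expect_true(all(nd$fixed[nd$slice %in% c(1, 15)]))
  inner <- nd[nd$slice %in% 2:14 & nd$j < 10, ]
  expect_false(any(inner$fixed))
})

test_that("element layers partition the columns 1/2/7 medially to laterally", {
  el1 <- mesh$elements[mesh$elements$slice == 1, ]
  counts <- table(el1$layer)
  expect_equal(unname(counts[c("SLLP", "LIG", "TA")]),
               c(1, 2, 7) * 2 * 6, ignore_attr = TRUE)
})

test_that("rest state with no load stays in static equilibrium", {
  fsys <- fold_system(act, cfg)
  ndof <- length(fsys$sys$M)
  run <- simulate_fold(fsys, duration_s = 0.005, aero = FALSE,
                       v0 = numeric(ndof))
  expect_equal(max(abs(run$u)), 0)
})

test_that("undamped free vibration conserves the discrete energy", {
  cfg0 <- vp_config(eta = 0)
  fsys <- fold_system(grid_activation(20, 20), cfg0)
  expect_equal(fsys$sys$beta, 0)
  expect_equal(fsys$sys$damp_a, 0)
  run <- simulate_fold(fsys, duration_s = 1000 / cfg0$fs, aero = FALSE,
                       track_energy = TRUE)
  E <- run$energy
  expect_gt(E[2], 0)
  expect_lt((max(E) - min(E)) / E[2], 0.01)
})

test_that("with zero fiber stiffness the slices decouple completely", {
  cfg0 <- vp_config(fiber_fraction = 0)
  fsys <- fold_system(grid_activation(20, 20), cfg0)
  ndof <- length(fsys$sys$M)
  u0 <- numeric(ndof)
  sl8 <- fsys$mesh$nodes$id[fsys$mesh$nodes$slice == 8 &
                              !fsys$mesh$nodes$fixed]
  u0[2 * sl8 - 1] <- 1e-4
  run <- simulate_fold(fsys, duration_s = 0.01, aero = FALSE, u0 = u0,
                       v0 = numeric(ndof))
  others <- fsys$mesh$nodes$id[fsys$mesh$nodes$slice != 8]
  moved <- c(run$u[2 * others - 1], run$u[2 * others])
  expect_equal(max(abs(moved)), 0)
  inslice <- run$u[2 * sl8 - 1]
  expect_gt(max(abs(inslice)), 0)
})

test_that("doubling the gel modulus scales modal frequencies by sqrt(2)", {
  tis <- tissue_state(geom$epsilon, act$aTA, cfg)
  s1 <- assemble_system(mesh, tis, cfg, mu = cfg$mu, include_strings = FALSE)
  s2 <- assemble_system(mesh, tis, cfg, mu = 2 * cfg$mu, include_strings = FALSE)
  # single clamped slice: free dofs of slice 8
  nd8 <- mesh$nodes$id[mesh$nodes$slice == 8 & !mesh$nodes$fixed]
  dofs <- sort(c(2 * nd8 - 1, 2 * nd8))
  m <- s1$M[dofs]
  A1 <- as.matrix(s1$K[dofs, dofs]) / sqrt(outer(m, m))
  A2 <- as.matrix(s2$K[dofs, dofs]) / sqrt(outer(m, m))
  w1 <- sqrt(sort(eigen(A1, symmetric = TRUE, only.values = TRUE)$values)[1:5])
  w2 <- sqrt(sort(eigen(A2, symmetric = TRUE, only.values = TRUE)$values)[1:5])
  expect_equal(w2 / w1, rep(sqrt(2), 5), tolerance = 1e-9)
})

test_that("glottal area tracker matches a mirrored trapezoid oracle", {
  set.seed(7)
  for (i in 1:10) {
    a <- grid_activation(sample(0:100, 1), sample(0:100, 1))
    fsys <- fold_system(a, cfg)
    run <- simulate_fold(fsys, duration_s = 2 / cfg$fs, aero = FALSE,
                         v0 = numeric(length(fsys$sys$M)))
    w <- fsys$xi0_med                             # slices x rows, at rest
    w[w < 0] <- 0
    wgt <- rep(1, nrow(w)); wgt[c(1, nrow(w))] <- 0.5
    a_rows <- 2 * colSums(w * wgt) * fsys$mesh$dy  # left fold mirrors right
    expect_equal(run$series$ag[1], min(a_rows), tolerance = 1e-12)
  }
})

test_that("constant sub-threshold pressure converges to the static deflection", {
  fsys <- fold_system(act, cfg)
  ndof <- length(fsys$sys$M)
  pr <- rep(500, 7)   # dyn/cm^2 on every medial row
  run <- simulate_fold(fsys, duration_s = 0.25, aero = FALSE,
                       p_rows_const = pr, v0 = numeric(ndof))
  Fv <- numeric(ndof)
  for (k in 1:7) for (s in 1:15) {
    nd <- fsys$med_ids[s, k]
    Fv[2 * nd - 1] <- Fv[2 * nd - 1] + pr[k] * fsys$med_area[s, k]
  }
  free <- fsys$sys$free
  u_static <- numeric(ndof)
  u_static[free] <- as.numeric(Matrix::solve(fsys$sys$K[free, free], Fv[free]))
  expect_lt(max(abs(run$u - u_static)), 1e-6 * max(abs(u_static)))
  # settled: no residual oscillation in the glottal area
  expect_lt(diff(range(utils::tail(run$series$ag, 2000))), 1e-10)
})
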