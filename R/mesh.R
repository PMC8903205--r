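#' Build the layered finite-element fold mesh
#'
#' Discretizes the right vocal fold into coronal slices along the fold
#' axis, each slice a structured grid of cells split into two linear
#' triangles. The medial column of nodes lies on the prephonatory
#' half-width surface; the lateral boundary sits at the configured fold
#' depth (and is therefore curved in z wherever the medial surface is).
#' Anterior, posterior (the two end slices) and lateral boundaries are
#' fixed; medial, inferior and superior surfaces are pressure-loaded.
#' Cell columns are assigned to layers medially to laterally: SLLP,
#' ligament, muscle (defaults 1/2/7 columns).
#'
#' @param geom a `postural_geometry` from [compute_posture()].
#' @param cfg a [vp_config()].
#' @return a `fold_mesh` list: `nodes` (tibble: id, slice, j, k, y, x, z,
#'   fixed, layer), `elements` (tibble: slice, n1, n2, n3, layer, area),
#'   slice positions `y`, slice spacing `dy`, the rest half-width matrix
#'   `xi0` (slices x z-rows), and the generating geometry.
#' @export
build_mesh <- function(geom, cfg = vp_config()) {
  stopifnot(inherits(geom, "postural_geometry"))
  if (geom$T <= 0 || geom$L <= 0) stop("build_mesh: degenerate geometry")
  M <- cfg$n_slices; nc <- cfg$n_cols; nr <- cfg$n_rows
  y <- seq(0, geom$L, length.out = M)
  dy <- geom$L / (M - 1)
  zk <- seq(0, geom$T, length.out = nr + 1)
  D <- cfg$depth_cm

  # rest half-width at each (slice, z-row)
  xi0 <- outer(y, zk, function(yy, zz) xi0_eval(yy, zz, geom))

  jj <- rep(0:nc, times = nr + 1)
  kk <- rep(0:nr, each = nc + 1)
  npsl <- (nc + 1) * (nr + 1)
  nodes <- purrr::map_dfr(seq_len(M), function(i) {
    xm <- xi0[i, kk + 1]
    tibble::tibble(
      id = (i - 1L) * npsl + kk * (nc + 1L) + jj + 1L,
      slice = i, j = jj, k = kk, y = y[i],
      x = xm + (jj / nc) * (D - xm),
      z = zk[kk + 1],
      fixed = jj == nc | i == 1L | i == M
    )
  })
  # node layer (for fiber tension): layer of the adjoining cell column
  col_layer <- rep(names(cfg$layer_cols), times = cfg$layer_cols)
  nodes$layer <- col_layer[pmin(nodes$j + 1L, nc)]

  # elements: two triangles per cell, counter-clockwise
  cj <- rep(0:(nc - 1), times = nr)
  ck <- rep(0:(nr - 1), each = nc)
  n00 <- ck * (nc + 1L) + cj + 1L
  n10 <- n00 + 1L
  n01 <- n00 + (nc + 1L)
  n11 <- n01 + 1L
  elements <- purrr::map_dfr(seq_len(M), function(i) {
    off <- (i - 1L) * npsl
    tibble::tibble(
      slice = i,
      n1 = off + c(n00, n00),
      n2 = off + c(n10, n11),
      n3 = off + c(n11, n01),
      layer = rep(col_layer[cj + 1L], 2L)
    )
  })
  x <- nodes$x; z <- nodes$z
  elements$area <- 0.5 * abs(
    (x[elements$n2] - x[elements$n1]) * (z[elements$n3] - z[elements$n1]) -
      (x[elements$n3] - x[elements$n1]) * (z[elements$n2] - z[elements$n1]))
  if (any(elements$area <= 0)) stop("build_mesh: degenerate element")

  structure(list(nodes = nodes, elements = elements, y = y, dy = dy,
                 zk = zk, xi0 = xi0, geom = geom,
                 n_slices = M, n_cols = nc, n_rows = nr,
                 nodes_per_slice = npsl, depth = D),
            class = "fold_mesh")
}

#' @export
print.fold_mesh <- function(x, ...) {
  cat(sprintf("<fold_mesh> %d slices x %d nodes (%d elements each), L=%.3f T=%.3f cm\n",
              x$n_slices, x$nodes_per_slice, nrow(x$elements) / x$n_slices,
              x$geom$L, x$geom$T))
  invisible(x)
}

# plane-strain elasticity matrix for a nearly incompressible gel:
# lambda implemented as a penalty multiple of mu
elastic_matrix <- function(mu, penalty) {
  lam <- penalty * mu
  matrix(c(lam + 2 * mu, lam, 0,
           lam, lam + 2 * mu, 0,
           0, 0, mu), 3, 3, byrow = TRUE)
}

#' Assemble stiffness, damping and mass operators for the fold mesh
#'
#' In-plane elasticity of each slice comes from the gel: linear-triangle
#' plane-strain stiffness with shear modulus `mu` and a penalty bulk term
#' enforcing near-incompressibility. Damping is Kelvin-Voigt
#' (C = (eta/mu) K, the gel viscosity acting through the same operator).
#' Fiber tension couples corresponding nodes of adjacent slices through
#' linear strings whose transverse stiffness is mu_prime times the
#' node's fiber cross-section over the slice spacing. Masses are lumped
#' from the tissue density.
#'
#' @param mesh a `fold_mesh`.
#' @param tissue a tibble from [tissue_state()] (per-layer `mu_prime`).
#' @param cfg a [vp_config()].
#' @param mu gel shear modulus override, dyn/cm^2.
#' @param include_strings logical; include the inter-slice fiber strings.
#' @return list with sparse symmetric `K` (2 dofs/node, x then z),
#'   Kelvin-Voigt factor `beta` (s), lumped mass vector `M` (g), the free
#'   dof mask, and the per-node fiber areas used for the strings.
#' @export
assemble_system <- function(mesh, tissue, cfg = vp_config(), mu = cfg$mu,
                            include_strings = TRUE) {
  stopifnot(inherits(mesh, "fold_mesh"))
  nd <- nrow(mesh$nodes)
  ndof <- 2L * nd
  Dm <- elastic_matrix(mu, cfg$poisson_penalty)
  el <- mesh$elements
  x <- mesh$nodes$x; z <- mesh$nodes$z

  # vectorized CST: geometric coefficients per element
  b1 <- z[el$n2] - z[el$n3]; b2 <- z[el$n3] - z[el$n1]; b3 <- z[el$n1] - z[el$n2]
  c1 <- x[el$n3] - x[el$n2]; c2 <- x[el$n1] - x[el$n3]; c3 <- x[el$n2] - x[el$n1]
  A <- el$area
  t <- mesh$dy   # slice thickness
  bmat <- cbind(b1, b2, b3); cmat <- cbind(c1, c2, c3)
  nods <- cbind(el$n1, el$n2, el$n3)

  ne <- nrow(el)
  ii <- integer(0); jjv <- integer(0); xv <- numeric(0)
  # 6x6 element stiffness assembled blockwise over node pairs (p, q)
  for (p in 1:3) for (q in 1:3) {
    bp <- bmat[, p]; cp <- cmat[, p]; bq <- bmat[, q]; cq <- cmat[, q]
    f <- t / (4 * A)
    kxx <- f * (Dm[1, 1] * bp * bq + Dm[3, 3] * cp * cq)
    kxz <- f * (Dm[1, 2] * bp * cq + Dm[3, 3] * cp * bq)
    kzx <- f * (Dm[1, 2] * cp * bq + Dm[3, 3] * bp * cq)
    kzz <- f * (Dm[1, 1] * cp * cq + Dm[3, 3] * bp * bq)
    dp <- 2L * nods[, p] - 1L; dq <- 2L * nods[, q] - 1L
    ii <- c(ii, dp, dp, dp + 1L, dp + 1L)
    jjv <- c(jjv, dq, dq + 1L, dq, dq + 1L)
    xv <- c(xv, kxx, kxz, kzx, kzz)
  }

  # inter-slice fiber strings
  fib_area <- node_fiber_areas(mesh, cfg)
  if (include_strings) {
    mup <- stats::setNames(tissue$mu_prime, tissue$layer)
    npsl <- mesh$nodes_per_slice
    lay1 <- mesh$nodes$layer[seq_len(npsl)]
    ks_node <- mup[lay1] * fib_area / mesh$dy    # dyn/cm per string
    for (i in seq_len(mesh$n_slices - 1L)) {
      na <- (i - 1L) * npsl + seq_len(npsl)
      nb <- na + npsl
      for (d in 0:1) {
        da <- 2L * na - 1L + d; db <- 2L * nb - 1L + d
        ii <- c(ii, da, db, da, db)
        jjv <- c(jjv, da, db, db, da)
        xv <- c(xv, ks_node, ks_node, -ks_node, -ks_node)
      }
    }
  }

  K <- Matrix::sparseMatrix(i = ii, j = jjv, x = xv, dims = c(ndof, ndof))
  K <- Matrix::drop0((K + Matrix::t(K)) / 2)

  # lumped mass
  Mv <- numeric(nd)
  mnode <- cfg$rho_tissue * t * A / 3
  for (p in 1:3) {
    tab <- tapply(mnode, nods[, p], sum)
    idx <- as.integer(names(tab))
    Mv[idx] <- Mv[idx] + as.numeric(tab)
  }
  Mdof <- rep(Mv, each = 2L)

  free <- rep(!mesh$nodes$fixed, each = 2L)

  # Rayleigh damping from the gel viscosity: the physical Kelvin-Voigt
  # factor is eta/mu, but stiffness-proportional damping of the highest
  # penalty modes is unstable under explicit integration at fs, so the
  # stiffness part is capped at the stable level and the remainder is
  # carried by a mass-proportional term matched at the reference frequency
  beta_phys <- cfg$eta / mu
  dt <- 1 / cfg$fs
  w2 <- max_eigen_ratio(K, Mdof, free)
  beta <- min(beta_phys, 0.5 / (w2 * dt))
  w_ref <- (2 * pi * cfg$damp_ref_hz)^2
  damp_a <- max(0, (beta_phys - beta) * w_ref)

  list(K = K, M = Mdof, beta = beta, damp_a = damp_a, free = free,
       fib_area = fib_area, mu = mu, omega_max = sqrt(w2))
}

# largest eigenvalue of M^-1 K on the free dofs (power iteration);
# used for the damping stability cap
max_eigen_ratio <- function(K, Mdof, free, iters = 50) {
  x <- rep(1, nrow(K)) * rep_len(c(1, -0.5, 0.25), nrow(K))
  x[!free] <- 0
  lam <- 0
  for (i in seq_len(iters)) {
    y <- as.numeric(K %*% x) / Mdof
    y[!free] <- 0
    lam <- sqrt(sum(y^2)) / sqrt(sum(x^2))
    x <- y / sqrt(sum(y^2))
  }
  lam
}

# per-node fiber cross-section area (cm^2): tributary rectangle in the
# coronal plane, halved on edge columns/rows
node_fiber_areas <- function(mesh, cfg) {
  nc <- mesh$n_cols; nr <- mesh$n_rows
  npsl <- mesh$nodes_per_slice
  nd1 <- mesh$nodes[seq_len(npsl), ]
  wx <- (mesh$depth - mean(mesh$xi0)) / nc
  wz <- mesh$geom$T / nr
  fx <- ifelse(nd1$j %in% c(0L, nc), 0.5, 1)
  fz <- ifelse(nd1$k %in% c(0L, nr), 0.5, 1)
  cfg$fiber_fraction * wx * wz * fx * fz
}
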