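# 3D Taylor-Hood mechanics: mesh construction, residual/tangent
# consistency, Newton solutions vs the closed-form uniaxial oracle,
# objectivity.

mp <- default_mp

test_that("structured mesh counts and volume", {
  m8 <- build_cube_mesh(2, 2, 2, L = 2)
  expect_equal(m8$n_elems, 8L)
  expect_equal(m8$n_nodes, 125L)           # (2*2+1)^3
  expect_equal(m8$n_pnodes, 27L)           # (2+1)^3
  expect_equal(mesh_volume(m8), 8, tolerance = 1e-12)
  m1 <- build_cube_mesh(1, 1, 1, L = 2)
  expect_equal(m1$n_elems, 1L)
  expect_equal(m1$n_nodes, 27L)
  expect_equal(m1$n_pnodes, 8L)
  expect_equal(nrow(m1$quad$xi), 27L)      # 3x3x3 Gauss points
  expect_equal(sum(m1$elem_quad[[1]]$wdetJ), 8, tolerance = 1e-12)
})

test_that("reference state with the stress-free pressure has zero residual", {
  mesh <- build_cube_mesh(1, 1, 1, L = 2)
  u0 <- matrix(0, mesh$n_nodes, 3)
  p0 <- rep(2 * mp$c10 + 4 * mp$c01, mesh$n_pnodes)
  sys <- assemble_system(mesh, u0, p0, mp)
  expect_lt(max(abs(sys$residual)), 1e-10)
})

test_that("residual is translation invariant", {
  mesh <- build_cube_mesh(1, 1, 1, L = 2)
  set.seed(3)
  u <- 0.02 * matrix(rnorm(mesh$n_nodes * 3), ncol = 3)
  p <- rep(2 * mp$c10 + 4 * mp$c01, mesh$n_pnodes) + runif(mesh$n_pnodes)
  r1 <- assemble_system(mesh, u, p, mp)$residual
  shift <- matrix(rep(c(0.3, -0.1, 0.2), each = mesh$n_nodes), ncol = 3)
  r2 <- assemble_system(mesh, u + shift, p, mp)$residual
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("assembled tangent matches a central-difference directional derivative", {
  mesh <- build_cube_mesh(1, 1, 1, L = 1)
  set.seed(5)
  u <- 0.01 * matrix(rnorm(mesh$n_nodes * 3), ncol = 3)
  p <- rep(2 * mp$c10 + 4 * mp$c01, mesh$n_pnodes) + 0.1 * rnorm(mesh$n_pnodes)
  sys <- assemble_system(mesh, u, p, mp, tangent = TRUE)
  ndof <- 3 * mesh$n_nodes + mesh$n_pnodes
  dz <- rnorm(ndof); dz <- dz / sqrt(sum(dz^2))
  h <- 1e-5
  du <- matrix(dz[1:(3 * mesh$n_nodes)], mesh$n_nodes, 3, byrow = TRUE)
  dp <- dz[(3 * mesh$n_nodes + 1):ndof]
  rp <- assemble_system(mesh, u + h * du, p + h * dp, mp)$residual
  rm2 <- assemble_system(mesh, u - h * du, p - h * dp, mp)$residual
  dir_fd <- (rp - rm2) / (2 * h)
  dir_an <- drop(sys$tangent %*% dz)
  expect_lt(max(abs(dir_fd - dir_an)) / max(abs(dir_fd)), 1e-5)
})

test_that("zero boundary motion gives the zero solution", {
  mesh <- build_cube_mesh(1, 1, 1, L = 2)
  sol <- newton_solve(mesh, bc_uniaxial(mesh, 0), mp)
  expect_equal(sol$u, matrix(0, mesh$n_nodes, 3))
  expect_equal(sol$iterations, 0L)
})

test_that("20% uniaxial stretch is homogeneous with lambda_f = 1.2 at all GPs", {
  mesh <- build_cube_mesh(1, 1, 1, L = 2)
  sol <- newton_solve(mesh, bc_uniaxial(mesh, 0.4), mp)
  kin <- gauss_point_kinematics(mesh, sol$u)
  expect_equal(as.vector(kin$lambda_f), rep(1.2, 27), tolerance = 1e-9)
  expect_lt(max(abs(kin$J - 1)), 1e-6)
})

test_that("affine imposed displacement reproduces F exactly at every GP", {
  mesh <- build_cube_mesh(2, 1, 1, L = c(2, 1, 1))
  A <- matrix(c(1.1, 0.05, 0, 0.02, 0.95, 0.01, 0, 0.03, 1.04), 3, 3)
  u <- mesh$nodes %*% t(A) - mesh$nodes
  kin <- gauss_point_kinematics(mesh, u)
  expect_equal(as.vector(kin$J), rep(det(A), length(kin$J)),
               tolerance = 1e-12)
  Fgp <- matrix(kin$F[1, ], 27, 9)
  expect_equal(unname(Fgp[13, ]), as.vector(A), tolerance = 1e-12)
})

test_that("FE passive uniaxial response matches the closed-form oracle", {
  mesh1 <- build_cube_mesh(1, 1, 1, L = 2)
  u0 <- NULL; p0 <- NULL
  for (lam in c(0.9, 1.0, 1.1, 1.2, 1.3)) {
    sol <- newton_solve(mesh1, bc_uniaxial(mesh1, (lam - 1) * 2), mp,
                        u0 = u0, p0 = p0)
    u0 <- sol$u; p0 <- sol$p
    P_fe <- endface_nominal_stress(mesh1, sol$reactions)
    P_or <- uniaxial_oracle(lam, 0, 0, mp)
    if (lam == 1.0) expect_lt(abs(P_fe - P_or), 1e-8)
    else expect_equal(P_fe, P_or, tolerance = 1e-4)
  }
})

test_that("single- and 8-element meshes agree on the homogeneous state", {
  mesh8 <- build_cube_mesh(2, 2, 2, L = 2)
  u0 <- NULL; p0 <- NULL
  for (d in c(0.2, 0.4)) {
    sol8 <- newton_solve(mesh8, bc_uniaxial(mesh8, d), mp, u0 = u0, p0 = p0)
    u0 <- sol8$u; p0 <- sol8$p
  }
  P8 <- endface_nominal_stress(mesh8, sol8$reactions)
  expect_equal(P8, uniaxial_oracle(1.2, 0, 0, mp), tolerance = 1e-4)
  kin <- gauss_point_kinematics(mesh8, sol8$u)
  expect_lt(diff(range(kin$lambda_f)), 1e-6)
  expect_equal(mean(kin$lambda_f), 1.2, tolerance = 1e-6)
})

test_that("active FE response matches the oracle with uniform activation", {
  mesh <- build_cube_mesh(1, 1, 1, L = 2)
  pas <- newton_solve(mesh, bc_uniaxial(mesh, 0.4), mp)
  act <- newton_solve(mesh, bc_uniaxial(mesh, 0.4), mp, gamma_gp = 1,
                      u0 = pas$u, p0 = pas$p)
  P_fe <- endface_nominal_stress(mesh, act$reactions)
  expect_equal(P_fe, uniaxial_oracle(1.2, 1, 0, mp), tolerance = 1e-4)
  expect_equal(P_fe - endface_nominal_stress(mesh, pas$reactions), 73,
               tolerance = 1e-3)           # Pmax on top of the passive part
})

test_that("uniaxial oracle closed-form checkpoints", {
  expect_equal(uniaxial_oracle(1, 0, 0, mp), 0)
  expect_equal(uniaxial_oracle(1.1, 0, 0, mp), 1.806, tolerance = 1e-3)
  expect_equal(uniaxial_oracle(1.2, 1, 0, mp),
               uniaxial_oracle(1.2, 0, 0, mp) + 73)
  # derivative check against numerical differentiation of the energy
  W1d <- function(l) {
    I1 <- l^2 + 2 / l; I2 <- 1 / l^2 + 2 * l
    w <- mp$c10 * (I1 - 3) + mp$c01 * (I2 - 3)
    if (l > 1) w <- w + mp$b1 / mp$d1 * (l^mp$d1 - 1) - mp$b1 * log(l)
    w
  }
  for (lam in c(0.92, 1.07, 1.24)) {
    h <- 1e-6
    expect_equal(uniaxial_oracle(lam, 0, 0, mp),
                 (W1d(lam + h) - W1d(lam - h)) / (2 * h), tolerance = 1e-6)
  }
})

test_that("mesh objectivity: rotating the setup rotates the solution", {
  # axis permutation rotation: solve the same uniaxial protocol along y
  mesh_x <- build_cube_mesh(1, 1, 1, L = 2, fiber_dir = c(1, 0, 0))
  mesh_y <- build_cube_mesh(1, 1, 1, L = 2, fiber_dir = c(0, 1, 0))
  sol_x <- newton_solve(mesh_x, bc_uniaxial(mesh_x, 0.4, axis = 1), mp,
                        gamma_gp = 0.5)
  sol_y <- newton_solve(mesh_y, bc_uniaxial(mesh_y, 0.4, axis = 2), mp,
                        gamma_gp = 0.5)
  P_x <- endface_nominal_stress(mesh_x, sol_x$reactions, axis = 1)
  P_y <- endface_nominal_stress(mesh_y, sol_y$reactions, axis = 2)
  expect_equal(P_x, P_y, tolerance = 1e-8)
  kx <- gauss_point_kinematics(mesh_x, sol_x$u)
  ky <- gauss_point_kinematics(mesh_y, sol_y$u)
  expect_equal(sort(as.vector(kx$lambda_f)), sort(as.vector(ky$lambda_f)),
               tolerance = 1e-8)
  expect_equal(sort(as.vector(kx$J)), sort(as.vector(ky$J)),
               tolerance = 1e-8)
})

test_that("element inversion and divergence raise informative errors", {
  mesh <- build_cube_mesh(1, 1, 1, L = 1)
  u_bad <- matrix(0, mesh$n_nodes, 3)
  u_bad[, 1] <- -1.2 * mesh$nodes[, 1]      # folds the element
  expect_error(gauss_point_kinematics(mesh, u_bad), "inversion")
  expect_error(newton_solve(mesh, bc_uniaxial(mesh, 0.4), mp, max_iter = 1),
               "divergence")
})
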