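# Quasi-static incompressible finite elasticity on Taylor-Hood hexahedra.
# Total-Lagrangian weak form: find (u, p) with
#   int_O0  P(F, p, gamma) : Grad(du) dV = 0,   P = F S,
#   int_O0  (J - 1) dp dV = 0,
# S from the transversely isotropic constitutive model (pk2_total). No
# inertia or body forces. The consistent tangent is assembled per element
# by forward differences of the analytic residual.

# Element residual, fully vectorized over the 27 Gauss points.
# Ue: 27x3 nodal displacements, pe: 8 nodal pressures.
# Returns c(f_u (81), f_p (8)) and J range via attribute.
elem_residual <- function(Ue, pe, eq, N1, a0, mp, gamma_g) {
  dU1 <- eq$Gx %*% Ue; dU2 <- eq$Gy %*% Ue; dU3 <- eq$Gz %*% Ue
  F11 <- 1 + dU1[, 1]; F21 <- dU1[, 2]; F31 <- dU1[, 3]
  F12 <- dU2[, 1]; F22 <- 1 + dU2[, 2]; F32 <- dU2[, 3]
  F13 <- dU3[, 1]; F23 <- dU3[, 2]; F33 <- 1 + dU3[, 3]
  Jd <- F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
        F13 * (F21 * F32 - F22 * F31)
  if (any(Jd <= 0)) stop("element inversion: non-positive J at a Gauss point")
  C11 <- F11^2 + F21^2 + F31^2
  C22 <- F12^2 + F22^2 + F32^2
  C33 <- F13^2 + F23^2 + F33^2
  C12 <- F11 * F12 + F21 * F22 + F31 * F32
  C13 <- F11 * F13 + F21 * F23 + F31 * F33
  C23 <- F12 * F13 + F22 * F23 + F32 * F33
  I1 <- C11 + C22 + C33
  lf2 <- a0[1]^2 * C11 + a0[2]^2 * C22 + a0[3]^2 * C33 +
    2 * (a0[1] * a0[2] * C12 + a0[1] * a0[3] * C13 + a0[2] * a0[3] * C23)
  lf <- sqrt(lf2)
  detC <- Jd^2
  # inverse of C (symmetric), componentwise
  Ci11 <- (C22 * C33 - C23^2) / detC
  Ci22 <- (C11 * C33 - C13^2) / detC
  Ci33 <- (C11 * C22 - C12^2) / detC
  Ci12 <- (C13 * C23 - C12 * C33) / detC
  Ci13 <- (C12 * C23 - C13 * C22) / detC
  Ci23 <- (C12 * C13 - C11 * C23) / detC
  p_g <- drop(N1 %*% pe)
  # fiber (passive tension-only + active) stress coefficient on a0 x a0
  coefA <- ifelse(lf > 1, mp$b1 * (lf^(mp$d1 - 2) - lf^(-2)), 0) +
    mp$Pmax * force_length(lf, mp$lambda_opt) * gamma_g / lf
  c10_2 <- 2 * mp$c10; c01_2 <- 2 * mp$c01
  S11 <- c10_2 + c01_2 * (I1 - C11) + coefA * a0[1]^2 - p_g * Ci11
  S22 <- c10_2 + c01_2 * (I1 - C22) + coefA * a0[2]^2 - p_g * Ci22
  S33 <- c10_2 + c01_2 * (I1 - C33) + coefA * a0[3]^2 - p_g * Ci33
  S12 <- -c01_2 * C12 + coefA * a0[1] * a0[2] - p_g * Ci12
  S13 <- -c01_2 * C13 + coefA * a0[1] * a0[3] - p_g * Ci13
  S23 <- -c01_2 * C23 + coefA * a0[2] * a0[3] - p_g * Ci23
  # P = F S (first Piola-Kirchhoff), componentwise over Gauss points
  P11 <- F11 * S11 + F12 * S12 + F13 * S13
  P12 <- F11 * S12 + F12 * S22 + F13 * S23
  P13 <- F11 * S13 + F12 * S23 + F13 * S33
  P21 <- F21 * S11 + F22 * S12 + F23 * S13
  P22 <- F21 * S12 + F22 * S22 + F23 * S23
  P23 <- F21 * S13 + F22 * S23 + F23 * S33
  P31 <- F31 * S11 + F32 * S12 + F33 * S13
  P32 <- F31 * S12 + F32 * S22 + F33 * S23
  P33 <- F31 * S13 + F32 * S23 + F33 * S33
  w <- eq$wdetJ
  fu <- crossprod(eq$Gx, w * cbind(P11, P21, P31)) +
        crossprod(eq$Gy, w * cbind(P12, P22, P32)) +
        crossprod(eq$Gz, w * cbind(P13, P23, P33))
  fp <- drop(crossprod(N1, w * (Jd - 1)))
  out <- c(as.vector(t(fu)), fp)   # interleave u dofs as (node1 xyz, ...)
  attr(out, "Jrange") <- range(Jd)
  out
}

elem_dof_indices <- function(mesh, e) {
  gn <- mesh$elems[e, ]
  udof <- as.vector(rbind(3 * gn - 2, 3 * gn - 1, 3 * gn))
  pdof <- 3 * mesh$n_nodes + mesh$pelems[e, ]
  c(udof, pdof)
}

#' Assemble the global residual (and optionally the consistent tangent)
#'
#' Weak-form residual of the momentum balance `div T = 0` (no inertia, no
#' body forces) and of the incompressibility constraint
#' `int (J - 1) dp dV = 0` on the current displacement and pressure fields.
#' The tangent is built per element by forward differences of the analytic
#' residual.
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param u displacement field, `n_nodes x 3` (cm).
#' @param p pressure field, length `n_pnodes` (kPa).
#' @param mp a [material_params()] record.
#' @param gamma_gp homogenized activation per Gauss point
#'   (`n_elems x 27` matrix or scalar; 0 for passive problems).
#' @param tangent also assemble the consistent tangent matrix.
#' @param fd_h forward-difference step for the tangent.
#' @return List with `residual` (length `3 n_nodes + n_pnodes`) and, if
#'   requested, dense `tangent`.
#' @export
assemble_system <- function(mesh, u, p, mp, gamma_gp = 0, tangent = FALSE,
                            fd_h = 1e-7) {
  ndof <- 3 * mesh$n_nodes + mesh$n_pnodes
  R <- numeric(ndof)
  Kt <- if (tangent) matrix(0, ndof, ndof) else NULL
  if (!is.matrix(gamma_gp))
    gamma_gp <- matrix(gamma_gp, mesh$n_elems, 27)
  for (e in seq_len(mesh$n_elems)) {
    gn <- mesh$elems[e, ]
    Ue <- u[gn, , drop = FALSE]
    pe <- p[mesh$pelems[e, ]]
    eq <- mesh$elem_quad[[e]]
    re <- elem_residual(Ue, pe, eq, mesh$quad$N1, mesh$a0, mp, gamma_gp[e, ])
    idx <- elem_dof_indices(mesh, e)
    R[idx] <- R[idx] + re
    if (tangent) {
      Ke <- matrix(0, 89, 89)
      ze <- c(as.vector(t(Ue)), pe)
      for (d in 1:89) {
        zp <- ze
        zp[d] <- zp[d] + fd_h
        Up <- matrix(zp[1:81], 27, 3, byrow = TRUE)
        rp <- elem_residual(Up, zp[82:89], eq, mesh$quad$N1, mesh$a0, mp,
                            gamma_gp[e, ])
        Ke[, d] <- (rp - re) / fd_h
      }
      Kt[idx, idx] <- Kt[idx, idx] + Ke
    }
  }
  list(residual = R, tangent = Kt)
}

#' Dirichlet boundary conditions
#'
#' Builds a boundary-condition set as parallel vectors of global dof
#' indices and prescribed values.
#'
#' @param nodes integer node indices.
#' @param comp component 1, 2, or 3 (x, y, z).
#' @param value prescribed displacement (cm), recycled.
#' @return A `data.frame` with columns `dof` and `value`.
#' @export
dirichlet_bc <- function(nodes, comp, value) {
  data.frame(dof = 3 * (nodes - 1) + comp,
             value = rep_len(value, length(nodes)))
}

#' Uniaxial stretch protocol boundary conditions
#'
#' The experiment boundary conditions used throughout: axial displacement
#' prescribed on both end faces (zero on the near face, `delta` on the far
#' face), transverse faces traction-free, and rigid-body modes removed by
#' minimal edge constraints compatible with the homogeneous solution (both
#' transverse components pinned on the edge at the transverse origin, plus
#' one component on a second edge to block rotation about the axis).
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param delta prescribed axial end-face displacement (cm).
#' @param axis loading axis (1, 2, or 3).
#' @return A boundary-condition `data.frame` (see [dirichlet_bc()]).
#' @export
bc_uniaxial <- function(mesh, delta, axis = 1) {
  ax <- c("x", "y", "z")[axis]
  t1 <- setdiff(1:3, axis)[1]
  t2 <- setdiff(1:3, axis)[2]
  tol <- 1e-9
  edge00 <- which(abs(mesh$nodes[, t1]) < tol & abs(mesh$nodes[, t2]) < tol)
  edge10 <- which(abs(mesh$nodes[, t1] - mesh$L[t1]) < tol &
                  abs(mesh$nodes[, t2]) < tol)
  rbind(
    dirichlet_bc(face_nodes(mesh, paste0(ax, "0")), axis, 0),
    dirichlet_bc(face_nodes(mesh, paste0(ax, "1")), axis, delta),
    dirichlet_bc(edge00, t1, 0),
    dirichlet_bc(edge00, t2, 0),
    dirichlet_bc(edge10, t2, 0))
}

#' Newton solver for the quasi-static mechanics problem
#'
#' Solves the incompressible finite-elasticity system for one protocol
#' step: applies the Dirichlet data, iterates Newton steps with a
#' backtracking line search (factor 0.5) on the free dofs, and checks
#' incompressibility (`J` at every Gauss point) at convergence.
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param bc boundary conditions from [bc_uniaxial()] / [dirichlet_bc()].
#' @param mp a [material_params()] record.
#' @param gamma_gp homogenized activation per Gauss point (matrix
#'   `n_elems x 27` or scalar).
#' @param u0,p0 initial guesses (default: reference state with the
#'   stress-free pressure `2 c10 + 4 c01`).
#' @param tol relative residual tolerance.
#' @param atol absolute residual floor (kPa cm^2).
#' @param max_iter Newton iteration cap.
#' @param check_J warn if `max |J - 1|` at the Gauss points exceeds this
#'   (homogeneous states satisfy it pointwise; Taylor-Hood enforces the
#'   constraint only weakly for inhomogeneous states). `NA` disables.
#' @return List with `u`, `p`, `iterations`, `residual_norm`, `Jrange`,
#'   and `reactions` (the residual at constrained dofs, i.e. nodal
#'   reaction forces in kPa cm^2).
#' @export
newton_solve <- function(mesh, bc, mp, gamma_gp = 0, u0 = NULL, p0 = NULL,
                         tol = 1e-8, atol = 1e-10, max_iter = 20,
                         check_J = 1e-6) {
  nN <- mesh$n_nodes
  ndof <- 3 * nN + mesh$n_pnodes
  u <- if (is.null(u0)) matrix(0, nN, 3) else u0
  p <- if (is.null(p0)) rep(2 * mp$c10 + 4 * mp$c01, mesh$n_pnodes) else p0
  z <- c(as.vector(t(u)), p)
  z[bc$dof] <- bc$value
  free <- setdiff(seq_len(ndof), bc$dof)
  unpack <- function(z) list(u = matrix(z[1:(3 * nN)], nN, 3, byrow = TRUE),
                             p = z[(3 * nN + 1):ndof])
  st <- unpack(z)
  sys <- assemble_system(mesh, st$u, st$p, mp, gamma_gp)
  rn <- sqrt(sum(sys$residual[free]^2))
  r0 <- max(rn, atol)
  it <- 0L
  while (rn > max(atol, tol * r0) && it < max_iter) {
    it <- it + 1L
    sys <- assemble_system(mesh, st$u, st$p, mp, gamma_gp, tangent = TRUE)
    dz <- numeric(ndof)
    dz[free] <- solve(sys$tangent[free, free, drop = FALSE],
                      -sys$residual[free])
    lam <- 1
    repeat {
      zn <- z + lam * dz
      stn <- unpack(zn)
      rn_new <- tryCatch(
        sqrt(sum(assemble_system(mesh, stn$u, stn$p, mp,
                                 gamma_gp)$residual[free]^2)),
        error = function(e) Inf)   # element inversion -> damp further
      if (rn_new < rn || lam <= 1 / 256) break
      lam <- lam / 2
    }
    if (!is.finite(rn_new))
      stop("nonlinear divergence: line search failed (residual ", rn, ")")
    z <- zn; st <- stn; rn <- rn_new
  }
  if (rn > max(atol, tol * r0))
    stop("nonlinear divergence: no convergence in ", max_iter,
         " iterations (last residual ", format(rn), ")")
  full <- assemble_system(mesh, st$u, st$p, mp, gamma_gp)
  kin <- gauss_point_kinematics(mesh, st$u)
  Jrange <- range(kin$J)
  if (is.finite(check_J) && max(abs(kin$J - 1)) > check_J)
    warning("incompressibility: max |J-1| at Gauss points = ",
            format(max(abs(kin$J - 1))))
  reactions <- full$residual
  reactions[free] <- 0
  list(u = st$u, p = st$p, iterations = it, residual_norm = rn,
       Jrange = Jrange, reactions = reactions)
}

#' Per-Gauss-point kinematics of a displacement field
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param u displacement field `n_nodes x 3`.
#' @return List of `n_elems x 27` matrices: `J`, `lambda_f`, and the nine
#'   deformation-gradient components `F11 ... F33` (column-major names).
#' @export
gauss_point_kinematics <- function(mesh, u) {
  nE <- mesh$n_elems
  out <- list(J = matrix(0, nE, 27), lambda_f = matrix(0, nE, 27))
  Fc <- matrix(0, nE, 27 * 9)
  a0 <- mesh$a0
  for (e in seq_len(nE)) {
    eq <- mesh$elem_quad[[e]]
    Ue <- u[mesh$elems[e, ], , drop = FALSE]
    dU1 <- eq$Gx %*% Ue; dU2 <- eq$Gy %*% Ue; dU3 <- eq$Gz %*% Ue
    F11 <- 1 + dU1[, 1]; F21 <- dU1[, 2]; F31 <- dU1[, 3]
    F12 <- dU2[, 1]; F22 <- 1 + dU2[, 2]; F32 <- dU2[, 3]
    F13 <- dU3[, 1]; F23 <- dU3[, 2]; F33 <- 1 + dU3[, 3]
    Jd <- F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
          F13 * (F21 * F32 - F22 * F31)
    if (any(Jd <= 0)) stop("element inversion: non-positive J at a Gauss point")
    lf2 <-
      (a0[1] * F11 + a0[2] * F12 + a0[3] * F13)^2 +
      (a0[1] * F21 + a0[2] * F22 + a0[3] * F23)^2 +
      (a0[1] * F31 + a0[2] * F32 + a0[3] * F33)^2
    out$J[e, ] <- Jd
    out$lambda_f[e, ] <- sqrt(lf2)
    Fc[e, ] <- c(F11, F21, F31, F12, F22, F32, F13, F23, F33)
  }
  out$F <- Fc
  out
}

#' Closed-form uniaxial oracle
#'
#' Nominal (first Piola-Kirchhoff) stress of the incompressible uniaxial
#' state `lambda1 = lambda`, `lambda2 = lambda3 = lambda^(-1/2)` loaded
#' along the fiber, obtained as the derivative of the constrained strain
#' energy:
#' `P(lambda) = c10 (2 lambda - 2 lambda^-2) + c01 (2 - 2 lambda^-3)
#'  + [lambda > 1] b1 (lambda^(d1-1) - lambda^-1)
#'  + Pmax f_l(lambda) gamma_bar vf(u)`.
#' Used as an independent verification target for the finite-element
#' solution.
#'
#' @param lambda axial stretch (> 0); vectorized.
#' @param gamma_bar normalized crossbridge activation in `[0, 1]`.
#' @param u normalized shortening speed in `[0, 1]`.
#' @param mp a [material_params()] record.
#' @return Nominal stress (kPa).
#' @export
uniaxial_oracle <- function(lambda, gamma_bar = 0, u = 0,
                            mp = material_params()) {
  stopifnot(all(lambda > 0))
  P <- mp$c10 * (2 * lambda - 2 * lambda^-2) +
       mp$c01 * (2 - 2 * lambda^-3) +
       ifelse(lambda > 1, mp$b1 * (lambda^(mp$d1 - 1) - lambda^-1), 0)
  P + mp$Pmax * force_length(lambda, mp$lambda_opt) * gamma_bar *
    velocity_factor(u, mp)
}

#' End-face nominal stress from reactions
#'
#' Sums the axial nodal reactions on the far end face and divides by the
#' reference cross-section area.
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param reactions reaction vector from [newton_solve()].
#' @param axis loading axis.
#' @return Nominal stress (kPa).
#' @export
endface_nominal_stress <- function(mesh, reactions, axis = 1) {
  ax <- c("x", "y", "z")[axis]
  nodes <- face_nodes(mesh, paste0(ax, "1"))
  force <- sum(reactions[3 * (nodes - 1) + axis])
  area <- prod(mesh$L[setdiff(1:3, axis)])
  force / area
}
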