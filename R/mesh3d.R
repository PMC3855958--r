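# Taylor-Hood (triquadratic displacement / trilinear pressure) structured
# hexahedral meshes with 3x3x3 Gauss quadrature. Local coordinates live in
# [0,1]^3; node and Gauss-point orderings are lexicographic with the first
# axis fastest.

quad_shape_1d <- function(x) {
  cbind((2 * x - 1) * (x - 1), 4 * x * (1 - x), x * (2 * x - 1))
}
quad_dshape_1d <- function(x) {
  cbind(4 * x - 3, 4 - 8 * x, 4 * x - 1)
}
lin_shape_1d <- function(x) cbind(1 - x, x)

#' 3x3x3 Gauss rule and Taylor-Hood basis tables on the unit cube
#'
#' @return List with Gauss coordinates `xi` (27 x 3), weights `w` (27),
#'   triquadratic values `N2` (27 gp x 27 nodes), derivatives `dN` (list of
#'   three 27 x 27 matrices, one per local direction), and trilinear values
#'   `N1` (27 gp x 8 nodes).
#' @keywords internal
gauss_tables <- function() {
  g1 <- 0.5 + 0.5 * c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  w1 <- c(5, 8, 5) / 18
  gp <- as.matrix(expand.grid(x = g1, y = g1, z = g1))
  w <- apply(as.matrix(expand.grid(w1, w1, w1)), 1, prod)
  tensor27 <- function(a, b, c) {
    # a,b,c: 27gp x 3 one-dimensional tables -> 27gp x 27node
    out <- matrix(0, nrow(a), 27)
    for (k in 0:2) for (j in 0:2) for (i in 0:2)
      out[, 1 + i + 3 * j + 9 * k] <- a[, i + 1] * b[, j + 1] * c[, k + 1]
    out
  }
  qx <- quad_shape_1d(gp[, 1]); qy <- quad_shape_1d(gp[, 2])
  qz <- quad_shape_1d(gp[, 3])
  dqx <- quad_dshape_1d(gp[, 1]); dqy <- quad_dshape_1d(gp[, 2])
  dqz <- quad_dshape_1d(gp[, 3])
  N2 <- tensor27(qx, qy, qz)
  dN <- list(tensor27(dqx, qy, qz), tensor27(qx, dqy, qz),
             tensor27(qx, qy, dqz))
  lx <- lin_shape_1d(gp[, 1]); ly <- lin_shape_1d(gp[, 2])
  lz <- lin_shape_1d(gp[, 3])
  N1 <- matrix(0, 27, 8)
  for (k in 0:1) for (j in 0:1) for (i in 0:1)
    N1[, 1 + i + 2 * j + 4 * k] <- lx[, i + 1] * ly[, j + 1] * lz[, k + 1]
  list(xi = unname(gp), w = w, N2 = N2, dN = dN, N1 = N1)
}

# triquadratic basis values at arbitrary local coordinates (m x 3)
q2_basis_at <- function(xi) {
  xi <- matrix(xi, ncol = 3)
  qx <- quad_shape_1d(xi[, 1]); qy <- quad_shape_1d(xi[, 2])
  qz <- quad_shape_1d(xi[, 3])
  out <- matrix(0, nrow(xi), 27)
  for (k in 0:2) for (j in 0:2) for (i in 0:2)
    out[, 1 + i + 3 * j + 9 * k] <- qx[, i + 1] * qy[, j + 1] * qz[, k + 1]
  out
}

#' Build a structured Taylor-Hood cube mesh
#'
#' Structured hexahedral mesh of a rectangular block with triquadratic
#' geometry/displacement nodes and trilinear pressure nodes, a uniform
#' reference fiber direction, and precomputed per-element quadrature data
#' (shape gradients with respect to reference coordinates and weighted
#' Jacobians at all 27 Gauss points).
#'
#' @param nx,ny,nz element counts per direction (>= 1); the default 2x2x2
#'   gives the 8-element reference cube.
#' @param L edge length(s) in cm; scalar or length-3.
#' @param fiber_dir reference fiber direction (normalized internally);
#'   uniform over the mesh.
#' @return Object of class `mech_mesh` with nodes (geometry and pressure),
#'   connectivities, fiber direction, and quadrature caches.
#' @export
build_cube_mesh <- function(nx = 2, ny = 2, nz = 2, L = 2,
                            fiber_dir = c(1, 0, 0)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, all(L > 0))
  Lv <- rep_len(L, 3)
  ne <- c(nx, ny, nz)
  gdim <- 2 * ne + 1
  xs <- lapply(1:3, function(d) seq(0, Lv[d], length.out = gdim[d]))
  nodes <- unname(as.matrix(expand.grid(xs[[1]], xs[[2]], xs[[3]])))
  pdim <- ne + 1
  pxs <- lapply(1:3, function(d) seq(0, Lv[d], length.out = pdim[d]))
  pnodes <- unname(as.matrix(expand.grid(pxs[[1]], pxs[[2]], pxs[[3]])))
  gid <- function(i, j, k) 1L + i + gdim[1] * (j + gdim[2] * k)
  pid <- function(i, j, k) 1L + i + pdim[1] * (j + pdim[2] * k)
  nE <- nx * ny * nz
  elems <- matrix(0L, nE, 27)
  pelems <- matrix(0L, nE, 8)
  e <- 0L
  for (ez in 0:(nz - 1)) for (ey in 0:(ny - 1)) for (ex in 0:(nx - 1)) {
    e <- e + 1L
    a <- 0L
    for (k in 0:2) for (j in 0:2) for (i in 0:2) {
      a <- 1L + i + 3L * j + 9L * k
      elems[e, a] <- gid(2 * ex + i, 2 * ey + j, 2 * ez + k)
    }
    for (k in 0:1) for (j in 0:1) for (i in 0:1)
      pelems[e, 1L + i + 2L * j + 4L * k] <- pid(ex + i, ey + j, ez + k)
  }
  a0 <- fiber_dir / sqrt(sum(fiber_dir^2))
  quad <- gauss_tables()
  # per-element shape gradients wrt X and weighted Jacobian determinants
  elem_quad <- vector("list", nE)
  for (e in seq_len(nE)) {
    Xe <- nodes[elems[e, ], , drop = FALSE]
    Gx <- matrix(0, 27, 27); Gy <- matrix(0, 27, 27); Gz <- matrix(0, 27, 27)
    wdetJ <- numeric(27)
    for (g in 1:27) {
      dNdxi <- cbind(quad$dN[[1]][g, ], quad$dN[[2]][g, ], quad$dN[[3]][g, ])
      J0 <- crossprod(Xe, dNdxi)        # dX/dxi, 3x3
      dJ <- det3(J0)
      if (dJ <= 0) stop("element ", e, " has non-positive reference Jacobian")
      dNdX <- dNdxi %*% inv3(t(J0))     # dN/dX = dN/dxi %*% (dxi/dX)
      Gx[g, ] <- dNdX[, 1]; Gy[g, ] <- dNdX[, 2]; Gz[g, ] <- dNdX[, 3]
      wdetJ[g] <- quad$w[g] * dJ
    }
    elem_quad[[e]] <- list(Gx = Gx, Gy = Gy, Gz = Gz, wdetJ = wdetJ)
  }
  structure(list(
    nx = nx, ny = ny, nz = nz, L = Lv, h = Lv / ne,
    nodes = nodes, elems = elems, pnodes = pnodes, pelems = pelems,
    n_nodes = nrow(nodes), n_pnodes = nrow(pnodes), n_elems = nE,
    a0 = a0, quad = quad, elem_quad = elem_quad),
    class = "mech_mesh")
}

#' @export
print.mech_mesh <- function(x, ...) {
  cat(sprintf(
    "<mech_mesh> %dx%dx%d Taylor-Hood elements (%d), %d geometry / %d pressure nodes, fiber a0 = (%g, %g, %g)\n",
    x$nx, x$ny, x$nz, x$n_elems, x$n_nodes, x$n_pnodes,
    x$a0[1], x$a0[2], x$a0[3]))
  invisible(x)
}

#' Geometry nodes on a coordinate face
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param face one of `"x0"`, `"x1"`, `"y0"`, `"y1"`, `"z0"`, `"z1"`.
#' @param tol coordinate tolerance (cm).
#' @return Integer vector of geometry node indices.
#' @export
face_nodes <- function(mesh, face, tol = 1e-9) {
  d <- match(substr(face, 1, 1), c("x", "y", "z"))
  val <- if (substr(face, 2, 2) == "0") 0 else mesh$L[d]
  which(abs(mesh$nodes[, d] - val) < tol)
}

#' Total reference volume by quadrature
#' @param mesh a [build_cube_mesh()] mesh.
#' @return Volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  sum(vapply(mesh$elem_quad, function(eq) sum(eq$wdetJ), numeric(1)))
}
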