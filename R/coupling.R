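# Transfer operators between the coarse 3D mechanics mesh and the fine
# embedded 1D fiber meshes: fiber seeding in local element coordinates,
# position interpolation through the triquadratic basis, a 7-node-patch
# backward-difference velocity estimate, and nearest-Gauss-point
# arithmetic-mean homogenization of the activation gamma.

#' Seed embedded fiber meshes in a structured cube mesh
#'
#' Distributes `n_fibers` straight fibers on a uniform, cell-centered
#' transverse lattice spanning the full specimen length along `axis`. Each
#' fiber node stores its host element and exact local coordinates
#' `xi` in `[0,1]^3`, the reference internode spacings, and a sparse
#' interpolation operator mapping deformed geometry nodes to fiber node
#' positions. Fiber-node-to-Gauss-point assignments for homogenization are
#' precomputed (nearest Gauss point in local coordinates, ties broken
#' towards the lowest Gauss-point index).
#'
#' @param mesh a [build_cube_mesh()] mesh.
#' @param n_fibers requested fiber count; must be a perfect square for the
#'   transverse lattice, otherwise the nearest square lattice is used with
#'   a warning.
#' @param n_elem_per_fiber linear 1D elements per fiber (nodes = count + 1).
#' @param axis fiber axis (1, 2, or 3); must be parallel to a parametric
#'   axis of the structured mesh.
#' @param mu_of_fiber optional motor-unit id per fiber (default all 1).
#' @return Object of class `fiber_mesh_set`.
#' @export
seed_fibers <- function(mesh, n_fibers, n_elem_per_fiber = 60, axis = 1,
                        mu_of_fiber = NULL) {
  stopifnot(n_fibers >= 1, n_elem_per_fiber >= 1)
  k <- max(1L, round(sqrt(n_fibers)))
  if (k * k != n_fibers) {
    warning("n_fibers = ", n_fibers, " is not a perfect transverse lattice; ",
            "using ", k, "x", k, " = ", k * k, " fibers")
  }
  t1 <- setdiff(1:3, axis)[1]
  t2 <- setdiff(1:3, axis)[2]
  n_nodes <- n_elem_per_fiber + 1L
  s_ax <- seq(0, mesh$L[axis], length.out = n_nodes)
  ne_vec <- c(mesh$nx, mesh$ny, mesh$nz)
  hx <- mesh$h
  fibers <- vector("list", k * k)
  f <- 0L
  for (j2 in seq_len(k)) for (j1 in seq_len(k)) {
    f <- f + 1L
    pos <- matrix(0, n_nodes, 3)
    pos[, axis] <- s_ax
    pos[, t1] <- (j1 - 0.5) / k * mesh$L[t1]
    pos[, t2] <- (j2 - 0.5) / k * mesh$L[t2]
    host <- integer(n_nodes)
    xi <- matrix(0, n_nodes, 3)
    ecoord <- matrix(0L, n_nodes, 3)
    for (d in 1:3) {
      ie <- pmin(floor(pos[, d] / hx[d]), ne_vec[d] - 1L)
      ecoord[, d] <- as.integer(ie)
      xi[, d] <- pos[, d] / hx[d] - ie
    }
    # element numbering: ex fastest, then ey, ez (as in build_cube_mesh)
    host <- as.integer(1L + ecoord[, 1] +
                         ne_vec[1] * (ecoord[, 2] + ne_vec[2] * ecoord[, 3]))
    B <- q2_basis_at(xi)
    ii <- rep(seq_len(n_nodes), each = 27L)
    jj <- as.vector(t(mesh$elems[host, , drop = FALSE]))
    interp <- Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(t(B)),
                                   dims = c(n_nodes, mesh$n_nodes))
    eta_ref <- diff(s_ax)
    fibers[[f]] <- list(
      host_elem = host, xi = xi, interp = interp,
      positions_ref = pos, eta_ref = eta_ref, L_ref = mesh$L[axis],
      n_nodes = n_nodes, junction = (n_nodes + 1L) %/% 2L,
      gp_assign = nearest_gp_assignment(xi, mesh$quad$xi),
      mu = if (is.null(mu_of_fiber)) 1L else mu_of_fiber[f])
  }
  structure(list(fibers = fibers, n_fibers = k * k, axis = axis,
                 mesh_n_elems = mesh$n_elems),
            class = "fiber_mesh_set")
}

#' @export
print.fiber_mesh_set <- function(x, ...) {
  cat(sprintf("<fiber_mesh_set> %d fibers x %d nodes along axis %d\n",
              x$n_fibers, x$fibers[[1]]$n_nodes, x$axis))
  invisible(x)
}

# nearest Gauss point (in local element coordinates) per fiber node;
# ties resolved to the lowest Gauss-point index (which.min does this).
nearest_gp_assignment <- function(xi, gp_xi) {
  n <- nrow(xi)
  out <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (gp_xi[, 1] - xi[i, 1])^2 + (gp_xi[, 2] - xi[i, 2])^2 +
          (gp_xi[, 3] - xi[i, 3])^2
    out[i] <- which.min(d2)
  }
  out
}

#' Interpolate deformed fiber node positions from the 3D solution
#'
#' Evaluates the triquadratic basis of each node's host element at its
#' stored local coordinates on the deformed geometry.
#'
#' @param fset a [seed_fibers()] set.
#' @param mesh the host mesh.
#' @param u displacement field `n_nodes x 3`.
#' @return List of `n_nodes x 3` position matrices, one per fiber.
#' @export
interpolate_positions <- function(fset, mesh, u) {
  coords <- mesh$nodes + u
  lapply(fset$fibers, function(fb) {
    if (any(fb$xi < -1e-12 | fb$xi > 1 + 1e-12))
      stop("embedding corruption: fiber local coordinates outside [0,1]^3")
    as.matrix(fb$interp %*% coords)
  })
}

#' Patch-averaged normalized fiber shortening speed
#'
#' Backward-difference estimate of the local fiber stretch rate from two
#' consecutive mechanics-step geometries: per-segment rate
#' `(eta_new - eta_old) / dt_cmm` divided by the reference segment length,
#' averaged onto nodes, then averaged over a centered patch of (up to)
#' seven sequential nodes (window shrinking symmetrically at the ends).
#' The result is normalized by the maximum stretch rate
#' `vmax / L_fiber_ref` and clamped to shortening only (`u >= 0`,
#' lengthening maps to 0).
#'
#' @param pos_new,pos_old `n x 3` fiber node positions at consecutive
#'   mechanics steps; pass `pos_old = NULL` (no history) to get zeros.
#' @param eta_ref reference internode distances (length `n - 1`).
#' @param dt_cmm mechanics time step (ms).
#' @param mp a [material_params()] record (supplies `vmax`).
#' @param L_ref reference fiber length (cm).
#' @param patch patch width in nodes (odd; default 7).
#' @return Per-node normalized shortening speed `u` in `[0, 1]`.
#' @export
fiber_velocity <- function(pos_new, pos_old, eta_ref, dt_cmm,
                           mp = material_params(),
                           L_ref = sum(eta_ref), patch = 7) {
  n <- length(eta_ref) + 1L
  if (is.null(pos_old)) return(numeric(n))
  eta_new <- seg_lengths(pos_new)
  eta_old <- seg_lengths(pos_old)
  seg_rate <- (eta_new - eta_old) / dt_cmm / eta_ref  # stretch rate per segment
  node_rate <- c(seg_rate[1],
                 if (n > 2) (seg_rate[-1] + seg_rate[-(n - 1)]) / 2,
                 seg_rate[n - 1])
  half <- (patch - 1L) %/% 2L
  avg <- vapply(seq_len(n), function(i) {
    w <- min(half, i - 1L, n - i)       # symmetric shrink at fiber ends
    mean(node_rate[(i - w):(i + w)])
  }, numeric(1))
  lam_dot_max <- mp$vmax / L_ref
  pmin(pmax(-avg / lam_dot_max, 0), 1)
}

seg_lengths <- function(pos) {
  d <- pos[-1L, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Homogenize fiber-node activation onto Gauss points
#'
#' Arithmetic mean of all 1D nodal gamma values assigned (nearest in local
#' element coordinates) to each Gauss point of the 3D mesh. Gauss points
#' with no assigned fiber node receive their host element's mean gamma;
#' elements containing no fiber nodes fall back to the global mean with a
#' warning.
#'
#' @param fset a [seed_fibers()] set.
#' @param gamma_nodes list (per fiber) of per-node gamma values.
#' @param mesh the host mesh.
#' @return `n_elems x 27` matrix of homogenized gamma-bar values.
#' @export
homogenize_gamma <- function(fset, gamma_nodes, mesh) {
  nE <- mesh$n_elems
  sums <- matrix(0, nE, 27)
  cnts <- matrix(0, nE, 27)
  for (f in seq_len(fset$n_fibers)) {
    fb <- fset$fibers[[f]]
    g <- gamma_nodes[[f]]
    for (i in seq_len(fb$n_nodes)) {
      e <- fb$host_elem[i]; q <- fb$gp_assign[i]
      sums[e, q] <- sums[e, q] + g[i]
      cnts[e, q] <- cnts[e, q] + 1
    }
  }
  gbar <- matrix(0, nE, 27)
  have <- cnts > 0
  gbar[have] <- sums[have] / cnts[have]
  all_g <- unlist(gamma_nodes)
  global_mean <- if (length(all_g)) mean(all_g) else 0
  for (e in seq_len(nE)) {
    miss <- !have[e, ]
    if (all(miss)) {
      warning("element ", e, " contains no fiber nodes; using global mean gamma")
      gbar[e, ] <- global_mean
    } else if (any(miss)) {
      gbar[e, miss] <- mean(gbar[e, !miss])
    }
  }
  gbar
}
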