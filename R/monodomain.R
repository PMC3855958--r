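#' 1D fiber monodomain system
#'
#' Builds the finite-element discretization of the monodomain equation
#' `d/ds (sigma dVm/ds) = Am (Cm dVm/dt + I_ion)` along one fiber path:
#' linear Lagrange elements on the arclength mesh computed from the node
#' positions, consistent (optionally lumped) mass matrix, natural
#' (zero-flux) boundary conditions at both ends, and one half-sarcomere
#' cell model per node. Action potentials are initiated at the
#' neuromuscular junction node in the middle of the fiber.
#'
#' @param positions n x 3 matrix of node positions (cm) along the fiber
#'   (ordered), or a numeric vector of arclength coordinates.
#' @param model a [cell_model_reduced()] object.
#' @param mp a [material_params()] record (supplies `sigma`, `Am`,
#'   `Cm_slow`/`Cm_fast`).
#' @param dt_deq diffusion time step (ms).
#' @param fiber_type `"fast"` or `"slow"`.
#' @param lumped_mass use a row-sum lumped mass matrix instead of the
#'   consistent one.
#' @param states optional 7 x n matrix of initial cell states (default:
#'   rest).
#' @return Object of class `fiber_system`.
#' @export
fiber_system <- function(positions, model, mp = material_params(),
                         dt_deq = 0.01, fiber_type = c("fast", "slow"),
                         lumped_mass = FALSE, states = NULL) {
  fiber_type <- match.arg(fiber_type)
  if (is.null(dim(positions))) positions <- cbind(positions, 0, 0)
  n <- nrow(positions)
  stopifnot(n >= 2, dt_deq > 0)
  Cm <- membrane_capacitance(mp, fiber_type)
  if (is.null(states)) {
    states <- matrix(rest_state(model, fiber_type), model$n_states, n)
    rownames(states) <- model$state_names
  }
  sys <- list(positions = positions, model = model, mp = mp,
              dt_deq = dt_deq, fiber_type = fiber_type, Cm = Cm,
              lumped_mass = lumped_mass, states = states,
              junction = (n + 1L) %/% 2L, n = n)
  sys <- refresh_matrices(sys)
  class(sys) <- "fiber_system"
  sys
}

#' @export
print.fiber_system <- function(x, ...) {
  cat(sprintf("<fiber_system> %d nodes, length %.4g cm, junction node %d, %s-twitch\n",
              x$n, x$s[x$n], x$junction, x$fiber_type))
  invisible(x)
}

#' Assemble 1D linear-FE mass and stiffness matrices
#'
#' Hand assembly of linear Lagrange elements on a strictly increasing
#' arclength mesh; zero-flux (natural) ends. `K` is scaled by the
#' conductivity `sigma`.
#'
#' @param s arclength coordinates (strictly increasing, cm).
#' @param sigma conductivity (mS/cm).
#' @param lumped use row-sum mass lumping.
#' @return List with dense matrices `M` (cm) and `K` (mS).
#' @export
assemble_fiber_matrices <- function(s, sigma, lumped = FALSE) {
  n <- length(s)
  h <- diff(s)
  if (any(h <= 0))
    stop("degenerate element: coincident or reordered fiber nodes")
  M <- matrix(0, n, n)
  K <- matrix(0, n, n)
  for (e in seq_len(n - 1L)) {
    idx <- c(e, e + 1L)
    M[idx, idx] <- M[idx, idx] + h[e] / 6 * matrix(c(2, 1, 1, 2), 2)
    K[idx, idx] <- K[idx, idx] + sigma / h[e] * matrix(c(1, -1, -1, 1), 2)
  }
  if (lumped) M <- diag(rowSums(M))
  list(M = M, K = K)
}

refresh_matrices <- function(sys) {
  d <- diff_rows(sys$positions)
  seg <- sqrt(rowSums(d^2))
  if (any(seg <= 0))
    stop("degenerate element: coincident fiber nodes")
  sys$s <- c(0, cumsum(seg))
  mats <- assemble_fiber_matrices(sys$s, sys$mp$sigma, sys$lumped_mass)
  sys$M <- mats$M
  sys$K <- mats$K
  A <- sys$M + sys$dt_deq / (sys$mp$Am * sys$Cm) * sys$K
  sys$cholA <- chol(A)
  sys
}

diff_rows <- function(x) x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE]

#' Reaction substep of the operator split
#'
#' Advances every node's half-sarcomere model by `n_steps` cell substeps of
#' size `dt_hsm` (subcycling of the reaction part of the Godunov split),
#' applying the stimulation current only at the junction node, and
#' overwrites the voltage vector from the cell states (the intermediate
#' `Vm*` of the split). Nodes are mutually independent in this substep.
#'
#' @param sys a [fiber_system()].
#' @param dt_hsm cell substep (ms).
#' @param n_steps number of substeps.
#' @param stim_values applied current at the junction per substep
#'   (length-`n_steps` vector, signed; 0 for no stimulus), or a scalar.
#' @param method integrator passed to [advance_reaction()].
#' @return Updated `fiber_system`.
#' @export
reaction_substep <- function(sys, dt_hsm, n_steps, stim_values = 0,
                             method = "semi_implicit") {
  stim <- matrix(0, n_steps, sys$n)
  stim[, sys$junction] <- rep_len(stim_values, n_steps)
  sys$states <- advance_reaction(sys$states, sys$model, dt_hsm, n_steps,
                                 I_stim = stim, Cm = sys$Cm,
                                 method = method)
  sys
}

#' Backward-Euler diffusion step
#'
#' Solves `(M + dt_deq/(Am Cm) K) Vm_new = M Vm*` on the current fiber
#' geometry. With zero-flux ends the mass-weighted mean of `Vm` is
#' conserved exactly.
#'
#' @param sys a [fiber_system()].
#' @return Updated `fiber_system` with the new voltage written into the
#'   cell states.
#' @export
diffusion_step <- function(sys) {
  vstar <- sys$states[1L, ]
  rhs <- sys$M %*% vstar
  v <- backsolve(sys$cholA, backsolve(sys$cholA, rhs, transpose = TRUE))
  sys$states[1L, ] <- v
  sys
}

#' Membrane voltage vector
#' @param sys a [fiber_system()].
#' @return Numeric vector of nodal `Vm` (mV).
#' @export
fiber_vm <- function(sys) sys$states[1L, ]

#' Update fiber geometry after a mechanics step
#'
#' Re-reads the node positions (material points carry their states),
#' recomputes the arclength as cumulative chord length, and reassembles and
#' refactors the FE matrices.
#'
#' @param sys a [fiber_system()].
#' @param new_positions n x 3 matrix (cm).
#' @return Updated `fiber_system`.
#' @export
update_geometry <- function(sys, new_positions) {
  if (is.null(dim(new_positions))) new_positions <- cbind(new_positions, 0, 0)
  stopifnot(nrow(new_positions) == sys$n)
  sys$positions <- new_positions
  refresh_matrices(sys)
}
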