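# 1D monodomain: assembly, operator splitting, conservation, propagation.

model <- cell_model_reduced()
mp <- default_mp

straight_fiber <- function(n_nodes, L = 2, dt_deq = 0.01, ...) {
  fiber_system(cbind(seq(0, L, length.out = n_nodes), 0, 0), model,
               mp, dt_deq = dt_deq, ...)
}

test_that("assembly: tridiagonal stiffness pattern, mass partition of unity", {
  s <- c(0, 0.5, 1.0)
  mats <- assemble_fiber_matrices(s, sigma = 2)
  h <- 0.5
  expect_equal(mats$K, 2 / h * matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3))
  # consistent mass row sums reproduce the nodal weights (partition of unity)
  expect_equal(rowSums(mats$M), c(h / 2, h, h / 2))
  expect_equal(sum(mats$M), 1.0)            # total length
  # conductivity scales the stiffness linearly
  expect_equal(assemble_fiber_matrices(s, sigma = 4)$K, 2 * mats$K)
  expect_error(assemble_fiber_matrices(c(0, 0, 1), 1), "degenerate")
})

test_that("nonuniform spacing assembles element-by-element", {
  s <- c(0, 0.2, 0.7)
  mats <- assemble_fiber_matrices(s, sigma = 1)
  expect_equal(mats$K[1, 1], 1 / 0.2)
  expect_equal(mats$K[2, 2], 1 / 0.2 + 1 / 0.5)
  expect_equal(mats$M[2, 2], (0.2 + 0.5) / 3)
})

test_that("diffusion: uniform field fixed point, exact mean conservation", {
  sys <- straight_fiber(17)
  sys$states[1, ] <- -80
  out <- diffusion_step(sys)
  expect_equal(fiber_vm(out), rep(-80, 17), tolerance = 1e-13)
  # non-uniform: mass-weighted mean conserved to 1e-12 relative
  sys$states[1, ] <- -80 + 50 * exp(-((sys$s - 1) / 0.2)^2)
  m0 <- drop(sys$M %*% fiber_vm(sys)) |> sum()
  out <- diffusion_step(sys)
  m1 <- drop(sys$M %*% fiber_vm(out)) |> sum()
  expect_equal(m1, m0, tolerance = 1e-12)
  # smoothing: variance decreases
  expect_lt(stats::var(fiber_vm(out)), stats::var(fiber_vm(sys)))
})

test_that("diffusion solve matches a dense direct solve", {
  sys <- straight_fiber(3, L = 1)
  sys$states[1, ] <- c(-80, -20, -80)
  out <- diffusion_step(sys)
  A <- sys$M + sys$dt_deq / (mp$Am * sys$Cm) * sys$K
  expect_equal(fiber_vm(out), drop(solve(A, sys$M %*% c(-80, -20, -80))),
               tolerance = 1e-12)
})

test_that("reaction substep equals the 0D operation applied nodewise", {
  sys <- straight_fiber(9)
  sys$states[1, 5] <- -30   # perturb the junction node
  out <- reaction_substep(sys, dt_hsm = 1e-3, n_steps = 10,
                          stim_values = rep(-700, 10))
  ref <- sys$states
  stim <- matrix(0, 10, 9); stim[, 5] <- -700
  ref <- advance_reaction(ref, model, 1e-3, 10, I_stim = stim, Cm = sys$Cm)
  expect_equal(out$states, ref, tolerance = 1e-14)
  # no stimulus at rest: voltages unchanged
  sys2 <- straight_fiber(9)
  out2 <- reaction_substep(sys2, 1e-3, 10, 0)
  expect_equal(fiber_vm(out2), fiber_vm(sys2), tolerance = 1e-6)
})

test_that("junction node index: exact middle for odd, floor(n/2) for even", {
  expect_equal(straight_fiber(61)$junction, 31L)
  expect_equal(straight_fiber(17)$junction, 9L)
  expect_equal(straight_fiber(16)$junction, 8L)
})

test_that("geometry update: scaling laws and state carry-over", {
  sys <- straight_fiber(9)
  same <- update_geometry(sys, sys$positions)
  expect_equal(same$M, sys$M)
  expect_equal(same$K, sys$K)
  lam <- 1.25
  stretched <- update_geometry(sys, sys$positions * lam)
  expect_equal(stretched$M, lam * sys$M, tolerance = 1e-12)
  expect_equal(stretched$K, sys$K / lam, tolerance = 1e-12)
  expect_equal(stretched$states, sys$states)
  # uniform Vm is still a diffusion fixed point after the update
  stretched$states[1, ] <- -70
  expect_equal(fiber_vm(diffusion_step(stretched)), rep(-70, 9),
               tolerance = 1e-12)
})

run_fiber <- function(sys, t_ms, protocol, dt_hsm = 1e-3, n_hsm = 10,
                      keep_every = Inf) {
  n_deq <- round(t_ms / sys$dt_deq)
  snaps <- list()
  for (j in seq_len(n_deq)) {
    times <- (j - 1) * sys$dt_deq + (seq_len(n_hsm) - 1) * dt_hsm
    sys <- reaction_substep(sys, dt_hsm, n_hsm,
                            stim_current_at(protocol, times))
    sys <- diffusion_step(sys)
    if (j %% keep_every == 0) snaps[[length(snaps) + 1]] <- fiber_vm(sys)
  }
  list(sys = sys, snaps = snaps)
}

test_that("propagation: symmetric about the junction, front moves outward", {
  prot <- stimulus_protocol(frequency = 100, amplitude = 700, width = 0.5)
  sys <- straight_fiber(41)
  out <- run_fiber(sys, 6, prot, keep_every = 100)  # snapshot every 1 ms
  for (v in out$snaps)
    expect_equal(v, rev(v), tolerance = 1e-8)       # mirror symmetry
  # depolarization front (outermost node above -20 mV) moves monotonically
  front <- vapply(out$snaps, function(v) {
    up <- which(v > -20)
    if (length(up)) max(abs(sys$s[up] - 1)) else 0
  }, numeric(1))
  active <- front[front > 0 & front < max(sys$s) / 2 - 1e-9]
  expect_true(all(diff(front[front < max(sys$s) / 2 - 1e-9]) >= 0))
  expect_gt(length(active), 1)
})

test_that("conduction speed increases with sigma (~sqrt within 20%)", {
  prot <- stimulus_protocol(frequency = 100, amplitude = 700, width = 0.5)
  speed <- function(sigma_val) {
    mp2 <- material_params(sigma = sigma_val)
    sys <- fiber_system(cbind(seq(0, 2, length.out = 61), 0, 0), model, mp2)
    # time for the front to reach the node 0.5 cm from the junction
    target <- which.min(abs(sys$s - 1.5))
    n_deq <- round(8 / sys$dt_deq)
    for (j in seq_len(n_deq)) {
      times <- (j - 1) * sys$dt_deq + (0:9) * 1e-3
      sys <- reaction_substep(sys, 1e-3, 10, stim_current_at(prot, times))
      sys <- diffusion_step(sys)
      if (fiber_vm(sys)[target] > -20) return(0.5 / (j * sys$dt_deq))
    }
    NA_real_
  }
  v1 <- speed(3.8)
  v2 <- speed(2 * 3.8)
  expect_gt(v2, v1)                          # monotone in sigma
  expect_equal(v2 / v1, sqrt(2), tolerance = 0.2)
})

test_that("no cross-talk between fibers in one simulation", {
  # two fibers stepped side by side; only fiber 1 is stimulated
  sys_list <- lapply(1:2, function(i) straight_fiber(17))
  prot <- stimulus_protocol(frequency = 100, amplitude = 700, width = 0.5)
  rest_vm <- fiber_vm(sys_list[[2]])[1]
  for (j in seq_len(300)) {
    times <- (j - 1) * 0.01 + (0:9) * 1e-3
    sys_list[[1]] <- diffusion_step(
      reaction_substep(sys_list[[1]], 1e-3, 10, stim_current_at(prot, times)))
    sys_list[[2]] <- diffusion_step(
      reaction_substep(sys_list[[2]], 1e-3, 10, 0))
  }
  expect_gt(max(fiber_vm(sys_list[[1]])), -30)   # fiber 1 active
  expect_equal(fiber_vm(sys_list[[2]]), rep(rest_vm, 17), tolerance = 1e-6)
})

test_that("Godunov splitting shows first-order convergence in dt", {
  # fixed smooth problem: Gaussian Vm bump relaxing (no stimulus), fixed
  # fiber; error at T = 1 ms against a tiny-step reference
  make_sys <- function(dt_deq) {
    sys <- straight_fiber(31, dt_deq = dt_deq)
    sys$states[1, ] <- -65 + 30 * exp(-((sys$s - 1) / 0.3)^2)
    sys
  }
  final_vm <- function(dt_deq, t_end = 1) {
    sys <- make_sys(dt_deq)
    n <- round(t_end / dt_deq)
    for (j in seq_len(n)) {
      sys <- reaction_substep(sys, dt_deq / 10, 10, 0)
      sys <- diffusion_step(sys)
    }
    fiber_vm(sys)
  }
  ref <- final_vm(0.00125)
  errs <- vapply(c(0.04, 0.02, 0.01), function(dt)
    max(abs(final_vm(dt) - ref)), numeric(1))
  rates <- log2(errs[-3] / errs[-1])
  expect_true(all(rates > 0.7 & rates < 1.5))  # ~O(dt)
})
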