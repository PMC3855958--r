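# Constitutive model: invariants, strain energy, stress tensors, activation
# scalings. Expected values are either trivial identities, closed-form
# evaluations frozen from independent arithmetic, or brute-force oracles.

mp <- default_mp

test_that("material parameter validation enforces the model invariants", {
  expect_s3_class(mp, "material_params")
  expect_error(material_params(c10 = -1), "> 0")
  expect_error(material_params(d1 = 2), "d1")
  expect_error(material_params(Pmax = 0), "> 0")
  expect_error(material_params(vmax = NA), "finite")
  expect_equal(membrane_capacitance(mp, "slow"), 0.58)
  expect_equal(membrane_capacitance(mp, "fast"), 1.0)
})

test_that("invariants of C: identity, diagonal case, brute-force oracle", {
  expect_equal(unname(invariants_of_C(diag(3), c(1, 0, 0))),
               c(3, 3, 1, 1, 1))
  C <- diag(c(1.44, 1 / 1.2, 1 / 1.2))
  I <- invariants_of_C(C, c(1, 0, 0))
  expect_equal(I[["I3"]], 1.0, tolerance = 1e-12)
  expect_equal(I[["I4"]], 1.44)
  expect_equal(I[["I5"]], 1.44^2)
  set.seed(42)
  for (rep in 1:20) {
    rc <- random_spd_with_stretch(c(0.8, 1.4))
    expect_equal(unname(invariants_of_C(rc$C, rc$a0)),
                 unname(invariants_bruteforce(rc$C, rc$a0)),
                 tolerance = 1e-10)
  }
})

test_that("invariants reject invalid kinematics and non-unit directions", {
  expect_error(invariants_of_C(diag(c(1, 1, -1)), c(1, 0, 0)),
               "positive definite")
  expect_error(invariants_of_C(matrix(1:9, 3), c(1, 0, 0)), "symmetric")
  expect_error(invariants_of_C(diag(3), c(2, 0, 0), strict = TRUE),
               "unit length")
  expect_warning(I <- invariants_of_C(diag(3), c(2, 0, 0)), "normalizing")
  expect_equal(I[["I4"]], 1)
})

test_that("strain energy: reference zero, compression drops W_ani, symbolic value", {
  kin_id <- kinematics(diag(3), c(1, 0, 0))
  expect_equal(strain_energy(kin_id, mp), 0)
  # pure fiber compression: anisotropic term absent
  lam <- 0.9
  Fc <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  kin_c <- kinematics(Fc, c(1, 0, 0))
  W_c <- strain_energy(kin_c, mp)
  I <- kin_c$I
  expect_equal(W_c, mp$c10 * (I[["I1"]] - 3) + mp$c01 * (I[["I2"]] - 3))
  # uniaxial incompressible tension at lambda = 1.1: closed-form evaluation
  lam <- 1.1
  Ft <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  kin_t <- kinematics(Ft, c(1, 0, 0))
  I1 <- lam^2 + 2 / lam
  I2 <- 1 / lam^2 + 2 * lam
  W_expect <- mp$c10 * (I1 - 3) + mp$c01 * (I2 - 3) +
    mp$b1 / mp$d1 * (lam^mp$d1 - 1) - mp$b1 * log(lam)
  expect_equal(strain_energy(kin_t, mp), W_expect, tolerance = 1e-12)
})

test_that("pk2_iso and pk2_ani closed forms", {
  expect_equal(pk2_iso(diag(3), mp), (2 * mp$c10 + 4 * mp$c01) * diag(3))
  expect_equal(2 * mp$c10 + 4 * mp$c01, 14.508, tolerance = 1e-6)
  expect_equal(pk2_ani(1, c(1, 0, 0), mp), matrix(0, 3, 3))
  expect_equal(pk2_ani(0.9, c(1, 0, 0), mp), matrix(0, 3, 3))
  S <- pk2_ani(1.1, c(1, 0, 0), mp)
  coef_expect <- mp$b1 * (1.1^(mp$d1 - 2) - 1.1^-2)
  expect_equal(S[1, 1], coef_expect)
  expect_equal(S[1, 1], 1.40e-3, tolerance = 2e-3)   # ~1.40e-3 kPa
  expect_equal(S[2, 2], 0)
})

test_that("force-length relation: vertex, support endpoints, interior value", {
  expect_equal(force_length(1.2, 1.2), 1.0)
  expect_equal(force_length(0.6 * 1.2, 1.2), 0)
  expect_equal(force_length(1.4 * 1.2, 1.2), 0)
  expect_equal(force_length(1.32, 1.2), 0.9375)
  # continuity at the support boundary and zero outside
  eps <- 1e-9
  expect_lt(force_length(1.4 * 1.2 - eps, 1.2), 1e-7)
  expect_equal(force_length(2.0, 1.2), 0)
  expect_equal(force_length(0.3, 1.2), 0)
  # maximum of 1 attained exactly at lambda_opt
  lf <- seq(0.5, 2, by = 1e-3)
  fl <- force_length(lf, 1.2)
  expect_true(all(fl <= 1 + 1e-12))
  expect_equal(lf[which.max(fl)], 1.2)
})

test_that("velocity factor: isometric limit, zero crossing, interior value", {
  expect_equal(velocity_factor(0, mp), mp$Fiso)
  expect_equal(velocity_factor(1, mp), 0)           # a_rel = b_rel
  expect_equal(velocity_factor(0.1, mp), 0.642857, tolerance = 1e-6)
  u <- seq(0, 1, by = 0.01)
  expect_true(all(diff(velocity_factor(u, mp)) < 0))  # strictly decreasing
  # clamped outside [0, 1]
  expect_equal(velocity_factor(-0.5, mp), velocity_factor(0, mp))
  expect_equal(velocity_factor(2, mp), velocity_factor(1, mp))
})

test_that("gamma scaling combines occupancy and velocity factor", {
  expect_equal(gamma_scale(0, 0.3, mp), 0)
  expect_equal(gamma_scale(1, 0, mp), 1)
  expect_equal(gamma_scale(0.5, 0.1, mp), 0.3214286, tolerance = 1e-6)
  expect_warning(gamma_scale(1.1, 0, mp), "clamping")
  expect_equal(suppressWarnings(gamma_scale(1.1, 0, mp)), 1)
})

test_that("active stress: zero activation, Pmax at optimum, support boundary", {
  expect_equal(pk2_active(1.1, 0, c(1, 0, 0), mp), matrix(0, 3, 3))
  S <- pk2_active(1.2, 1, c(1, 0, 0), mp)
  expect_equal(1.2 * S[1, 1], 73)      # nominal P_act = Pmax at lambda_opt
  expect_equal(pk2_active(1.68, 1, c(1, 0, 0), mp), matrix(0, 3, 3))
})

test_that("total stress: stress-free reference pressure, symmetry, FD oracle", {
  kin <- kinematics(diag(3), c(1, 0, 0))
  p_ref <- 2 * mp$c10 + 4 * mp$c01
  expect_equal(pk2_total(kin, p_ref, 0, mp), matrix(0, 3, 3))
  set.seed(7)
  for (rep in 1:10) {
    F <- random_F()
    a0 <- rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    kin <- kinematics(F, a0)
    p <- runif(1, -5, 5)
    S <- pk2_total(kin, p, 0, mp)
    expect_equal(S, t(S))
    S_fd <- pk2_fd_passive(kin$C, a0, mp) - p * solve(kin$C)
    expect_equal(S, 0.5 * (S_fd + t(S_fd)), tolerance = 1e-5)
    Tc <- cauchy_from_pk2(S, F)
    expect_equal(Tc, t(Tc), tolerance = 1e-12)
  }
})

test_that("derivative consistency: pk2_iso + pk2_ani equals 2 dW/dC", {
  set.seed(11)
  for (rep in 1:100) {
    rc <- random_spd_with_stretch(c(1.001, 1.4))
    S_an <- pk2_iso(rc$C, mp) + pk2_ani(rc$lambda_f, rc$a0, mp)
    S_fd <- pk2_fd_passive(rc$C, rc$a0, mp)
    expect_equal(S_an, 0.5 * (S_fd + t(S_fd)), tolerance = 1e-6)
  }
})

test_that("frame indifference under rotated reference configurations", {
  set.seed(13)
  for (rep in 1:10) {
    F <- random_F()
    a0 <- c(1, 0, 0)
    A <- matrix(rnorm(9), 3)
    Q <- qr.Q(qr(A)); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    kin1 <- kinematics(F, a0)
    kin2 <- kinematics(F %*% t(Q), drop(Q %*% a0))   # rotated reference
    expect_equal(unname(kin2$I), unname(kin1$I), tolerance = 1e-9)
    S1 <- pk2_total(kin1, 1.5, 0.3, mp)
    S2 <- pk2_total(kin2, 1.5, 0.3, mp)
    expect_equal(S2, Q %*% S1 %*% t(Q), tolerance = 1e-9)
    # spatial rotation QF leaves C and the invariants unchanged
    kin3 <- kinematics(Q %*% F, a0)
    expect_equal(unname(kin3$I), unname(kin1$I), tolerance = 1e-9)
  }
})

test_that("small-strain anisotropy is negligible", {
  lam <- 1.05
  P_ani <- mp$b1 * (lam^(mp$d1 - 1) - lam^-1)      # nominal fiber term
  P_iso <- mp$c10 * (2 * lam - 2 * lam^-2) + mp$c01 * (2 - 2 * lam^-3)
  expect_lt(P_ani / P_iso, 0.01)
})

test_that("shear-modulus consistency 2(c10 + c01) is about 7 kPa", {
  expect_equal(2 * (mp$c10 + mp$c01), 7, tolerance = 0.05)
})
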