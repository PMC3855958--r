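#' Passive strain-energy density
#'
#' Evaluates the passive strain energy `W_iso + W_ani` (kPa) of the
#' transversely isotropic, incompressible muscle model: a Mooney-Rivlin
#' ground matrix
#' `W_iso = c10 (I1 - 3) + c01 (I2 - 3)`
#' plus a polynomial fiber-reinforcement term of the fiber stretch
#' `W_ani = b1/d1 (lambda_f^d1 - 1) - b1 log lambda_f`,
#' the latter active only in tension (`lambda_f > 1`).
#'
#' The active contribution is never evaluated as an energy; the active
#' stress is specified directly in [pk2_active()].
#'
#' @param kin a [kinematics()] record.
#' @param mp a [material_params()] record.
#' @return Energy density in kPa (per unit reference volume).
#' @export
strain_energy <- function(kin, mp) {
  stopifnot(inherits(kin, "kinematics"))
  lf <- kin$lambda_f
  if (!is.finite(lf) || lf <= 0)
    stop("invalid kinematics: lambda_f must be > 0")
  W <- mp$c10 * (kin$I[["I1"]] - 3) + mp$c01 * (kin$I[["I2"]] - 3)
  if (lf > 1)
    W <- W + mp$b1 / mp$d1 * (lf^mp$d1 - 1) - mp$b1 * log(lf)
  W
}

#' Isotropic (Mooney-Rivlin) second Piola-Kirchhoff stress
#'
#' `S_iso = 2 c10 I + 2 c01 (I1 I - C)`.
#'
#' @param C 3x3 symmetric positive definite right Cauchy-Green tensor.
#' @param mp a [material_params()] record.
#' @return 3x3 stress tensor (kPa).
#' @export
pk2_iso <- function(C, mp) {
  check_spd(C)
  I1 <- C[1, 1] + C[2, 2] + C[3, 3]
  2 * mp$c10 * diag(3) + 2 * mp$c01 * (I1 * diag(3) - C)
}

#' Anisotropic (fiber-reinforcement) second Piola-Kirchhoff stress
#'
#' `S_ani = b1 (lambda_f^(d1-2) - lambda_f^(-2)) a0 x a0`, zero in
#' compression (`lambda_f <= 1`).
#'
#' @param lambda_f fiber stretch (> 0).
#' @param a0 unit reference fiber direction.
#' @param mp a [material_params()] record.
#' @return 3x3 stress tensor (kPa).
#' @export
pk2_ani <- function(lambda_f, a0, mp) {
  if (!is.finite(lambda_f) || lambda_f <= 0)
    stop("invalid kinematics: lambda_f must be > 0")
  a0 <- check_unit_vector(a0)
  coef <- pk2_ani_coef(lambda_f, mp)
  coef * tcrossprod(a0)
}

pk2_ani_coef <- function(lambda_f, mp) {
  ifelse(lambda_f > 1,
         mp$b1 * (lambda_f^(mp$d1 - 2) - lambda_f^(-2)),
         0)
}

#' Force-length relation
#'
#' Piecewise-quadratic dependence of the active stress on fiber stretch,
#' `f_l(r) = -25/4 r^2 + 25/2 r - 5.25` for `r = lambda_f / lambda_opt` in
#' `[0.6, 1.4]` and zero outside; its maximum value 1 is attained exactly
#' at the optimal stretch.
#'
#' @param lambda_f fiber stretch (> 0); vectorized.
#' @param lambda_opt optimal fiber stretch.
#' @return Values in `[0, 1]`.
#' @export
force_length <- function(lambda_f, lambda_opt = 1.2) {
  r <- lambda_f / lambda_opt
  out <- -25 / 4 * r^2 + 25 / 2 * r - 5.25
  out[r < 0.6 | r > 1.4] <- 0
  pmax(out, 0)
}

#' Hill force-velocity factor
#'
#' Evaluates the hyperbolic force-velocity relation for a normalized
#' shortening speed `u = (-lambda_dot_f) / lambda_dot_max` in `[0, 1]`
#' (lengthening is clamped to `u = 0` upstream):
#' `Fiso * ((1 + a_rel) * b_rel / (b_rel + u) - a_rel)`,
#' which equals `Fiso` at `u = 0` and, for `a_rel = b_rel`, vanishes at
#' `u = 1` (zero force at the maximum shortening velocity).
#'
#' @param u normalized shortening speed, clamped into `[0, 1]`; vectorized.
#' @param mp a [material_params()] record.
#' @return Dimensionless factor, decreasing in `u`.
#' @export
velocity_factor <- function(u, mp) {
  u <- pmin(pmax(u, 0), 1)
  mp$Fiso * ((1 + mp$a_rel) * mp$b_rel / (mp$b_rel + u) - mp$a_rel)
}

#' Microscale activation scaling gamma
#'
#' `gamma = A2_norm * velocity_factor(u)`: the normalized postpower-stroke
#' crossbridge concentration scaled by Hill's force-velocity relation.
#' Small calibration overshoot of `A2_norm` above 1 is tolerated and
#' clamped.
#'
#' @param A2_norm normalized A2 concentration in `[0, 1]`; vectorized.
#' @param u normalized shortening speed in `[0, 1]`; vectorized.
#' @param mp a [material_params()] record.
#' @param overshoot_tol clamp tolerance for `A2_norm` above 1.
#' @return gamma, dimensionless.
#' @export
gamma_scale <- function(A2_norm, u, mp, overshoot_tol = 1e-3) {
  if (any(A2_norm < -overshoot_tol | A2_norm > 1 + overshoot_tol))
    warning("A2_norm outside [0, 1] beyond tolerance; clamping")
  A2_norm <- pmin(pmax(A2_norm, 0), 1)
  A2_norm * velocity_factor(u, mp)
}

#' Active second Piola-Kirchhoff stress
#'
#' `S_act = lambda_f^(-1) Pmax f_l(lambda_f) gamma_bar a0 x a0`, where
#' `gamma_bar` already contains the crossbridge occupancy and the
#' force-velocity factor. The corresponding nominal active stress is
#' `P_act = Pmax f_l(lambda_f) gamma_bar`.
#'
#' @param lambda_f fiber stretch (> 0).
#' @param gamma_bar homogenized activation scaling (>= 0).
#' @param a0 unit reference fiber direction.
#' @param mp a [material_params()] record.
#' @return 3x3 stress tensor (kPa).
#' @export
pk2_active <- function(lambda_f, gamma_bar, a0, mp) {
  if (!is.finite(lambda_f) || lambda_f <= 0)
    stop("invalid kinematics: lambda_f must be > 0")
  stopifnot(gamma_bar >= 0)
  a0 <- check_unit_vector(a0)
  coef <- pk2_active_coef(lambda_f, gamma_bar, mp)
  coef * tcrossprod(a0)
}

pk2_active_coef <- function(lambda_f, gamma_bar, mp) {
  mp$Pmax * force_length(lambda_f, mp$lambda_opt) * gamma_bar / lambda_f
}

#' Total second Piola-Kirchhoff stress
#'
#' `S = S_iso + S_ani + S_act - p C^(-1)` with hydrostatic pressure `p`
#' acting as the Lagrange multiplier of the incompressibility constraint.
#' `gamma_bar` is the upstream product of normalized crossbridge occupancy
#' and the force-velocity factor (see [gamma_scale()]).
#'
#' @param kin a [kinematics()] record.
#' @param p hydrostatic pressure (kPa).
#' @param gamma_bar homogenized activation scaling.
#' @param mp a [material_params()] record.
#' @return 3x3 symmetric stress tensor (kPa).
#' @export
pk2_total <- function(kin, p, gamma_bar, mp) {
  stopifnot(inherits(kin, "kinematics"))
  S <- pk2_iso(kin$C, mp) +
    pk2_ani_coef(kin$lambda_f, mp) * tcrossprod(kin$a0) +
    pk2_active_coef(kin$lambda_f, gamma_bar, mp) * tcrossprod(kin$a0) -
    p * inv3(kin$C)
  0.5 * (S + t(S))
}

#' Push-forward of a second Piola-Kirchhoff stress to Cauchy stress
#'
#' `T = J^(-1) F S F^T`.
#'
#' @param S 3x3 second Piola-Kirchhoff stress (kPa).
#' @param F 3x3 deformation gradient.
#' @return 3x3 Cauchy stress tensor (kPa).
#' @export
cauchy_from_pk2 <- function(S, F) {
  J <- det3(F)
  if (J <= 0) stop("invalid kinematics: det F must be > 0")
  (F %*% S %*% t(F)) / J
}
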