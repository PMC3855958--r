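# Shared test helpers: deterministic random tensors and tiny oracles.

# random SPD C with controlled fiber stretch: eigenvalues in given ranges,
# a0 = first eigenvector, so lambda_f = sqrt(ev1) exactly.
random_spd_with_stretch <- function(lf_range = c(1.0, 1.4),
                                    ev_range = c(0.6, 1.6)) {
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  lf <- runif(1, lf_range[1], lf_range[2])
  ev <- c(lf^2, runif(2, ev_range[1], ev_range[2]))
  C <- Q %*% diag(ev) %*% t(Q)
  C <- 0.5 * (C + t(C))
  list(C = C, a0 = Q[, 1], lambda_f = lf)
}

# random deformation gradient near identity with positive determinant
random_F <- function(scale = 0.15) {
  repeat {
    F <- diag(3) + scale * matrix(runif(9, -1, 1), 3)
    if (det(F) > 0.2) return(F)
  }
}

# brute-force invariants by minor/cofactor expansion (independent oracle)
invariants_bruteforce <- function(C, a0) {
  minor <- function(i, j) det(C[-i, -j, drop = FALSE])
  I2 <- minor(1, 1) + minor(2, 2) + minor(3, 3)
  I3 <- C[1, 1] * minor(1, 1) - C[1, 2] * minor(1, 2) + C[1, 3] * minor(1, 3)
  c(I1 = sum(diag(C)), I2 = I2, I3 = I3,
    I4 = drop(t(a0) %*% C %*% a0),
    I5 = drop(t(a0) %*% C %*% C %*% a0))
}

# central finite difference of 2 dW/dC (componentwise, naturally extended W)
pk2_fd_passive <- function(C, a0, mp, h = 1e-6) {
  W <- function(Cm) {
    lf <- sqrt(drop(t(a0) %*% Cm %*% a0))
    trC <- sum(diag(Cm))
    I1 <- trC
    I2 <- 0.5 * (trC^2 - sum(Cm * t(Cm)))
    w <- mp$c10 * (I1 - 3) + mp$c01 * (I2 - 3)
    if (lf > 1) w <- w + mp$b1 / mp$d1 * (lf^mp$d1 - 1) - mp$b1 * log(lf)
    w
  }
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Cp <- C; Cp[i, j] <- Cp[i, j] + h
    Cm2 <- C; Cm2[i, j] <- Cm2[i, j] - h
    S[i, j] <- (W(Cp) - W(Cm2)) / h      # = 2 dW/dC with central diff /(2h)*2
  }
  S
}

default_mp <- material_params()

reduced_cube_config <- function(t_end = 20, mode = "isometric", ...) {
  cfg <- unclass(make_fixture("cube1_4"))
  cfg$schedule$t_end <- t_end
  cfg$experiment$mode <- mode
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], extra[[nm]])
  validate_config(cfg)
}
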