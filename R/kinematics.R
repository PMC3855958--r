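#' Principal and mixed invariants of a right Cauchy-Green tensor
#'
#' Computes `I1 = tr C`, `I2 = ((tr C)^2 - tr C^2)/2`, `I3 = det C`,
#' `I4 = a0 . C a0`, and `I5 = a0 . C^2 a0` for a symmetric positive
#' definite 3x3 tensor `C` and a unit reference fiber direction `a0`.
#'
#' @param C 3x3 symmetric positive definite matrix.
#' @param a0 reference fiber direction (unit 3-vector). If not of unit
#'   length: with `strict = TRUE` an error is raised, otherwise it is
#'   normalized with a warning.
#' @param strict logical; see `a0`.
#' @return Named numeric vector `c(I1, I2, I3, I4, I5)`.
#' @export
invariants_of_C <- function(C, a0, strict = FALSE) {
  check_spd(C)
  a0 <- check_unit_vector(a0, strict)
  Ca <- C %*% a0
  trC <- C[1, 1] + C[2, 2] + C[3, 3]
  trC2 <- sum(C * t(C))                # tr(C %*% C) for symmetric C
  c(I1 = trC,
    I2 = 0.5 * (trC^2 - trC2),
    I3 = det3(C),
    I4 = sum(a0 * Ca),
    I5 = sum(Ca * Ca))                 # a0' C^2 a0 = |C a0|^2 (C symmetric)
}

#' Kinematic state at an evaluation point
#'
#' Derives the full per-point deformation record (right Cauchy-Green tensor,
#' Green-Lagrange strain, Jacobian, fiber stretch, invariants) from a
#' deformation gradient and a reference fiber direction.
#'
#' @param F 3x3 deformation gradient with `det F > 0`.
#' @param a0 unit reference fiber direction.
#' @param strict passed to [invariants_of_C()].
#' @return Object of class `kinematics`: list with `F`, `C`, `E`, `J`,
#'   `a0`, `lambda_f` and `I` (the five invariants).
#' @export
kinematics <- function(F, a0, strict = FALSE) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)), all(is.finite(F)))
  J <- det3(F)
  if (J <= 0)
    stop("invalid kinematics: det F = ", format(J), " must be > 0")
  a0 <- check_unit_vector(a0, strict)
  C <- crossprod(F)
  I <- invariants_of_C(C, a0)
  structure(list(F = F, C = C, E = 0.5 * (C - diag(3)), J = J, a0 = a0,
                 lambda_f = sqrt(I[["I4"]]), I = I),
            class = "kinematics")
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics> J = %.6g, lambda_f = %.6g\n", x$J, x$lambda_f))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

det3 <- function(M) {
  M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
  M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
  M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
}

inv3 <- function(M) {
  d <- det3(M)
  if (!is.finite(d) || abs(d) < .Machine$double.xmin)
    stop("invalid kinematics: singular tensor")
  adj <- matrix(c(
    M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2],
    M[1, 3] * M[3, 2] - M[1, 2] * M[3, 3],
    M[1, 2] * M[2, 3] - M[1, 3] * M[2, 2],
    M[2, 3] * M[3, 1] - M[2, 1] * M[3, 3],
    M[1, 1] * M[3, 3] - M[1, 3] * M[3, 1],
    M[1, 3] * M[2, 1] - M[1, 1] * M[2, 3],
    M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1],
    M[1, 2] * M[3, 1] - M[1, 1] * M[3, 2],
    M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]), 3, 3, byrow = TRUE)
  adj / d
}

check_spd <- function(C, tol = 1e-8) {
  if (!is.matrix(C) || any(dim(C) != 3L) || any(!is.finite(C)))
    stop("invalid kinematics: C must be a finite 3x3 matrix")
  if (max(abs(C - t(C))) > tol * max(1, max(abs(C))))
    stop("invalid kinematics: C is not symmetric")
  ev <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ev))
    stop("invalid kinematics: C is not positive definite")
  invisible(TRUE)
}

check_unit_vector <- function(a0, strict = FALSE, tol = 1e-8) {
  stopifnot(is.numeric(a0), length(a0) == 3L, all(is.finite(a0)))
  n <- sqrt(sum(a0^2))
  if (n == 0) stop("fiber direction a0 must be nonzero")
  if (abs(n - 1) > tol) {
    if (strict)
      stop("fiber direction a0 is not of unit length (|a0| = ", format(n), ")")
    warning("normalizing non-unit fiber direction a0")
    a0 <- a0 / n
  }
  a0
}
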