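#' Material and membrane parameters
#'
#' Bundles every constitutive, Hill, and membrane constant used by the
#' simulator into one validated record. Units follow the package-wide
#' cm / ms / mV / kPa / uA/cm^2 / uF/cm^2 / mS/cm system, so the maximum
#' active nominal stress of 7.3 N/cm^2 is stored as 73 kPa and the maximum
#' shortening velocity of 200 mm/s as 0.02 cm/ms.
#'
#' The shipped defaults are the passive Mooney-Rivlin + fiber-reinforcement
#' parameters fitted to uniaxial compression/extension data of skeletal
#' muscle, together with the standard Hill constants a/F_iso = b/ldot_max =
#' 0.25 and the membrane constants of slow- and fast-twitch fibers.
#'
#' @param c10,c01 Mooney-Rivlin coefficients (kPa).
#' @param b1,d1 fiber-reinforcement coefficient (kPa) and exponent (-);
#'   `d1 > 2` so the anisotropic stress vanishes at unit stretch and grows
#'   in tension.
#' @param Pmax maximum active nominal stress (kPa).
#' @param lambda_opt optimal fiber stretch (-).
#' @param a_rel,b_rel Hill constants a/F_iso and b/ldot_max (-).
#' @param vmax maximum shortening velocity (cm/ms).
#' @param Fiso dimensionless maximum isometric force scale; kept at 1 so the
#'   activation scaling gamma lies in [0, 1] and the active nominal stress
#'   attains Pmax at isometric tetanus.
#' @param sigma effective intracellular conductivity along the fiber (mS/cm).
#' @param Am membrane surface-to-volume ratio (1/cm).
#' @param Cm_slow,Cm_fast membrane capacitance per unit area (uF/cm^2) for
#'   slow- and fast-twitch fibers.
#' @return An object of class `material_params`.
#' @export
material_params <- function(c10 = 6.352e-10, c01 = 3.627,
                            b1 = 2.756e-5, d1 = 43.373,
                            Pmax = 73, lambda_opt = 1.2,
                            a_rel = 0.25, b_rel = 0.25,
                            vmax = 0.02, Fiso = 1,
                            sigma = 3.8, Am = 500,
                            Cm_slow = 0.58, Cm_fast = 1.0) {
  mp <- list(c10 = c10, c01 = c01, b1 = b1, d1 = d1, Pmax = Pmax,
             lambda_opt = lambda_opt, a_rel = a_rel, b_rel = b_rel,
             vmax = vmax, Fiso = Fiso, sigma = sigma, Am = Am,
             Cm_slow = Cm_slow, Cm_fast = Cm_fast)
  for (nm in names(mp)) {
    v <- mp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("material parameter '", nm, "' must be a finite numeric scalar")
  }
  pos <- c("c10", "c01", "b1", "Pmax", "lambda_opt", "a_rel", "b_rel",
           "vmax", "Fiso", "sigma", "Am", "Cm_slow", "Cm_fast")
  bad <- pos[vapply(pos, function(nm) mp[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("material parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  if (d1 <= 2)
    stop("material parameter 'd1' must be > 2 (anisotropic stress must ",
         "vanish at unit stretch and increase in tension)")
  structure(mp, class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params>\n")
  cat(sprintf("  passive: c10 = %g kPa, c01 = %g kPa, b1 = %g kPa, d1 = %g\n",
              x$c10, x$c01, x$b1, x$d1))
  cat(sprintf("  active : Pmax = %g kPa, lambda_opt = %g, a_rel = %g, b_rel = %g, vmax = %g cm/ms\n",
              x$Pmax, x$lambda_opt, x$a_rel, x$b_rel, x$vmax))
  cat(sprintf("  membrane: sigma = %g mS/cm, Am = %g 1/cm, Cm slow/fast = %g/%g uF/cm^2\n",
              x$sigma, x$Am, x$Cm_slow, x$Cm_fast))
  invisible(x)
}

#' Membrane capacitance by twitch type
#'
#' @param mp a [material_params()] record.
#' @param fiber_type `"slow"` or `"fast"`.
#' @return Capacitance in uF/cm^2.
#' @export
membrane_capacitance <- function(mp, fiber_type = c("fast", "slow")) {
  fiber_type <- match.arg(fiber_type)
  if (fiber_type == "slow") mp$Cm_slow else mp$Cm_fast
}
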