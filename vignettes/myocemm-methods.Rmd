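---
title: "Methods: multiscale chemoelectromechanical muscle simulation"
author: "myocemm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale chemoelectromechanical muscle simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`myocemm` simulates skeletal-muscle contraction across three coupled
scales on a desk-scale problem (a cube of tissue with embedded straight
fibers):

1. **Half-sarcomere (0D).** At every node of every 1D fiber mesh sits an
   ODE cell model producing the membrane ionic current and the attached
   crossbridge pools $A_1$ (prepower stroke) and $A_2$ (postpower stroke).
   The normalized occupancy $A_2/A_2^{\max} \in [0,1]$ is the cellular
   drive of active stress.
2. **Fiber electrophysiology (1D).** Action potentials propagate along
   each fiber by the monodomain (cable) equation
   $\partial_s(\sigma\,\partial_s V_m) = A_m (C_m \dot V_m + I_{\rm ion})$,
   solved on the *deformed* fiber geometry with zero-flux ends. A
   first-order Godunov operator split separates the stiff reaction part
   (the cell ODEs, subcycled with step $\Delta t^{\rm HSM}$) from the
   diffusion part (linear FEM + backward Euler, step $\Delta t^{\rm DEQ}$).
   Stimulation is a rectangular current pulse injected at the
   neuromuscular-junction node in the middle of each fiber.
3. **Continuum mechanics (3D).** Quasi-static, incompressible,
   transversely isotropic hyperelasticity:
   $\mathbf S = 2\partial W/\partial\mathbf C - p\,\mathbf C^{-1}$ with
   $W = c_{10}(I_1-3) + c_{01}(I_2-3)
      + \tfrac{b_1}{d_1}(\lambda_f^{d_1}-1) - b_1\ln\lambda_f$
   (the fiber term only for $\lambda_f>1$), plus the active stress
   $\mathbf S^{\rm act} = \lambda_f^{-1} P^{\max} f_\ell(\lambda_f)\,
   \bar\gamma\; \mathbf a_0\!\otimes\!\mathbf a_0$.
   Here $f_\ell$ is the piecewise-quadratic force-length relation with
   optimum $\lambda_f^{\rm opt}=1.2$, and
   $\gamma = \frac{A_2}{A_2^{\max}}\left[\frac{(1+a_{\rm rel})\,b_{\rm rel}}
   {b_{\rm rel}+u} - a_{\rm rel}\right]$ combines crossbridge occupancy
   with Hill's hyperbolic force-velocity relation evaluated at the
   normalized shortening speed $u$. Discretization: Taylor-Hood hexahedra
   (triquadratic displacement / trilinear pressure), $3\times3\times3$
   Gauss quadrature, Newton iteration.

The scales communicate through two transfer operators: *homogenization*
(fiber-node $\gamma$ values averaged onto the nearest Gauss point of the
host element, in local element coordinates, ties to the lowest Gauss-point
index) and *interpolation* (fiber node positions re-evaluated through the
triquadratic basis after each mechanics solve). The shortening velocity is
estimated per fiber segment by a backward difference of internode
distances over one mechanics step, averaged over a centered patch of seven
nodes (shrinking symmetrically at fiber ends).

# Parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| $c_{10}, c_{01}$ | Mooney-Rivlin matrix | 6.352e-10, 3.627 | kPa |
| $b_1, d_1$ | fiber reinforcement | 2.756e-5, 43.373 | kPa, - |
| $P^{\max}$ | max active nominal stress | 73 (= 7.3 N/cm^2) | kPa |
| $\lambda_f^{\rm opt}$ | optimal fiber stretch | 1.2 | - |
| $a_{\rm rel}, b_{\rm rel}$ | Hill constants $a/F^{\rm iso}$, $b/\dot\lambda_{\max}$ | 0.25, 0.25 | - |
| $v_{\max}$ | max shortening velocity | 0.02 (= 200 mm/s) | cm/ms |
| $\sigma$ | fiber conductivity | 3.8 | mS/cm |
| $A_m$ | surface-to-volume ratio | 500 | 1/cm |
| $C_m$ | membrane capacitance slow/fast | 0.58 / 1.0 | uF/cm^2 |

Unit system: cm / ms / mV / kPa / uA/cm^2 / uF/cm^2 / mS/cm throughout.
With these units the shear modulus consistency $2(c_{10}+c_{01}) \approx
7$ kPa holds by construction of the passive fit.

$\sigma = 3.8$ mS/cm is a package default chosen in the physiological
range (conduction speed ~2 m/s on the reference discretization); no
printed value exists for it and all quantitative targets are insensitive
to it. The stimulus (700 uA/cm^2, 0.5 ms, applied as a depolarizing
membrane current at the junction node) is likewise a calibration freedom:
only suprathreshold behavior matters.

# The reduced cell model

The cell-model layer is pluggable (any model exposing a state vector,
`cell_rhs()`, and an identifiable $A_2$ component can be advanced by the
generic backward-Euler integrator). The shipped default is a reduced
model, built to exercise the full excitation-contraction pathway without
transcribing a ~50-state published system:

* **Sarcolemma**: Hodgkin-Huxley Na/K/leak electrophysiology with
  standard gating; resting potential ~ -65 mV, action potentials
  overshoot 0 mV and last a few ms.
* **Calcium**: one voltage-gated release variable with sigmoidal
  activation around -20 mV and first-order reuptake
  ($\tau \approx 33$ ms), emulating sarcoplasmic-reticulum release and
  pumping.
* **Crossbridges**: a three-pool chain $D \to A_1 \rightleftharpoons A_2$
  with saturating calcium-dependent attachment
  ($k_{\rm att}\,{\rm Ca}^2/({\rm Ca}^2 + K_{\rm Ca}^2)$), in the spirit of
  two-attached-state crossbridge kinetics. The saturating attachment makes
  the tetanic $A_2$ plateau robust (a few percent) against differences in
  action-potential waveform between the 0D calibration run and propagated
  APs on coarse fiber meshes — a deliberate design property, since the
  activation scaling is normalized by the 0D plateau.

Rate constants live in the configuration; only qualitative behaviors are
contractual: quiescence at rest, threshold firing, sub-tetanic single
twitches, tetanic fusion (100 Hz ripple < 10 Hz ripple), nonnegative
concentrations, gates in $[0,1]$. Crossbridge rates are faster than
literature values for real muscle so that tetanic plateaus develop within
~100 ms of simulated time; this is a desk-scale compression of the time
axis, not a fit to twitch data. Fatigue (phosphate) dynamics and the
titin filament are intentionally absent.

**Calibration.** $A_2^{\max}$ is the plateau of a 0D run under the
maximal tetanic protocol (100 Hz, default pulse), detected by a windowed
drift criterion (< 1e-3 per 100 ms) and averaged over the final 10% of
the run. Calibration always uses the maximal protocol even when the
experiment is sub-tetanic or unstimulated, so normalization is
experiment-independent. Results are cached per parameter set.

# Numerical choices

* **Cell integrator.** The production path is a semi-implicit scheme:
  exact exponential (Rush-Larsen) gate updates at frozen voltage,
  linearized-implicit voltage update with conductances from the new
  gates, and implicit linear calcium and 2x2 crossbridge updates. Every
  sub-update is unconditionally stable, and the linear subsystems preserve
  positivity. It is implemented twice — in C++ (production) and in pure R
  (reference) — and the two are tested for agreement at rounding level. A
  generic backward-Euler + damped-Newton integrator (numeric Jacobian)
  serves arbitrary pluggable models and is equivalence-tested against the
  semi-implicit path by step halving.
* **Diffusion.** Linear Lagrange FEM on the current arclength mesh,
  consistent mass matrix (row-sum lumping available by flag), backward
  Euler, Cholesky factorization reused until the geometry changes. With
  natural boundary conditions the mass-weighted mean voltage is conserved
  to machine precision — tested at 1e-12.
* **Mechanics.** Total-Lagrangian residual with analytic stresses,
  consistent tangent by element-level forward differences (step 1e-7),
  Newton with backtracking line search (factor 0.5), relative tolerance
  1e-8. Incompressibility is enforced weakly by the Taylor-Hood pair; for
  the homogeneous experiment states it holds pointwise (|J-1| < 1e-6 at
  every Gauss point). Experiment boundary conditions: axial displacement
  prescribed on both end faces, traction-free lateral faces, rigid-body
  modes removed by pinning the two transverse components along the edge at
  the transverse origin plus one component on a second edge (all
  compatible with the homogeneous solution, so the constraints carry zero
  reactions). No pressure datum is needed while traction boundaries exist;
  prescribed loads are ramped in increments when starting from scratch.
* **Schedule.** Defaults $\Delta t^{\rm HSM} = 0.001$ ms, 10 cell substeps
  per diffusion step, 50 diffusion steps per mechanics step
  ($\Delta t^{\rm CMM} = 0.5$ ms). The historical ratio preset (50 cell
  substeps, 1000 diffusion steps per mechanics step) is available as
  `time_schedule(preset = "ratios_50_1000")`; the published ratios are
  mutually inconsistent with the published mechanics-step study values
  (0.1-2.0 ms would imply sub-microsecond cell steps), so ratios and
  absolute steps are independently configurable and the defaults favor
  resolved membrane dynamics at desk-scale cost.
* **Stimulus timing** is snapped to the reaction-substep grid; pulses
  shorter than a substep would be lost rather than stretched.

# Velocity coupling and the staggered instability

The velocity normalization is a documented reconciliation: the per-segment
backward-difference stretch rate is divided by
$\dot\lambda_{\max} = v_{\max}/L_{\rm fiber}^{\rm ref}$, so whole-specimen
shortening at fraction $q$ of $v_{\max}$ yields $u = q$ at every node
independent of the segment count. Lengthening clamps to $u = 0$ (extending
Hill's hyperbola past the isometric point would introduce a singularity).

This normalization gives the staggered loop a high feedback gain: near the
force-length optimum the stress-stretch stiffness is small, so small
spatial perturbations of stretch produce velocity estimates that swing the
force-velocity factor strongly one mechanics step later. In shortening
experiments the per-node velocity estimate can enter a bounded,
clamp-limited alternation (a seesaw mode of the stretch profile that
mirror-flips between steps) at any mechanics step size. The patch average
damps node-scale noise but not this fiber-scale mode. Consequences are
visible but bounded: the mean activation during shortening runs sits below
the isometric value by more than the Hill factor alone would predict. The
reference trace comparisons in the time-step study are unaffected in kind:
the two finest step sizes agree within 5% while the coarsest (2 ms)
develops amplitude-significant overshoot-recovery oscillation.

The **oscillation index** reported by `timestep_study()` counts sign
alternations of the discrete second difference of the (resampled) stress
trace whose magnitude exceeds 5% of the trace amplitude. A raw sign-change
count is dominated by the physiological stimulation-frequency ripple,
which is present identically at every step size; the amplitude floor makes
the index a detector of nonphysical oscillation. The raw count is also
returned.

# What the synthetic world does and does not establish

The fixture generators produce the reference cube geometries (2 cm cube;
8 Taylor-Hood elements with 400 or 36 fibers of 60 linear elements) and a
reduced variant (1 element, 4 fibers of 16 elements) used by default in
tests for runtime. Fibers are straight, uniformly seeded on a transverse
lattice, and share one motor unit unless configured otherwise. Real
muscle differs in ways the generator does not emulate: curved fascicle
paths, motor-unit territories, fiber-type mixtures, mechanical
interaction with neighboring tissue, and physiological crossbridge
kinetics. A green test therefore establishes the numerical contracts
(convergence orders, conservation, transfer-operator exactness,
homogeneous-state recovery, plateau normalization) — not physiological
fidelity of twitch shapes or absolute force transients.

# Known limitations

* The velocity-activation staggered coupling oscillates in space at the
  force-length optimum (see above); a sub-iterated (implicit) coupling
  would remove it but is out of scope for the pure staggered scheme.
* Taylor-Hood incompressibility is weak; |J-1| pointwise is only
  guaranteed for homogeneous states.
* The reduced cell model is qualitative; no attempt is made to reproduce
  published twitch or fatigue curves.
* Geometry is restricted to structured boxes with axis-parallel fibers;
  anatomical meshes and curved fiber tracking are out of scope.
* Eccentric (lengthening) contractions carry no force-velocity
  enhancement (clamped at the isometric value).
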