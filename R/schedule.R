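#' Three-rate time-step schedule
#'
#' Defines the nested step sizes of the staggered solution scheme: the
#' cell-model substep `dt_hsm`, the diffusion step
#' `dt_deq = n_hsm_per_deq * dt_hsm`, and the continuum-mechanics step
#' `dt_cmm = n_deq_per_cmm * dt_deq`. The shipped defaults
#' (`dt_hsm = 0.001 ms`, 10 cell substeps per diffusion step, 50 diffusion
#' steps per mechanics step, so `dt_cmm = 0.5 ms`) resolve the stiff
#' membrane dynamics while keeping desk-scale runtimes; the historical
#' ratio preset 50/1000 is available via `preset = "ratios_50_1000"`.
#'
#' @param dt_hsm cell-model substep (ms).
#' @param n_hsm_per_deq cell substeps per diffusion step (integer >= 1).
#' @param n_deq_per_cmm diffusion steps per mechanics step (integer >= 1).
#' @param t_end final time (ms).
#' @param preset optional named preset; `"ratios_50_1000"` sets
#'   `n_hsm_per_deq = 50`, `n_deq_per_cmm = 1000`.
#' @return Object of class `schedule` with derived `dt_deq`, `dt_cmm`,
#'   `n_cmm` (number of mechanics steps covering `t_end`).
#' @export
time_schedule <- function(dt_hsm = 1e-3, n_hsm_per_deq = 10L,
                          n_deq_per_cmm = 50L, t_end = 100,
                          preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "ratios_50_1000")
    n_hsm_per_deq <- 50L
    n_deq_per_cmm <- 1000L
  }
  stopifnot(dt_hsm > 0, t_end >= 0,
            n_hsm_per_deq >= 1, n_hsm_per_deq == round(n_hsm_per_deq),
            n_deq_per_cmm >= 1, n_deq_per_cmm == round(n_deq_per_cmm))
  dt_deq <- n_hsm_per_deq * dt_hsm
  dt_cmm <- n_deq_per_cmm * dt_deq
  n_cmm <- if (t_end == 0) 0L else as.integer(ceiling(t_end / dt_cmm - 1e-9))
  structure(list(dt_hsm = dt_hsm, n_hsm_per_deq = as.integer(n_hsm_per_deq),
                 dt_deq = dt_deq, n_deq_per_cmm = as.integer(n_deq_per_cmm),
                 dt_cmm = dt_cmm, t_end = t_end, n_cmm = n_cmm),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf(
    "<schedule> dt_hsm = %g ms x%d -> dt_deq = %g ms x%d -> dt_cmm = %g ms; t_end = %g ms (%d mechanics steps)\n",
    x$dt_hsm, x$n_hsm_per_deq, x$dt_deq, x$n_deq_per_cmm, x$dt_cmm,
    x$t_end, x$n_cmm))
  invisible(x)
}

#' Stimulation protocol
#'
#' Regular-frequency (or explicit firing-time) rectangular current pulses
#' delivered at the neuromuscular junction node of each fiber. The pulse
#' amplitude is stored positive; it is applied as a depolarizing (negative)
#' membrane current in `dVm/dt = -(I_ion + I_stim)/Cm`. The neural
#' discharge times are predefined (unidirectional coupling); per-fiber
#' motor-unit assignment selects which fibers a discharge reaches.
#'
#' @param frequency firing rate (Hz) of each motor unit; scalar recycled
#'   over motor units.
#' @param amplitude pulse amplitude (uA/cm^2).
#' @param width pulse width (ms).
#' @param start,end stimulation window (ms).
#' @param firing_times optional explicit sorted firing times (ms),
#'   overriding `frequency` (single motor unit), or a list of such vectors
#'   (one per motor unit).
#' @param mu_of_fiber integer motor-unit id per fiber (default: all fibers
#'   in motor unit 1).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(frequency = 100, amplitude = 700, width = 0.5,
                              start = 0, end = Inf, firing_times = NULL,
                              mu_of_fiber = NULL) {
  stopifnot(all(frequency > 0), amplitude >= 0, width > 0, start >= 0,
            end >= start)
  if (!is.null(firing_times)) {
    if (!is.list(firing_times)) firing_times <- list(firing_times)
    for (ft in firing_times)
      if (is.unsorted(ft)) stop("firing times must be sorted")
  }
  structure(list(frequency = frequency, amplitude = amplitude,
                 width = width, start = start, end = end,
                 firing_times = firing_times, mu_of_fiber = mu_of_fiber),
            class = "stimulus_protocol")
}

#' Applied junction current at given times
#'
#' Evaluates the protocol's pulse train: the (signed, depolarizing =
#' negative) applied membrane current at each time, for one motor unit.
#'
#' @param protocol a [stimulus_protocol()].
#' @param times numeric vector of times (ms).
#' @param mu motor-unit index (for per-unit firing times).
#' @return Vector of applied currents (uA/cm^2).
#' @export
stim_current_at <- function(protocol, times, mu = 1L) {
  if (!is.null(protocol$firing_times)) {
    ft <- protocol$firing_times[[min(mu, length(protocol$firing_times))]]
    on <- vapply(times, function(t)
      any(t >= ft & t < ft + protocol$width), logical(1))
  } else {
    f <- protocol$frequency[[min(mu, length(protocol$frequency))]]
    period <- 1000 / f
    rel <- times - protocol$start
    on <- times >= protocol$start & times < protocol$end &
      (rel %% period) < protocol$width
  }
  ifelse(on, -protocol$amplitude, 0)
}
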