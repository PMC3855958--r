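#' Reduced half-sarcomere cell model
#'
#' Constructs the shipped reduced biophysical half-sarcomere model: a
#' Hodgkin-Huxley-type sarcolemma (Na, K, leak currents with standard m/h/n
#' gating, action-potential duration a few ms), a voltage-gated calcium
#' release variable with first-order reuptake emulating sarcoplasmic
#' reticulum release and pumping, and a three-pool attached-crossbridge
#' chain D -> A1 <-> A2 with calcium-dependent (saturating, Hill-type)
#' attachment. The normalized postpower-stroke pool A2 drives the active
#' stress. All rate constants are configurable; only the qualitative
#' behaviors (quiescence at rest, threshold firing, tetanic fusion,
#' sub-tetanic twitch) are contractual.
#'
#' State variables (in order): `Vm` (mV), gates `m`, `h`, `n` (-),
#' `Ca` (normalized free calcium, -), `A1`, `A2` (normalized attached
#' crossbridge pools, -).
#'
#' @param params named list overriding individual rate constants; see
#'   `cell_model_reduced()$params` for names and defaults. Units: mV, /ms,
#'   mS/cm^2.
#' @return Object of class `cell_model`.
#' @export
cell_model_reduced <- function(params = list()) {
  p <- list(
    gNa = 120, ENa = 50, gK = 36, EK = -77, gL = 0.3, EL = -54.387,
    k_rel = 0.15, V_rel = -20, k_slope = 4, k_up = 0.03,
    k_att = 0.35, K_ca = 0.25, k_det = 0.06, f_p = 0.12, f_m = 0.01,
    g_d = 0.03)
  if (length(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown))
      stop("unknown cell-model parameter(s): ", paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  stopifnot(all(vapply(p, function(v) is.numeric(v) && is.finite(v), TRUE)))
  structure(list(
    name = "reduced",
    n_states = 7L,
    state_names = c("Vm", "m", "h", "n", "Ca", "A1", "A2"),
    a2_index = 7L,
    params = p),
    class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model:%s> %d states: %s\n", x$name, x$n_states,
              paste(x$state_names, collapse = ", ")))
  invisible(x)
}

par_vector <- function(model) {
  unlist(model$params[c("gNa", "ENa", "gK", "EK", "gL", "EL", "k_rel",
                        "V_rel", "k_slope", "k_up", "k_att", "K_ca",
                        "k_det", "f_p", "f_m", "g_d")])
}

gate_rates <- function(V, p) {
  xm <- V + 40
  am <- ifelse(abs(xm) < 1e-7, 1, 0.1 * xm / (1 - exp(-xm / 10)))
  xn <- V + 55
  an <- ifelse(abs(xn) < 1e-7, 0.1, 0.01 * xn / (1 - exp(-xn / 10)))
  list(am = am, bm = 4 * exp(-(V + 65) / 18),
       ah = 0.07 * exp(-(V + 65) / 20),
       bh = 1 / (1 + exp(-(V + 35) / 10)),
       an = an, bn = 0.125 * exp(-(V + 65) / 80))
}

#' Ionic membrane current of a cell state
#'
#' Sum of Na, K and leak currents (uA/cm^2) crossing the membrane; positive
#' outward.
#'
#' @param model a [cell_model_reduced()] object.
#' @param state state vector (7) or matrix (7 x n cells).
#' @return Current(s) in uA/cm^2.
#' @export
ionic_current <- function(model, state) {
  s <- as_state_matrix(state, model)
  p <- model$params
  V <- s[1, ]; m <- s[2, ]; h <- s[3, ]; n <- s[4, ]
  p$gNa * m^3 * h * (V - p$ENa) + p$gK * n^4 * (V - p$EK) + p$gL * (V - p$EL)
}

#' Time derivative of the cell state
#'
#' Right-hand side of the reduced half-sarcomere ODE system, with
#' `dVm/dt = -(I_ion + I_stim)/Cm` (a depolarizing applied current is
#' therefore negative).
#'
#' @param model a [cell_model_reduced()] object.
#' @param state state vector (7) or matrix (7 x n).
#' @param I_stim applied membrane current (uA/cm^2), scalar or per cell.
#' @param Cm membrane capacitance (uF/cm^2).
#' @return Derivative array of the same shape as `state`.
#' @export
cell_rhs <- function(model, state, I_stim = 0, Cm = 1) {
  s <- as_state_matrix(state, model)
  p <- model$params
  V <- s[1, ]; m <- s[2, ]; h <- s[3, ]; n <- s[4, ]
  Ca <- s[5, ]; A1 <- s[6, ]; A2 <- s[7, ]
  g <- gate_rates(V, p)
  srel <- 1 / (1 + exp(-(V - p$V_rel) / p$k_slope))
  hc <- Ca^2 / (Ca^2 + p$K_ca^2)
  r1 <- p$k_att * hc
  d <- rbind(
    -(ionic_current(model, s) + I_stim) / Cm,
    g$am * (1 - m) - g$bm * m,
    g$ah * (1 - h) - g$bh * h,
    g$an * (1 - n) - g$bn * n,
    p$k_rel * srel * (1 - Ca) - p$k_up * Ca,
    r1 * (1 - A1 - A2) - (p$k_det + p$f_p) * A1 + p$f_m * A2,
    p$f_p * A1 - (p$f_m + p$g_d) * A2)
  if (is.matrix(state)) d else drop(d)
}

#' Resting (quiescent) state of a cell model
#'
#' Computes the zero-stimulus fixed point: resting potential from the root
#' of the steady-state ionic current, gates at their voltage-dependent
#' steady values, calcium and crossbridge pools at the corresponding linear
#' balance. The rest state is independent of the membrane capacitance.
#'
#' @param model a [cell_model_reduced()] object.
#' @param fiber_type `"fast"` or `"slow"` (stored as attribute; the reduced
#'   model's rest point does not depend on it).
#' @return Named state vector of length 7.
#' @export
rest_state <- function(model, fiber_type = c("fast", "slow")) {
  fiber_type <- match.arg(fiber_type)
  p <- model$params
  iss <- function(V) {
    g <- gate_rates(V, p)
    m <- g$am / (g$am + g$bm); h <- g$ah / (g$ah + g$bh)
    n <- g$an / (g$an + g$bn)
    p$gNa * m^3 * h * (V - p$ENa) + p$gK * n^4 * (V - p$EK) +
      p$gL * (V - p$EL)
  }
  V <- stats::uniroot(iss, c(-90, -45), tol = 1e-12)$root
  g <- gate_rates(V, p)
  srel <- 1 / (1 + exp(-(V - p$V_rel) / p$k_slope))
  Ca <- p$k_rel * srel / (p$k_rel * srel + p$k_up)
  r1 <- p$k_att * Ca^2 / (Ca^2 + p$K_ca^2)
  # steady 2x2: r1 (1 - A1 - A2) = (k_det + f_p) A1 - f_m A2;
  #             f_p A1 = (f_m + g_d) A2
  rho <- p$f_p / (p$f_m + p$g_d)
  A1 <- r1 / (r1 * (1 + rho) + p$k_det + p$f_p - p$f_m * rho)
  st <- c(Vm = V, m = g$am / (g$am + g$bm), h = g$ah / (g$ah + g$bh),
          n = g$an / (g$an + g$bn), Ca = Ca, A1 = A1, A2 = rho * A1)
  attr(st, "fiber_type") <- fiber_type
  st
}

as_state_matrix <- function(state, model) {
  if (is.matrix(state)) {
    stopifnot(nrow(state) == model$n_states)
    state
  } else {
    stopifnot(length(state) == model$n_states)
    matrix(state, ncol = 1)
  }
}

# R twin of the Rcpp kernel; same scheme, used as an independent in-R
# reference and as fallback for small problems.
reduced_step_r <- function(states, dt, n_steps, Cm, p,
                           stim_nodes = integer(0), stim_vals = NULL,
                           record = FALSE) {
  S <- states
  nc <- ncol(S)
  trace <- if (record) matrix(NA_real_, n_steps, 4) else NULL
  iapp <- numeric(nc)
  for (k in seq_len(n_steps)) {
    if (length(stim_nodes)) iapp[stim_nodes] <- stim_vals[k, ]
    V <- S[1, ]; m <- S[2, ]; h <- S[3, ]; n <- S[4, ]
    Ca <- S[5, ]; A1 <- S[6, ]; A2 <- S[7, ]
    g <- gate_rates(V, p)
    sm <- g$am + g$bm; sh <- g$ah + g$bh; sn <- g$an + g$bn
    m <- g$am / sm + (m - g$am / sm) * exp(-dt * sm)
    h <- g$ah / sh + (h - g$ah / sh) * exp(-dt * sh)
    n <- g$an / sn + (n - g$an / sn) * exp(-dt * sn)
    gna <- p$gNa * m^3 * h; gk <- p$gK * n^4
    gtot <- gna + gk + p$gL
    drive <- gna * p$ENa + gk * p$EK + p$gL * p$EL - iapp
    V <- (V + dt / Cm * drive) / (1 + dt / Cm * gtot)
    srel <- 1 / (1 + exp(-(V - p$V_rel) / p$k_slope))
    Ca <- (Ca + dt * p$k_rel * srel) / (1 + dt * (p$k_rel * srel + p$k_up))
    hc <- Ca^2 / (Ca^2 + p$K_ca^2)
    r1 <- p$k_att * hc
    a11 <- 1 + dt * (r1 + p$k_det + p$f_p); a12 <- dt * (r1 - p$f_m)
    a21 <- -dt * p$f_p; a22 <- 1 + dt * (p$f_m + p$g_d)
    dete <- a11 * a22 - a12 * a21
    b1 <- A1 + dt * r1; b2 <- A2
    A1 <- (a22 * b1 - a12 * b2) / dete
    A2 <- (a11 * b2 - a21 * b1) / dete
    if (any(!is.finite(V)))
      stop("cell-model solver divergence at cell ",
           which(!is.finite(V))[1], ", substep ", k)
    S[1, ] <- V; S[2, ] <- m; S[3, ] <- h; S[4, ] <- n
    S[5, ] <- Ca; S[6, ] <- A1; S[7, ] <- A2
    if (record) trace[k, ] <- c(V[1], Ca[1], A1[1], A2[1])
  }
  if (record) list(states = S, trace = trace) else list(states = S)
}

# Generic backward-Euler + damped-Newton integrator for arbitrary cell
# models exposing cell_rhs(); numeric Jacobian, per-cell. Reference/stiff
# fallback for pluggable models — not a production path.
be_step <- function(model, states, dt, n_steps, Cm,
                    stim_nodes = integer(0), stim_vals = NULL) {
  S <- states
  nc <- ncol(S)
  ns <- model$n_states
  iapp <- numeric(nc)
  for (k in seq_len(n_steps)) {
    if (length(stim_nodes)) iapp[stim_nodes] <- stim_vals[k, ]
    for (j in seq_len(nc)) {
      x0 <- S[, j]
      x <- x0
      for (it in 1:30) {
        f <- cell_rhs(model, x, iapp[j], Cm)
        res <- x - x0 - dt * f
        if (max(abs(res)) < 1e-12 * max(1, max(abs(x)))) break
        J <- diag(ns)
        hstep <- pmax(1e-7 * abs(x), 1e-9)
        for (c2 in seq_len(ns)) {
          xp <- x; xp[c2] <- xp[c2] + hstep[c2]
          J[, c2] <- J[, c2] - dt * (cell_rhs(model, xp, iapp[j], Cm) - f) /
            hstep[c2]
        }
        dx <- solve(J, -res)
        lam <- 1
        repeat {
          xn <- x + lam * dx
          rn <- xn - x0 - dt * cell_rhs(model, xn, iapp[j], Cm)
          if (sum(rn^2) <= sum(res^2) || lam < 1e-4) break
          lam <- lam / 2
        }
        x <- xn
      }
      if (any(!is.finite(x)))
        stop("cell-model solver divergence at cell ", j, ", substep ", k)
      S[, j] <- x
    }
  }
  list(states = S)
}

#' Advance cell states through the reaction part of the operator split
#'
#' Integrates the full cell ODE system (including the membrane equation
#' `dVm/dt = -(I_ion + I_stim)/Cm`, the reaction half of the split) over
#' `n_steps * dt` for one or many cells at once.
#'
#' Two integration paths are available: the default `"semi_implicit"`
#' scheme (exponential gate updates plus linearized-implicit voltage,
#' calcium and crossbridge updates; unconditionally stable, implemented in
#' compiled code with an equivalent pure-R reference) and a generic
#' `"backward_euler"` stiff integrator (damped Newton with numeric
#' Jacobian) usable with any pluggable model that provides [cell_rhs()].
#'
#' @param states state vector (7) or matrix (7 x n cells).
#' @param model a [cell_model_reduced()] object.
#' @param dt substep size Delta t^HSM (ms).
#' @param n_steps number of substeps (>= 1).
#' @param I_stim applied membrane current (uA/cm^2): scalar for all cells,
#'   vector per cell, or matrix `n_steps x n_cells` per substep
#'   (depolarizing currents are negative).
#' @param Cm membrane capacitance (uF/cm^2).
#' @param method `"semi_implicit"` (default), `"semi_implicit_r"` (pure-R
#'   twin) or `"backward_euler"`.
#' @param record if `TRUE` (single cell only), also return a per-substep
#'   trace of `Vm`, `Ca`, `A1`, `A2`.
#' @return Updated states (same shape as input); with `record = TRUE` a
#'   list `(states, trace)`.
#' @export
advance_reaction <- function(states, model, dt, n_steps, I_stim = 0,
                             Cm = 1,
                             method = c("semi_implicit", "semi_implicit_r",
                                        "backward_euler"),
                             record = FALSE) {
  method <- match.arg(method)
  stopifnot(dt > 0, n_steps >= 1)
  vec_in <- !is.matrix(states)
  S <- as_state_matrix(states, model)
  nc <- ncol(S)
  if (is.matrix(I_stim)) {
    stopifnot(nrow(I_stim) == n_steps, ncol(I_stim) == nc)
    stim_nodes <- seq_len(nc)
    stim_vals <- I_stim
  } else {
    sv <- rep_len(I_stim, nc)
    stim_nodes <- which(sv != 0)
    stim_vals <- matrix(rep(sv[stim_nodes], each = n_steps), nrow = n_steps)
  }
  out <- switch(method,
    semi_implicit = reduced_step_cpp(S, dt, as.integer(n_steps), Cm,
                                     par_vector(model),
                                     as.integer(stim_nodes - 1L),
                                     stim_vals, record),
    semi_implicit_r = reduced_step_r(S, dt, n_steps, Cm, model$params,
                                     stim_nodes, stim_vals, record),
    backward_euler = be_step(model, S, dt, n_steps, Cm, stim_nodes,
                             stim_vals))
  res <- out$states
  dimnames(res) <- dimnames(S)
  if (vec_in) {
    v <- drop(res)
    names(v) <- model$state_names
    res <- v
  }
  if (record && !is.null(out$trace)) {
    colnames(out$trace) <- c("Vm", "Ca", "A1", "A2")
    return(list(states = res, trace = out$trace))
  }
  res
}

#' Normalized postpower-stroke crossbridge concentration
#'
#' `clamp(A2 / A2max, 0, 1)` with `A2max` from [calibrate_a2max()].
#'
#' @param state state vector (7), state matrix (7 x n), or a bare numeric
#'   vector of A2 values.
#' @param A2max calibration plateau value (> 0).
#' @param model the cell model (used to locate A2 in a full state).
#' @return Values in `[0, 1]`.
#' @export
a2_normalized <- function(state, A2max, model = NULL) {
  if (!is.numeric(A2max) || length(A2max) != 1L || !is.finite(A2max) ||
      A2max <= 0)
    stop("calibration missing: A2max must be a positive scalar ",
         "(run calibrate_a2max first)")
  A2 <- if (is.matrix(state)) {
    idx <- if (!is.null(model)) model$a2_index else nrow(state)
    state[idx, ]
  } else if (!is.null(model) && length(state) == model$n_states) {
    state[model$a2_index]
  } else state
  pmin(pmax(A2 / A2max, 0), 1)
}

#' Calibrate the tetanic plateau of A2
#'
#' Runs a 0D (no diffusion) stimulation of a single half-sarcomere under a
#' maximal tetanic protocol (default 100 Hz) until the windowed mean of A2
#' drifts by less than `drift_tol` per 100 ms, and returns the plateau A2
#' (mean over the final 10% of the run). The result normalizes A2 so that
#' the activation scaling gamma reaches 1 at maximal tetanus.
#'
#' Results are cached per (model parameters, fiber type, protocol, step
#' size) within the session.
#'
#' @param model a [cell_model_reduced()] object.
#' @param fiber_type `"fast"` or `"slow"` (selects the membrane
#'   capacitance).
#' @param protocol a [stimulus_protocol()]; default 100 Hz maximal tetanus.
#' @param mp a [material_params()] record (membrane capacitances).
#' @param dt integration substep (ms).
#' @param chunk_ms horizon increment between plateau checks (ms).
#' @param max_ms maximum horizon before a calibration-failure error.
#' @param drift_tol relative drift threshold per 100 ms.
#' @return Plateau A2 value (scalar), with attribute `"t_plateau_ms"`.
#' @export
calibrate_a2max <- function(model, fiber_type = c("fast", "slow"),
                            protocol = stimulus_protocol(),
                            mp = material_params(), dt = 1e-3,
                            chunk_ms = 100, max_ms = 1000,
                            drift_tol = 1e-3) {
  fiber_type <- match.arg(fiber_type)
  key <- paste(c(model$name, unlist(model$params), fiber_type,
                 protocol$frequency, protocol$amplitude, protocol$width,
                 dt), collapse = "|")
  hit <- .myocemm_cache$a2max[[key]]
  if (!is.null(hit)) return(hit)
  Cm <- membrane_capacitance(mp, fiber_type)
  st <- matrix(rest_state(model, fiber_type), ncol = 1)
  n_chunk <- round(chunk_ms / dt)
  a2_all <- numeric(0)
  prev_mean <- NA_real_
  t0 <- 0
  plateau_reached <- FALSE
  while (t0 < max_ms) {
    times <- t0 + (seq_len(n_chunk) - 1) * dt
    vals <- matrix(stim_current_at(protocol, times), ncol = 1)
    out <- advance_reaction(st, model, dt, n_chunk, I_stim = vals, Cm = Cm,
                            record = TRUE)
    st <- out$states
    a2_all <- c(a2_all, out$trace[, "A2"])
    t0 <- t0 + chunk_ms
    win <- round(10 / dt)      # last 10 ms of the chunk
    cur_mean <- mean(out$trace[(n_chunk - win + 1):n_chunk, "A2"])
    if (!is.na(prev_mean) && cur_mean > 0 &&
        abs(cur_mean - prev_mean) / cur_mean < drift_tol * (chunk_ms / 100)) {
      plateau_reached <- TRUE
      break
    }
    prev_mean <- cur_mean
  }
  if (!plateau_reached)
    stop("calibration failure: no tetanic A2 plateau within ", max_ms, " ms")
  tail_n <- max(1L, round(length(a2_all) * 0.1))
  a2max <- mean(a2_all[(length(a2_all) - tail_n + 1):length(a2_all)])
  if (a2max <= 10 * rest_state(model, fiber_type)[["A2"]] + 1e-12)
    stop("calibration failure: no tetanic response above rest ",
         "(is the stimulus suprathreshold?)")
  attr(a2max, "t_plateau_ms") <- t0
  .myocemm_cache$a2max[[key]] <- a2max
  a2max
}

.myocemm_cache <- new.env(parent = emptyenv())
.myocemm_cache$a2max <- list()
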