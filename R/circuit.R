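# Capacitor-discharge pulse-coil circuit: closed-form transient solution,
# shut-off models, induced-voltage accounting and waveform metrics.

#' Define a capacitor-discharge pulser circuit
#'
#' Bundles the electrical parameters of a magnetic pulser built around a
#' charged capacitor bank discharging through a coil: initial capacitor
#' voltage, capacitance, coil inductance, the equivalent series resistance of
#' the discharge loop, and the current-to-field conversion factor at the fixed
#' position of the bird's head. Two shut-off behaviours are supported: a
#' linear current ramp to zero (hard switch with snubber) and a flyback-diode
#' exponential decay with relaxation time \code{L / r_total}.
#'
#' The switch on-resistance \code{r_on} is recorded for completeness but is
#' folded into \code{r_total}, which is dominated by the coil's equivalent
#' series resistance (~80 ohm for the coil modelled here, against a 0.024 ohm
#' MOSFET).
#'
#' @param u0 Initial capacitor voltage (V).
#' @param capacitance Capacitance of the bank (F). Parallel capacitors sum.
#' @param inductance Coil inductance (H).
#' @param r_total Equivalent series resistance during discharge (ohm).
#' @param r_on Switch on-resistance (ohm); informational, already included in
#'   \code{r_total}.
#' @param k_field Current-to-field conversion at the bird position (mT per A).
#' @param shutoff Shut-off model: \code{"ramp"} (linear descent over
#'   \code{fall_time}) or \code{"flyback"} (exponential decay, time constant
#'   \code{inductance / r_total}).
#' @param fall_time Ramp fall time (s); used only when \code{shutoff = "ramp"}.
#' @param t_d Programmed pulse duration (s): time from switch-on to the start
#'   of shut-off.
#'
#' @return An object of class \code{pulse_circuit}.
#' @seealso [circuit_profile()] for the two built-in device parameter sets,
#'   [solve_discharge()] to simulate the on-phase.
#' @export
#' @examples
#' pc <- pulse_circuit(u0 = 230, capacitance = 270e-6, inductance = 0.170)
#' initial_current_rate(pc)   # A/ms at switch-on
pulse_circuit <- function(u0 = 230, capacitance = 270e-6, inductance = 0.170,
                          r_total = 80, r_on = 0.024, k_field = 24,
                          shutoff = c("ramp", "flyback"),
                          fall_time = 0.69e-3, t_d = 9e-3) {
  shutoff <- match.arg(shutoff)
  num <- c(u0 = u0, capacitance = capacitance, inductance = inductance,
           r_total = r_total, r_on = r_on, k_field = k_field, t_d = t_d)
  if (!all(is.finite(num)))
    stop("invalid-parameter: non-finite circuit parameter(s): ",
         paste(names(num)[!is.finite(num)], collapse = ", "), call. = FALSE)
  if (u0 < 0) stop("invalid-parameter: u0 must be >= 0", call. = FALSE)
  if (capacitance <= 0) stop("invalid-parameter: capacitance must be > 0", call. = FALSE)
  if (inductance <= 0) stop("invalid-parameter: inductance must be > 0", call. = FALSE)
  if (r_total < 0) stop("invalid-parameter: r_total must be >= 0", call. = FALSE)
  if (k_field <= 0) stop("invalid-parameter: k_field must be > 0", call. = FALSE)
  if (t_d <= 0) stop("invalid-parameter: t_d must be > 0", call. = FALSE)
  if (shutoff == "ramp" && (!is.finite(fall_time) || fall_time <= 0))
    stop("invalid-parameter: fall_time must be > 0 for the ramp shut-off",
         call. = FALSE)
  structure(list(u0 = u0, capacitance = capacitance, inductance = inductance,
                 r_total = r_total, r_on = r_on, k_field = k_field,
                 shutoff = shutoff, fall_time = fall_time, t_d = t_d),
            class = "pulse_circuit")
}

#' Built-in pulser circuit profiles
#'
#' Returns the parameter set of one of the two pulser generations used with
#' the same 170 mH coil: \code{"mp09_2020"}, a modified commercial pulser with
#' a 270 uF capacitor and a hard switch-off (modelled as a 0.69 ms linear
#' ramp for the 9 ms treatment pulse), and \code{"custom_2021"}, a custom
#' MOSFET-switched circuit with two 470 uF capacitors in parallel and a
#' flyback diode draining the coil after switch-off. Both charge to 230 V and
#' convert 24 mT per A at the bird position.
#'
#' @param name Profile name, \code{"mp09_2020"} or \code{"custom_2021"}.
#' @param ... Overrides passed on to [pulse_circuit()] (e.g. \code{t_d} or
#'   \code{fall_time} to configure a sham pulse).
#' @return A \code{pulse_circuit}.
#' @export
#' @examples
#' circuit_profile("custom_2021")
#' # sham configuration of the 2020 device: 0.2 ms pulse, 0.1 ms fall
#' circuit_profile("mp09_2020", t_d = 0.2e-3, fall_time = 0.1e-3)
circuit_profile <- function(name = c("mp09_2020", "custom_2021"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    mp09_2020 = list(u0 = 230, capacitance = 270e-6, inductance = 0.170,
                     r_total = 80, r_on = 0.024, k_field = 24,
                     shutoff = "ramp", fall_time = 0.69e-3, t_d = 9e-3),
    custom_2021 = list(u0 = 230, capacitance = 940e-6, inductance = 0.170,
                       r_total = 80, r_on = 0.024, k_field = 24,
                       shutoff = "flyback", fall_time = 0.69e-3, t_d = 10e-3))
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown circuit parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(over)] <- over
  do.call(pulse_circuit, base)
}

#' @export
print.pulse_circuit <- function(x, ...) {
  cat("Pulse circuit (series RLC capacitor discharge)\n")
  cat(sprintf("  U0 = %g V, C = %g uF, L = %g mH, R = %g ohm\n",
              x$u0, x$capacitance * 1e6, x$inductance * 1e3, x$r_total))
  cat(sprintf("  k = %g mT/A, t_d = %g ms, shut-off: %s", x$k_field,
              x$t_d * 1e3, x$shutoff))
  if (x$shutoff == "ramp") cat(sprintf(" (fall %g ms)", x$fall_time * 1e3))
  cat(sprintf("\n  initial dI/dt = U0/L = %.4g A/ms\n", initial_current_rate(x)))
  invisible(x)
}

#' Initial current slope at switch-on
#'
#' At the instant the switch closes, the full capacitor voltage sits across
#' the coil, so the coil current rises at \code{u0 / inductance} regardless of
#' resistance or capacitance. Because the field at a fixed position is
#' proportional to the current, this single slope fixes the onset dB/dt of
#' every pulse fired from the circuit -- the quantity the sham pulse matches.
#'
#' @param circuit A [pulse_circuit()].
#' @return Initial current rate in A/ms.
#' @export
initial_current_rate <- function(circuit) {
  stopifnot(inherits(circuit, "pulse_circuit"))
  if (circuit$inductance <= 0)
    stop("invalid-parameter: inductance must be > 0", call. = FALSE)
  circuit$u0 / circuit$inductance / 1e3
}

# Closed-form solution I(t) of L I'' + R I' + I/C = 0 with I(0)=0,
# I'(0)=U0/L; returns a vectorized function of t (seconds).
discharge_current_fn <- function(circuit) {
  U0 <- circuit$u0; L <- circuit$inductance
  R <- circuit$r_total; C <- circuit$capacitance
  if (U0 == 0) return(function(t) rep(0, length(t)))
  alpha <- R / (2 * L)
  omega0 <- 1 / sqrt(L * C)
  if (abs(alpha - omega0) < 1e-9 * omega0) {
    # critically damped; the explicit t*exp form avoids the cancellation the
    # over/underdamped forms would suffer here
    function(t) (U0 / L) * t * exp(-alpha * t)
  } else if (alpha > omega0) {
    beta <- sqrt(alpha^2 - omega0^2)
    s1 <- -alpha + beta; s2 <- -alpha - beta
    function(t) U0 / (L * (s1 - s2)) * (exp(s1 * t) - exp(s2 * t))
  } else {
    omega_d <- sqrt(omega0^2 - alpha^2)
    function(t) U0 / (L * omega_d) * exp(-alpha * t) * sin(omega_d * t)
  }
}

# integer-multiple time grid covering [0, t_end]: points are exact products
# k * step so that a truncated pulse's grid is a strict prefix of a longer
# one's; a non-commensurate t_end is appended (or snapped when within
# rounding error of the last product)
grid_times <- function(t_end, step) {
  n <- round(t_end / step)
  if (n >= 1 && abs(n * step - t_end) <= 1e-9 * t_end) return((0:n) * step)
  n <- floor(t_end / step)
  tt <- (0:n) * step
  if (tt[n + 1] >= t_end * (1 - 1e-12)) tt[n + 1] <- t_end
  else tt <- c(tt, t_end)
  tt
}

new_pulse_waveform <- function(t, i, k_field, phase_marks, grid_step) {
  stopifnot(length(t) == length(i), !is.unsorted(t, strictly = TRUE))
  structure(list(t = t, i = i, b_mt = k_field * i, k_field = k_field,
                 phase_marks = phase_marks, grid_step = grid_step),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf(
    "Pulse waveform: %d samples over %.4g ms (grid %.3g us)\n",
    length(x$t), max(x$t) * 1e3, x$grid_step * 1e6))
  cat(sprintf("  I peak %.4g A, B peak %.4g mT (k = %g mT/A)\n",
              max(x$i), max(x$b_mt), x$k_field))
  pm <- x$phase_marks
  cat(sprintf("  phases: on at %g ms, shut-off at %s ms, end %g ms\n",
              pm[["switch_on"]] * 1e3,
              ifelse(is.na(pm[["shutoff_start"]]), "?", format(pm[["shutoff_start"]] * 1e3)),
              pm[["end"]] * 1e3))
  invisible(x)
}

#' Simulate the on-phase of a pulse discharge
#'
#' Samples the closed-form solution of the series RLC discharge (over-,
#' critically or underdamped, chosen by the sign of
#' \code{R/(2L) - 1/sqrt(LC)}) on a regular grid from switch-on to the
#' programmed pulse duration \code{t_d}. The current starts at zero with
#' slope \code{u0 / inductance}; the field trace is the current scaled by
#' \code{k_field}.
#'
#' @param circuit A [pulse_circuit()].
#' @param grid_step Sampling step (s); must be at most \code{t_d / 50}.
#' @return A \code{pulse_waveform} covering the on-phase only (the shut-off
#'   mark is set at \code{t_d}; append the tail with [apply_shutoff()]).
#' @export
#' @examples
#' w <- solve_discharge(circuit_profile("custom_2021"))
#' max(w$i)  # ~2.66 A
solve_discharge <- function(circuit, grid_step = 1e-6) {
  stopifnot(inherits(circuit, "pulse_circuit"))
  if (!is.finite(grid_step) || grid_step <= 0)
    stop("invalid-parameter: grid_step must be > 0", call. = FALSE)
  if (grid_step > circuit$t_d / 50)
    stop("resolution error: grid_step must be <= t_d / 50", call. = FALSE)
  t <- grid_times(circuit$t_d, grid_step)
  t_end <- t[length(t)]
  fn <- discharge_current_fn(circuit)
  i <- fn(t)
  new_pulse_waveform(t, i, circuit$k_field,
                     phase_marks = c(switch_on = 0,
                                     shutoff_start = t_end,
                                     end = t_end),
                     grid_step = grid_step)
}

#' Append the shut-off phase to an on-phase waveform
#'
#' Two shut-off behaviours are modelled. \code{"ramp"}: the current descends
#' linearly from its value at \code{t_d} to zero over the circuit's
#' \code{fall_time} (a hard switch whose snubbed descent is approximated as a
#' straight ramp). \code{"flyback"}: a flyback diode drains the coil, so the
#' current decays exponentially with relaxation time
#' \code{inductance / r_total}; the tail is truncated once the current falls
#' below \code{1e-4} of the waveform's peak.
#'
#' @param waveform An on-phase \code{pulse_waveform} from [solve_discharge()].
#' @param circuit The [pulse_circuit()] it was solved from.
#' @return A full \code{pulse_waveform} with updated phase marks.
#' @export
apply_shutoff <- function(waveform, circuit) {
  stopifnot(inherits(waveform, "pulse_waveform"),
            inherits(circuit, "pulse_circuit"))
  t_d <- waveform$phase_marks[["shutoff_start"]]
  n <- length(waveform$t)
  i_d <- waveform$i[n]
  if (i_d < 0) stop("invalid-input: on-phase must end with current >= 0",
                    call. = FALSE)
  step <- waveform$grid_step
  i_max <- max(waveform$i)
  if (i_d == 0 || i_max == 0) {
    # nothing to drain; keep a short zero tail so the off-phase exists
    t_tail <- t_d + seq(step, 2 * step, by = step)
    i_tail <- c(0, 0)
  } else if (circuit$shutoff == "ramp") {
    fall <- circuit$fall_time
    t_tail <- grid_times(fall, step)[-1]
    i_tail <- i_d * (1 - t_tail / fall)
    i_tail[length(i_tail)] <- 0
    t_tail <- t_d + t_tail
  } else if (circuit$shutoff == "flyback") {
    if (circuit$r_total <= 0)
      stop("configuration error: flyback shut-off needs r_total > 0",
           call. = FALSE)
    tau <- circuit$inductance / circuit$r_total
    t_end <- tau * log(i_d / (1e-4 * i_max))
    t_tail <- grid_times(t_end, step)[-1]
    i_tail <- i_d * exp(-t_tail / tau)
    t_tail <- t_d + t_tail
  } else {
    stop("configuration error: unknown shut-off model '", circuit$shutoff,
         "'", call. = FALSE)
  }
  new_pulse_waveform(c(waveform$t, t_tail), c(waveform$i, i_tail),
                     waveform$k_field,
                     phase_marks = c(switch_on = 0, shutoff_start = t_d,
                                     end = t_tail[length(t_tail)]),
                     grid_step = step)
}

#' Simulate a complete pulse (on-phase plus shut-off)
#'
#' Convenience wrapper: [solve_discharge()] followed by [apply_shutoff()].
#'
#' @inheritParams solve_discharge
#' @return A full \code{pulse_waveform}.
#' @export
#' @examples
#' sham <- simulate_pulse(circuit_profile("mp09_2020", t_d = 0.2e-3,
#'                                        fall_time = 0.1e-3))
simulate_pulse <- function(circuit, grid_step = 1e-6) {
  apply_shutoff(solve_discharge(circuit, grid_step), circuit)
}

#' Define a pickup coil
#'
#' A pickup coil converts the local rate of field change into a voltage:
#' \code{U = -a_eff * dB/dt}, with \code{a_eff} the effective area times
#' turns, in V per (T/s).
#'
#' @param a_eff Effective area-turns, V/(T/s); must be positive.
#' @return An object of class \code{pickup_coil}.
#' @export
pickup_coil <- function(a_eff) {
  if (!is.finite(a_eff) || a_eff <= 0)
    stop("invalid-parameter: a_eff must be > 0", call. = FALSE)
  structure(list(a_eff = a_eff), class = "pickup_coil")
}

#' Induced voltage seen by a pickup coil
#'
#' Computes \code{U(t) = -a_eff * dB/dt} by central differences on the
#' waveform's (possibly non-uniform) grid, one-sided at the two boundaries.
#' The field trace is converted from mT to T before differentiating, so the
#' result is in volts when \code{a_eff} is in V/(T/s).
#'
#' @param waveform A \code{pulse_waveform} with at least 3 samples.
#' @param pickup A [pickup_coil()].
#' @return Numeric vector of voltages, one per waveform sample.
#' @export
induced_voltage <- function(waveform, pickup) {
  stopifnot(inherits(waveform, "pulse_waveform"),
            inherits(pickup, "pickup_coil"))
  t <- waveform$t
  n <- length(t)
  if (n < 3)
    stop("resolution error: need at least 3 samples to differentiate",
         call. = FALSE)
  b <- waveform$b_mt / 1e3  # T
  dbdt <- numeric(n)
  dbdt[1] <- (b[2] - b[1]) / (t[2] - t[1])
  dbdt[n] <- (b[n] - b[n - 1]) / (t[n] - t[n - 1])
  idx <- 2:(n - 1)
  dbdt[idx] <- (b[idx + 1] - b[idx - 1]) / (t[idx + 1] - t[idx - 1])
  -pickup$a_eff * dbdt
}

#' Construct pulse metrics directly (e.g. from Hall-probe measurements)
#'
#' Metrics normally come from [waveform_metrics()] on a simulated waveform
#' (provenance \code{"modelled"}); this constructor records externally
#' measured quantities instead, so that measured and modelled peaks can be
#' carried side by side and the adequacy verifier can consume either.
#'
#' @param b_peak Peak field at the bird position (mT).
#' @param onset_field_rate Onset dB/dt (mT/ms), or \code{NA}.
#' @param i_peak,t_peak,onset_current_rate,shutoff_current_rate Optional
#'   current-side metrics (A, s, A/ms, A/ms).
#' @param provenance \code{"measured"} or \code{"modelled"}.
#' @return An object of class \code{pulse_metrics}.
#' @export
#' @examples
#' treat <- pulse_metrics(b_peak = 52, onset_field_rate = 30)
#' sham  <- pulse_metrics(b_peak = 5.2, onset_field_rate = 30)
pulse_metrics <- function(b_peak, onset_field_rate = NA_real_,
                          i_peak = NA_real_, t_peak = NA_real_,
                          onset_current_rate = NA_real_,
                          shutoff_current_rate = NA_real_,
                          provenance = c("measured", "modelled")) {
  provenance <- match.arg(provenance)
  if (!is.finite(b_peak) || b_peak < 0)
    stop("invalid-input: b_peak must be a non-negative field in mT",
         call. = FALSE)
  structure(list(i_peak = i_peak, t_peak = t_peak, b_peak = b_peak,
                 onset_current_rate = onset_current_rate,
                 onset_field_rate = onset_field_rate,
                 shutoff_current_rate = shutoff_current_rate,
                 duration_on = NA_real_, duration_fall = NA_real_,
                 duration_total = NA_real_,
                 u_onset = NA_real_, u_shutoff_peak = NA_real_,
                 provenance = provenance),
            class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf("Pulse metrics (%s)\n", x$provenance))
  cat(sprintf("  B peak %.4g mT", x$b_peak))
  if (is.finite(x$i_peak))
    cat(sprintf("  (I peak %.4g A at %.4g ms)", x$i_peak, x$t_peak * 1e3))
  cat("\n")
  if (is.finite(x$onset_field_rate))
    cat(sprintf("  onset dB/dt %.4g mT/ms", x$onset_field_rate))
  if (is.finite(x$shutoff_current_rate))
    cat(sprintf("  | shut-off |dI/dt| %.4g A/ms", x$shutoff_current_rate))
  cat("\n")
  invisible(x)
}

#' Extract summary metrics from a pulse waveform
#'
#' Reports peak current, its time, peak field, onset rates (least-squares
#' slope over the first 5% of the on-phase), the mean shut-off rate
#' magnitude over the descent, and the phase durations. With a pickup coil,
#' the onset and shut-off induced-voltage spike amplitudes are included.
#'
#' When comparing onset rates between a sham pulse and the treatment pulse
#' it was truncated from, fit both over the same window -- the first 5% of
#' the shorter (sham) on-phase -- by passing \code{onset_window}; the ideal
#' mismatch is then zero and the tolerance absorbs sampling error only.
#'
#' @param waveform A \code{pulse_waveform} (full pulse or on-phase only).
#' @param pickup Optional [pickup_coil()] for induced-voltage metrics.
#' @param onset_window Length (s) of the initial window for the onset-rate
#'   fit; defaults to 5% of this waveform's own on-phase.
#' @return A \code{pulse_metrics} object with provenance \code{"modelled"}.
#' @export
waveform_metrics <- function(waveform, pickup = NULL, onset_window = NULL) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  t <- waveform$t; i <- waveform$i
  if (length(t) == 0) stop("invalid-input: empty waveform", call. = FALSE)
  k <- waveform$k_field
  pm <- waveform$phase_marks
  t_on_end <- pm[["shutoff_start"]]
  if (all(i == 0)) {
    m <- pulse_metrics(b_peak = 0, onset_field_rate = 0, i_peak = 0,
                       t_peak = 0, onset_current_rate = 0,
                       shutoff_current_rate = 0, provenance = "modelled")
    m$duration_on <- t_on_end; m$duration_fall <- pm[["end"]] - t_on_end
    m$duration_total <- pm[["end"]]
    return(m)
  }
  idx_peak <- which.max(i)
  i_peak <- i[idx_peak]
  # onset slope: least-squares fit over the first 5% of the on-phase
  if (is.null(onset_window)) onset_window <- 0.05 * t_on_end
  sel <- which(t <= onset_window)
  if (length(sel) < 2) sel <- 1:2
  ts <- t[sel]; is_ <- i[sel]
  slope <- sum((ts - mean(ts)) * (is_ - mean(is_))) / sum((ts - mean(ts))^2)
  # shut-off: mean descent slope from the shut-off mark to the end
  off_sel <- which(t >= t_on_end)
  shut_rate <- if (length(off_sel) >= 2 && pm[["end"]] > t_on_end) {
    abs((i[off_sel[1]] - i[off_sel[length(off_sel)]]) /
          (pm[["end"]] - t_on_end)) / 1e3
  } else NA_real_
  m <- pulse_metrics(b_peak = k * i_peak, provenance = "modelled")
  m$i_peak <- i_peak
  m$t_peak <- t[idx_peak]
  m$onset_current_rate <- slope / 1e3          # A/ms
  m$onset_field_rate <- k * slope / 1e3        # mT/ms
  m$shutoff_current_rate <- shut_rate
  m$duration_on <- t_on_end
  m$duration_fall <- pm[["end"]] - t_on_end
  m$duration_total <- pm[["end"]]
  if (!is.null(pickup)) {
    u <- induced_voltage(waveform, pickup)
    m$u_onset <- abs(u[1])
    if (length(off_sel) >= 1) m$u_shutoff_peak <- max(abs(u[off_sel]))
  }
  m
}

#' Write / read a waveform as CSV
#'
#' Serializes the time, current, field and (if a pickup coil is supplied)
#' induced-voltage traces with header \code{t_s,i_a,b_mt,u_v}. Values are
#' written with 9 significant digits; a read/write round trip preserves the
#' traces at that precision. Phase marks are not serialized: a re-read
#' waveform has its end marks but an unknown shut-off start.
#'
#' @param waveform A \code{pulse_waveform}.
#' @param path Output file path.
#' @param pickup Optional [pickup_coil()]; without it the \code{u_v} column
#'   is empty.
#' @return \code{path}, invisibly (writer); a \code{pulse_waveform} (reader).
#' @export
write_waveform_csv <- function(waveform, path, pickup = NULL) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  u <- if (is.null(pickup)) rep(NA_real_, length(waveform$t))
       else induced_voltage(waveform, pickup)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.9g", x))
  lines <- c("t_s,i_a,b_mt,u_v",
             paste(fmt(waveform$t), fmt(waveform$i), fmt(waveform$b_mt),
                   fmt(u), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("t_s", "i_a", "b_mt", "u_v")))
    stop("schema error: expected header t_s,i_a,b_mt,u_v", call. = FALSE)
  k <- if (any(df$i_a != 0)) df$b_mt[which.max(abs(df$i_a))] /
         df$i_a[which.max(abs(df$i_a))] else 1
  new_pulse_waveform(df$t_s, df$i_a, k,
                     phase_marks = c(switch_on = df$t_s[1],
                                     shutoff_start = NA_real_,
                                     end = df$t_s[length(df$t_s)]),
                     grid_step = min(diff(df$t_s)))
}
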