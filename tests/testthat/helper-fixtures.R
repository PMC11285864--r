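# Shared fixtures: the two pulser generations, a sham variant, and small
# record tables built in code.

treat_2020 <- function() circuit_profile("mp09_2020")
treat_2021 <- function() circuit_profile("custom_2021")
sham_2020 <- function() circuit_profile("mp09_2020", t_d = 0.2e-3,
                                        fall_time = 0.1e-3)

# numerical ODE oracle for the series RLC discharge: state (I, Vc) with
# L I' = Vc - R I, C Vc' = -I, I(0) = 0, Vc(0) = U0
ode_discharge <- function(circuit, times) {
  deriv <- function(t, y, parms) {
    with(as.list(parms), list(c((y[2] - R * y[1]) / L, -y[1] / C)))
  }
  out <- deSolve::lsoda(c(I = 0, Vc = circuit$u0), times, deriv,
                        parms = c(L = circuit$inductance,
                                  R = circuit$r_total,
                                  C = circuit$capacitance),
                        rtol = 1e-12, atol = 1e-12)
  out[, "I"]
}

small_records <- function() {
  bird_records(data.frame(
    bird_id = c("a", "b", "c", "d"),
    year = c(2020, 2020, 2021, 2021),
    age = c("juvenile", "adult", "juvenile", "adult"),
    group = c("sham", "treatment", "sham", "treatment"),
    departed_first_night = c(TRUE, FALSE, FALSE, NA),
    stopover_nights = c(0L, 3L, 11L, NA),
    night_fraction = c(0.5, 0.25, 0.3, NA),
    departure_bearing_deg = c(138, 95, 120, NA),
    coast_bearing_deg = c(125, 100, 140, NA),
    fuel_load = c(0.1, 0.2, NA, 0.3),
    stringsAsFactors = FALSE))
}

# brute-force two-sided exact Wilcoxon p by enumerating all labelings
brute_wilcoxon_p <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  ws <- apply(utils::combn(N, nx), 2, function(ix) sum(rk[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
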