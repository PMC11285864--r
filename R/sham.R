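# Sham-pulse design and adequacy verification against single-domain
# magnetite switching thresholds.

#' Single-domain magnetite switching thresholds
#'
#' Field thresholds bracketing the switching behaviour of the candidate
#' magnetite-based receptor: below \code{b_no_effect} the particles are
#' unaffected; at or above \code{b_full_switch} their polarity flips. The
#' defaults (12 and 25 mT) come from magnetization curves of the one
#' candidate receptor structure characterised to date (in rainbow trout), so
#' both are configurable.
#'
#' @param b_no_effect Field below which particles are unaffected (mT).
#' @param b_full_switch Field at or above which polarity switches (mT).
#' @return An object of class \code{switching_model}.
#' @export
switching_model <- function(b_no_effect = 12, b_full_switch = 25) {
  if (!(is.finite(b_no_effect) && is.finite(b_full_switch) &&
        b_no_effect > 0 && b_no_effect < b_full_switch))
    stop("invalid-parameter: need 0 < b_no_effect < b_full_switch",
         call. = FALSE)
  structure(list(b_no_effect = b_no_effect, b_full_switch = b_full_switch),
            class = "switching_model")
}

#' Sham-adequacy criteria
#'
#' The two quantitative requirements a sham pulse must satisfy relative to
#' its treatment pulse: its peak field may reach at most
#' \code{max_peak_ratio} of the treatment peak (default 10%), while its
#' onset dB/dt must match the treatment's within
#' \code{onset_rate_tolerance} (relative, default 1%) so that both pulses
#' induce the same voltage spike at switch-on.
#'
#' @param max_peak_ratio Upper bound on sham/treatment peak-field ratio.
#' @param onset_rate_tolerance Max relative onset-rate mismatch.
#' @return An object of class \code{sham_criteria}.
#' @export
sham_criteria <- function(max_peak_ratio = 0.10, onset_rate_tolerance = 0.01) {
  if (!(is.finite(max_peak_ratio) && max_peak_ratio > 0 && max_peak_ratio < 1))
    stop("invalid-parameter: max_peak_ratio must be in (0, 1)", call. = FALSE)
  if (!(is.finite(onset_rate_tolerance) && onset_rate_tolerance > 0))
    stop("invalid-parameter: onset_rate_tolerance must be > 0", call. = FALSE)
  structure(list(max_peak_ratio = max_peak_ratio,
                 onset_rate_tolerance = onset_rate_tolerance),
            class = "sham_criteria")
}

#' Design the sham-pulse duration for a target peak-field ratio
#'
#' Because the sham pulse is the treatment pulse truncated early, its peak
#' field is simply the on-phase current at the truncation time. This function
#' returns the smallest duration \code{t} at which the on-phase current
#' reaches \code{target_ratio} times the treatment peak, by bracketed
#' root-finding on the closed-form solution over \code{(0, t_peak)}, where
#' the current is strictly increasing.
#'
#' @param circuit A [pulse_circuit()].
#' @param t_d_treat Treatment pulse duration (s); the treatment peak is the
#'   maximum of the on-phase current over \code{[0, t_d_treat]}.
#' @param target_ratio Desired sham/treatment peak ratio, in \code{(0, 1)}.
#' @return Sham duration in seconds (always less than the peak time).
#' @export
#' @examples
#' design_sham_duration(circuit_profile("mp09_2020"), 9e-3, 0.1)  # ~0.19 ms
design_sham_duration <- function(circuit, t_d_treat = circuit$t_d,
                                 target_ratio = 0.10) {
  stopifnot(inherits(circuit, "pulse_circuit"))
  if (!is.finite(target_ratio) || target_ratio <= 0 || target_ratio >= 1)
    stop("domain error: target_ratio must be in (0, 1)", call. = FALSE)
  if (!is.finite(t_d_treat) || t_d_treat <= 0)
    stop("invalid-parameter: t_d_treat must be > 0", call. = FALSE)
  if (circuit$u0 == 0)
    stop("domain error: zero drive voltage, no peak to scale against",
         call. = FALSE)
  fn <- discharge_current_fn(circuit)
  # locate the on-phase peak on [0, t_d_treat]
  opt <- stats::optimize(fn, c(0, t_d_treat), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  t_peak <- opt$maximum
  i_peak <- max(opt$objective, fn(t_d_treat))
  if (fn(t_d_treat) >= opt$objective) t_peak <- t_d_treat
  target <- target_ratio * i_peak
  stats::uniroot(function(t) fn(t) - target, c(1e-12, t_peak),
                 tol = 1e-15)$root
}

#' Verify sham adequacy of a sham/treatment pulse pair
#'
#' Evaluates the four criteria that make a sham pulse an adequate control:
#' \enumerate{
#'   \item onset dB/dt of sham and treatment match within the relative
#'     tolerance (same induced voltage spike at switch-on);
#'   \item the sham/treatment peak-field ratio does not exceed
#'     \code{max_peak_ratio};
#'   \item the sham peak stays below the no-effect switching threshold;
#'   \item the treatment peak reaches the full-switch threshold.
#' }
#' Metrics may be modelled ([waveform_metrics()]) or measured
#' ([pulse_metrics()]); their provenance is carried into the report.
#'
#' @param metrics_sham,metrics_treat \code{pulse_metrics} for the two pulses,
#'   from the same field-conversion geometry.
#' @param criteria A [sham_criteria()].
#' @param switching A [switching_model()].
#' @return A \code{sham_adequacy_report}: data frame of per-criterion records
#'   (name, measured value, threshold, pass) with an \code{overall} attribute
#'   equal to the conjunction of the four flags.
#' @export
#' @examples
#' rep <- verify_sham_adequacy(pulse_metrics(5.2, onset_field_rate = 30),
#'                             pulse_metrics(52, onset_field_rate = 30))
#' attr(rep, "overall")  # TRUE
verify_sham_adequacy <- function(metrics_sham, metrics_treat,
                                 criteria = sham_criteria(),
                                 switching = switching_model()) {
  stopifnot(inherits(metrics_sham, "pulse_metrics"),
            inherits(metrics_treat, "pulse_metrics"),
            inherits(criteria, "sham_criteria"),
            inherits(switching, "switching_model"))
  if (!is.finite(metrics_treat$b_peak) || metrics_treat$b_peak <= 0)
    stop("undefined-ratio error: treatment peak field is zero", call. = FALSE)
  rate_s <- metrics_sham$onset_field_rate
  rate_t <- metrics_treat$onset_field_rate
  mismatch <- if (is.finite(rate_s) && is.finite(rate_t) && rate_t != 0)
    abs(rate_s / rate_t - 1) else NA_real_
  ratio <- metrics_sham$b_peak / metrics_treat$b_peak
  rows <- data.frame(
    criterion = c("onset_rate_match", "peak_ratio_bound",
                  "sham_below_no_effect", "treatment_above_full_switch"),
    measured = c(mismatch, ratio, metrics_sham$b_peak, metrics_treat$b_peak),
    threshold = c(criteria$onset_rate_tolerance, criteria$max_peak_ratio,
                  switching$b_no_effect, switching$b_full_switch),
    pass = c(is.finite(mismatch) && mismatch <= criteria$onset_rate_tolerance,
             ratio <= criteria$max_peak_ratio + 1e-9,
             metrics_sham$b_peak < switching$b_no_effect,
             metrics_treat$b_peak >= switching$b_full_switch),
    stringsAsFactors = FALSE)
  structure(rows, overall = all(rows$pass),
            provenance = c(sham = metrics_sham$provenance,
                           treatment = metrics_treat$provenance),
            class = c("sham_adequacy_report", "data.frame"))
}

#' @export
print.sham_adequacy_report <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("Sham adequacy report (sham: %s, treatment: %s)\n",
              prov[["sham"]], prov[["treatment"]]))
  for (j in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-28s measured %.4g vs threshold %.4g\n",
                ifelse(x$pass[j], "pass", "FAIL"), x$criterion[j],
                x$measured[j], x$threshold[j]))
  cat(sprintf("  overall: %s\n",
              ifelse(attr(x, "overall"), "ADEQUATE", "NOT adequate")))
  invisible(x)
}

#' Classify a peak field against magnetite switching thresholds
#'
#' Labels a peak field as \code{"sub_threshold"} (below the no-effect field),
#' \code{"full_switch"} (at or above the full-switch field; the boundary is
#' inclusive on the stronger-effect side) or \code{"partial"} in between.
#'
#' @param b_peak Peak field (mT), non-negative. Vectorized.
#' @param switching A [switching_model()].
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_remagnetization(c(5.2, 15, 52))
classify_remagnetization <- function(b_peak, switching = switching_model()) {
  stopifnot(inherits(switching, "switching_model"))
  if (any(!is.finite(b_peak)) || any(b_peak < 0))
    stop("invalid-input: b_peak must be non-negative and finite",
         call. = FALSE)
  ifelse(b_peak < switching$b_no_effect, "sub_threshold",
         ifelse(b_peak >= switching$b_full_switch, "full_switch", "partial"))
}
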