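# Runs the five-trait sham-vs-treatment battery across year x age subsets
# and lays the p-values out as the standard 5 x 9 grid.

BATTERY_TRAITS <- c("departure_probability", "stopover_duration",
                    "departure_timing", "departure_direction",
                    "consistency_in_flight")

battery_subsets <- function() {
  g <- expand.grid(age = c("juvenile", "adult", "both"),
                   year = c("2020", "2021", "pooled"),
                   stringsAsFactors = FALSE)
  g$label <- paste(g$year, g$age, sep = ".")
  g[, c("year", "age", "label")]
}

#' Run the five-trait statistical battery
#'
#' For each subset of the data (each year, and both years pooled, crossed
#' with each age class and both pooled) the sham and treatment groups are
#' compared on the five traits: first-night departure by the
#' continuity-corrected chi-square test, stopover duration and departure
#' timing by the Wilcoxon rank sum test (exact whenever the policy
#' triggers), and departure direction and flight-direction consistency by
#' the Mardia-Watson-Wheeler test with repeated random tie breaking.
#' Missing trait values are dropped test by test, so sample sizes decline
#' across traits as in real telemetry data.
#'
#' A subset in which a test cannot run (an empty group, a zero margin, too
#' few angles) yields an \code{NA} cell rather than an error. No
#' multiple-testing correction is applied; the grid reports raw p-values.
#'
#' @param traits A \code{trait_table} from [derive_traits()] (a raw
#'   \code{bird_records} table is accepted and derived with the default
#'   window).
#' @param alpha Significance mark level for the printed grid.
#' @param seed Seed for the circular tests' random tie breaking; per-cell
#'   seeds are derived deterministically from it.
#' @param mww_reps Tie-breaking repetitions for [mww_test()].
#' @param wilcoxon_policy Exactness policy for [wilcoxon_ranksum()].
#' @param subsets Optional character vector of subset labels (e.g.
#'   \code{"pooled.both"}, \code{"2020.adult"}) to restrict the grid to;
#'   default all nine. Cell seeds are tied to the full grid, so a
#'   restricted run reproduces the corresponding cells of the full one.
#' @return A \code{battery_table}: list with the 5 x 9 p-value matrix
#'   (\code{$p}; fewer columns if \code{subsets} restricts them), the
#'   matching test-result objects (\code{$results}), and \code{$alpha}.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 30), seed = 11)
#' bt <- run_battery(derive_traits(coh), seed = 1, mww_reps = 50)
#' bt$p[, "pooled.both"]
run_battery <- function(traits, alpha = 0.05, seed = 1, mww_reps = 10000,
                        wilcoxon_policy = "auto", subsets = NULL) {
  if (!inherits(traits, "trait_table")) traits <- derive_traits(traits)
  subs <- battery_subsets()
  if (!is.null(subsets)) {
    bad <- setdiff(subsets, subs$label)
    if (length(bad))
      stop("unknown subset label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  p <- matrix(NA_real_, nrow = length(BATTERY_TRAITS), ncol = nrow(subs),
              dimnames = list(BATTERY_TRAITS, subs$label))
  results <- vector("list", length(p))
  dim(results) <- dim(p)
  dimnames(results) <- dimnames(p)
  try_test <- function(expr) tryCatch(suppressWarnings(expr),
                                      error = function(e) NULL)
  for (j in seq_len(nrow(subs))) {
    if (!is.null(subsets) && !subs$label[j] %in% subsets) next
    sel <- rep(TRUE, nrow(traits))
    if (subs$year[j] != "pooled") sel <- sel & traits$year == subs$year[j]
    if (subs$age[j] != "both") sel <- sel & traits$age == subs$age[j]
    d <- traits[sel, , drop = FALSE]
    sham <- d[d$group == "sham", , drop = FALSE]
    trt <- d[d$group == "treatment", , drop = FALSE]
    cell_seed <- child_seed(seed, j)
    tests <- list(
      departure_probability = function() {
        s <- sham$departed_first_night[!is.na(sham$departed_first_night)]
        t_ <- trt$departed_first_night[!is.na(trt$departed_first_night)]
        if (!length(s) || !length(t_)) return(NULL)
        chi2_yates_2x2(sum(s), sum(!s), sum(t_), sum(!t_))
      },
      stopover_duration = function()
        wilcoxon_ranksum(sham$stopover_nights, trt$stopover_nights,
                         policy = wilcoxon_policy),
      departure_timing = function()
        wilcoxon_ranksum(sham$night_fraction, trt$night_fraction,
                         policy = wilcoxon_policy),
      departure_direction = function()
        mww_test(sham$departure_bearing, trt$departure_bearing,
                 seed = cell_seed, reps = mww_reps),
      consistency_in_flight = function()
        mww_test(sham$consistency_deviation, trt$consistency_deviation,
                 seed = child_seed(cell_seed, 1), reps = mww_reps)
    )
    for (tr in BATTERY_TRAITS) {
      res <- try_test(tests[[tr]]())
      if (!is.null(res)) {
        p[tr, j] <- res$p
        results[[tr, j]] <- res
      }
    }
  }
  if (!is.null(subsets)) {
    keep <- subs$label %in% subsets
    p <- p[, keep, drop = FALSE]
    results <- results[, keep, drop = FALSE]
  }
  structure(list(p = p, results = results, alpha = alpha, seed = seed),
            class = "battery_table")
}

#' @export
print.battery_table <- function(x, digits = 3, ...) {
  cat("Five-trait battery: sham vs treatment, raw p-values",
      sprintf("(* marks p < %g)\n", x$alpha))
  m <- x$p
  txt <- matrix(ifelse(is.na(m), "-",
                       paste0(formatC(m, digits = digits, format = "f"),
                              ifelse(!is.na(m) & m < x$alpha, "*", ""))),
                nrow = nrow(m), dimnames = dimnames(m))
  print(as.data.frame(txt), right = TRUE)
  invisible(x)
}

#' Battery grid as a data frame (Table-style layout)
#'
#' Flattens a \code{battery_table} into a 5-row data frame whose first
#' column names the trait and whose remaining nine columns are the subsets
#' (year crossed with age class), suitable for CSV export.
#'
#' @param battery A \code{battery_table} from [run_battery()].
#' @return Data frame with 5 rows and 10 columns.
#' @export
battery_grid <- function(battery) {
  stopifnot(inherits(battery, "battery_table"))
  out <- data.frame(trait = rownames(battery$p), battery$p,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
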