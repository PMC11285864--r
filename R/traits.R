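# Per-bird behavioural records: schema validation, CSV ingestion, and
# derivation of the five free-flight migratory traits.

BIRD_CSV_HEADER <- c("bird_id", "year", "age", "group",
                     "departed_first_night", "stopover_nights",
                     "night_fraction", "departure_bearing_deg",
                     "coast_bearing_deg", "fuel_load")

# signed wrapped difference a - b mapped to (-180, 180]; negative means the
# first bearing lies anticlockwise of the second
wrap_diff_deg <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

#' Assemble and validate a table of per-bird records
#'
#' Checks one row per bird against the record invariants: year in
#' {2020, 2021}, age in {juvenile, adult}, group in {sham, treatment},
#' stopover nights a non-negative integer, night fraction in [0, 1],
#' bearings in [0, 360), and -- when both are present -- first-night
#' departure consistent with a stopover of zero nights. Any field may be
#' missing (\code{NA}) except the four identifiers. Violations are reported
#' with the offending row and field.
#'
#' @param df Data frame with the columns listed in the bird-records CSV
#'   schema (see [read_bird_records()]).
#' @return The validated data frame, classed \code{bird_records}.
#' @export
bird_records <- function(df) {
  missing_cols <- setdiff(BIRD_CSV_HEADER, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[BIRD_CSV_HEADER]
  fail <- function(bad, field, why) {
    j <- which(bad)
    if (length(j))
      stop(sprintf("schema error: row %d, field '%s': %s", j[1], field, why),
           call. = FALSE)
  }
  fail(is.na(df$bird_id) | !nzchar(df$bird_id), "bird_id", "empty")
  fail(!df$year %in% c(2020, 2021), "year", "must be 2020 or 2021")
  fail(!df$age %in% c("juvenile", "adult"), "age",
       "must be 'juvenile' or 'adult'")
  fail(!df$group %in% c("sham", "treatment"), "group",
       "must be 'sham' or 'treatment'")
  fail(!is.na(df$stopover_nights) &
         (df$stopover_nights < 0 | df$stopover_nights %% 1 != 0),
       "stopover_nights", "must be a non-negative integer")
  fail(!is.na(df$night_fraction) &
         (df$night_fraction < 0 | df$night_fraction > 1),
       "night_fraction", "must be in [0, 1]")
  for (f in c("departure_bearing_deg", "coast_bearing_deg"))
    fail(!is.na(df[[f]]) & (df[[f]] < 0 | df[[f]] >= 360), f,
         "must be in [0, 360)")
  fail(!is.na(df$departed_first_night) & !is.na(df$stopover_nights) &
         df$departed_first_night != (df$stopover_nights == 0),
       "departed_first_night",
       "inconsistent with stopover_nights (first-night departure <=> 0 nights)")
  class(df) <- c("bird_records", "data.frame")
  df
}

#' Read / write bird records as CSV
#'
#' Strict schema: header \code{bird_id,year,age,group,departed_first_night,}
#' \code{stopover_nights,night_fraction,departure_bearing_deg,}
#' \code{coast_bearing_deg,fuel_load}; an empty field is a missing value;
#' \code{departed_first_night} is \code{TRUE}/\code{FALSE}. Validation
#' errors name the offending row and field.
#'
#' @param path CSV file path.
#' @param records A \code{bird_records} data frame (writer).
#' @return A validated \code{bird_records} data frame (reader); \code{path}
#'   invisibly (writer).
#' @export
read_bird_records <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!identical(names(df), BIRD_CSV_HEADER))
    stop("schema error: expected header ",
         paste(BIRD_CSV_HEADER, collapse = ","), call. = FALSE)
  df$departed_first_night <- as.logical(df$departed_first_night)
  bird_records(df)
}

#' @rdname read_bird_records
#' @export
write_bird_records <- function(records, path) {
  records <- bird_records(as.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive the five migratory traits from bird records
#'
#' From each bird's record the battery's five traits are laid out:
#' \describe{
#'   \item{I, departure probability}{first-night departure, for every bird
#'     with a known first-night status;}
#'   \item{II, stopover duration}{nights until departure, for every bird
#'     with a known stopover;}
#'   \item{III, departure timing}{fraction of the night elapsed at
#'     departure;}
#'   \item{IV, departure direction}{bearing off the island, degrees
#'     clockwise from geographic north;}
#'   \item{V, flight-direction consistency}{signed wrapped difference
#'     (coastline-passage bearing minus departure bearing) in
#'     \code{(-180, 180]}; negative = anticlockwise.}
#' }
#' Traits III-V are restricted to birds that departed within
#' \code{departure_window_nights} nights (stopover strictly less than the
#' window, i.e. departure within the first \code{window} nights); traits
#' I-II are unrestricted.
#'
#' @param records A \code{bird_records} data frame (validated on entry).
#' @param departure_window_nights Window for traits III-V (default 10).
#' @return A \code{trait_table} data frame: identifiers, the five trait
#'   columns and the \code{in_window} flag.
#' @export
#' @examples
#' rec <- generate_cohort(cohort_config(n = 12), seed = 7)
#' head(derive_traits(rec))
derive_traits <- function(records, departure_window_nights = 10) {
  records <- bird_records(as.data.frame(records))
  in_window <- !is.na(records$stopover_nights) &
    records$stopover_nights < departure_window_nights
  out <- data.frame(
    bird_id = records$bird_id,
    year = records$year,
    age = records$age,
    group = records$group,
    departed_first_night = records$departed_first_night,
    stopover_nights = records$stopover_nights,
    night_fraction = ifelse(in_window, records$night_fraction, NA_real_),
    departure_bearing = ifelse(in_window, records$departure_bearing_deg,
                               NA_real_),
    consistency_deviation = ifelse(
      in_window & !is.na(records$coast_bearing_deg) &
        !is.na(records$departure_bearing_deg),
      wrap_diff_deg(records$coast_bearing_deg,
                    records$departure_bearing_deg),
      NA_real_),
    fuel_load = records$fuel_load,
    in_window = in_window,
    stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}
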