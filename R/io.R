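# Configuration files, report writing with run manifests, and the
# deterministic seed fan-out shared by every stochastic component.

#' Derive a child seed deterministically
#'
#' All randomness in a run flows from one user-visible seed; components that
#' need independent streams (tie-breaking repetitions, Monte-Carlo
#' repetitions, battery cells) derive child seeds with this mixing function,
#' so each sub-computation can be re-run reproducibly on its own. Values
#' stay within the 32-bit integer range.
#'
#' @param seed Parent seed (integer).
#' @param index Child index (integer >= 0).
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x + 1)
}

CIRCUIT_CONFIG_KEYS <- c("u0_volts", "capacitance_farads",
                         "inductance_henries", "r_total_ohms", "k_mt_per_a",
                         "shutoff", "fall_time_s", "t_d_s")

#' Parse a circuit configuration file
#'
#' Reads a flat key-value file (\code{key = value} lines, \code{#}
#' comments). Recognised keys: \code{u0_volts}, \code{capacitance_farads},
#' \code{inductance_henries}, \code{r_total_ohms}, \code{k_mt_per_a},
#' \code{shutoff} (\code{ramp} or \code{flyback}), \code{fall_time_s},
#' \code{t_d_s}. Unknown keys are rejected; omitted keys fall back to the
#' 2020 device profile defaults; an empty file yields the all-defaults
#' circuit (a message notes it).
#'
#' @param path Config file path.
#' @return A [pulse_circuit()].
#' @export
parse_circuit_config <- function(path) {
  if (!file.exists(path))
    stop("missing-file error: no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("config error: expected 'key = value', got: ", ln, call. = FALSE)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% CIRCUIT_CONFIG_KEYS)
      stop("unknown-key error: '", key, "' is not a circuit key",
           call. = FALSE)
    kv[[key]] <- val
  }
  if (!length(kv)) message("empty circuit config: using built-in defaults")
  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v))
      stop("unit-mismatch error: key '", key, "' must be numeric (",
           kv[[key]], ")", call. = FALSE)
    v
  }
  shutoff <- if (is.null(kv$shutoff)) "ramp" else kv$shutoff
  if (!shutoff %in% c("ramp", "flyback"))
    stop("config error: shutoff must be 'ramp' or 'flyback'", call. = FALSE)
  pulse_circuit(u0 = num("u0_volts", 230),
                capacitance = num("capacitance_farads", 270e-6),
                inductance = num("inductance_henries", 0.170),
                r_total = num("r_total_ohms", 80),
                k_field = num("k_mt_per_a", 24),
                shutoff = shutoff,
                fall_time = num("fall_time_s", 0.69e-3),
                t_d = num("t_d_s", 9e-3))
}

#' Write a results report with a run manifest
#'
#' Serializes a result object to JSON (fixed key order, full precision) or
#' CSV (for data frames), and writes a companion manifest
#' (\code{<path>.manifest.json}) recording the subcommand, configuration
#' snapshot, seed, package version, input/output paths and a timestamp. The
#' report itself contains no timestamp, so identical inputs and seed give a
#' byte-identical report file.
#'
#' @param results A list (JSON) or data frame (JSON or CSV).
#' @param path Output file path.
#' @param format \code{"json"} or \code{"csv"}.
#' @param subcommand,config,seed,inputs Manifest fields.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         subcommand = "report", config = list(), seed = NA,
                         inputs = character(0)) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null", dataframe = "rows")
    } else {
      if (!is.data.frame(results))
        results <- as.data.frame(results)
      utils::write.csv(results, path, row.names = FALSE, na = "")
    }
    TRUE
  }, error = function(e) {
    stop("I/O error writing ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(subcommand = subcommand,
                   config = config,
                   seed = seed,
                   package = "pulsesham",
                   version = as.character(utils::packageVersion("pulsesham")),
                   inputs = as.list(inputs),
                   outputs = list(path),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Path of the report file whose manifest to read (the
#'   \code{.manifest.json} suffix is appended).
#' @return Manifest as a list.
#' @export
read_manifest <- function(path) {
  mp <- paste0(path, ".manifest.json")
  if (!file.exists(mp))
    stop("missing-file error: no manifest at ", mp, call. = FALSE)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}
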