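# CSV/TSV/JSON boundary and run-configuration parsing.
#
# Unit rule at the CSV boundary: the file uses the conventional printed
# units (LMDR/obesity/inactivity in percent, MMR per 100,000 live births,
# neonatal per 1,000 live births); internally every rate is a proportion.
# The single conversion point prevents silent 100x errors.

csv_column_map <- function() {
  c(nation = "nation",
    lmdr_1990 = "lmdr",
    mmr_1990 = "mmr",
    neonatal_mortality_1990 = "neonatal",
    obesity_1990 = "obesity_1990",
    obesity_2016 = "obesity_2016",
    gdp_per_capita = "gdp",
    calorie_intake = "calories",
    insufficient_physical_activity = "inactivity",
    antibiotic_consumption = "antibiotics",
    development_class = "development_class")
}

# percent -> proportion etc., applied on read; inverted on write
csv_unit_divisor <- function() {
  c(lmdr = 100, mmr = 1e5, neonatal = 1e3, obesity_1990 = 100,
    obesity_2016 = 100, inactivity = 100)
}

# parse one numeric CSV column; "<x" below-detection markers become x/2
parse_numeric_cells <- function(x, column, warnings) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  below <- !is.na(x) & grepl("^<", x)
  out <- suppressWarnings(as.numeric(sub("^<", "", x)))
  if (any(below & !is.na(out))) {
    out[below] <- out[below] / 2
    warnings$add(sprintf(
      "column `%s`: %d below-detection cell(s) ('<x') parsed as x/2 (rows %s)",
      column, sum(below), paste(which(below), collapse = ",")))
  }
  malformed <- !is.na(x) & is.na(out)
  if (any(malformed)) {
    warnings$add(sprintf(
      "column `%s`: %d malformed numeric cell(s) set missing (rows %s)",
      column, sum(malformed), paste(which(malformed), collapse = ",")))
  }
  out
}

warning_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$messages <- character(0)
  env$add <- function(msg) {
    env$messages <- c(env$messages, msg)
    warning(msg, call. = FALSE)
  }
  env
}

#' Read a country-level CSV
#'
#' Reads the documented comma-delimited schema (header case-insensitive:
#' `nation, LMDR_1990, MMR_1990, neonatal_mortality_1990, obesity_1990,
#' obesity_2016, GDP_per_capita, calorie_intake,
#' insufficient_physical_activity, antibiotic_consumption,
#' development_class`), converts the printed units to internal
#' proportions, parses `<x` below-detection markers as `x/2`, turns
#' malformed numerics into missing values (with logged row numbers), and
#' sanity-checks units (percent columns within \[0, 100\], MMR
#' non-negative). Unknown columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @return A [country_table()]; parse warnings are attached as the
#'   `warnings` attribute (machine-readable, also emitted as R warnings).
#' @export
read_country_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) {
      stop("schema error: cannot parse country CSV (",
           conditionMessage(e), ")", call. = FALSE)
    })
  if (!nrow(raw) || !ncol(raw)) {
    stop("schema error: empty country CSV, no data rows under the documented schema",
         call. = FALSE)
  }
  if (ncol(raw) == 1 && grepl("[;\t]", names(raw)[1])) {
    stop("wrong delimiter: expected comma-separated columns, header looks like '",
         names(raw)[1], "'", call. = FALSE)
  }
  cmap <- csv_column_map()
  hdr <- tolower(names(raw))
  known <- hdr %in% names(cmap)
  w <- warning_collector()
  if (any(!known)) {
    w$add(paste("unknown column(s) dropped:",
                paste(names(raw)[!known], collapse = ", ")))
  }
  raw <- raw[known]
  names(raw) <- cmap[hdr[known]]
  required <- c("nation", "lmdr", "mmr", "obesity_2016")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("schema error: required column(s) missing from header: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # absent optional columns become all-missing so the pipeline can proceed
  for (v in setdiff(unname(cmap), names(raw))) {
    raw[[v]] <- if (v %in% c("nation", "development_class"))
      NA_character_ else NA_real_
  }
  div <- csv_unit_divisor()
  for (v in setdiff(unname(cmap), c("nation", "development_class"))) {
    vals <- parse_numeric_cells(raw[[v]], v, w)
    if (v %in% names(div) && div[[v]] == 100) {
      out_of_range <- !is.na(vals) & (vals < 0 | vals > 100)
      if (any(out_of_range)) {
        w$add(sprintf("column `%s`: %d value(s) outside [0, 100] percent set missing",
                      v, sum(out_of_range)))
        vals[out_of_range] <- NA_real_
      }
    }
    if (v %in% names(div)) vals <- vals / div[[v]]
    raw[[v]] <- vals
  }
  if (is.na(raw$development_class[1]) &&
      all(is.na(raw$development_class))) {
    raw$development_class <- rep("other", nrow(raw))
  }
  out <- country_table(raw)
  attr(out, "warnings") <- w$messages
  attr(out, "source") <- normalizePath(path)
  out
}

#' Write a country table as CSV in printed units
#'
#' Inverse of [read_country_csv()]: proportions are converted back to the
#' conventional printed units and the documented header is written.
#'
#' @param table A [country_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_csv <- function(table, path) {
  stopifnot(inherits(table, "country_table"))
  cmap <- csv_column_map()
  div <- csv_unit_divisor()
  out <- as.data.frame(table)[unname(cmap)]
  for (v in names(div)) out[[v]] <- out[[v]] * div[[v]]
  names(out) <- names(cmap)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Parse a flat key-value run configuration
#'
#' Reads a minimal YAML-style flat file of `key: value` lines (comments
#' with `#`, blank lines ignored) into a named list; numeric-looking
#' values become numeric. Mortality-schedule keys are prefixed `pre_` /
#' `post_` and architecture keys `arch_`.
#'
#' @param path Config file path.
#' @return Named list of raw key-value pairs.
#' @export
parse_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key: value'): ", ln,
           call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

config_schedule <- function(cfg, prefix) {
  get <- function(key, default) {
    v <- cfg[[paste0(prefix, key)]]
    if (is.null(v)) default else v
  }
  mortality_schedule(
    lmdr = get("lmdr", 0),
    neonatal_rate = get("neonatal_rate", 0),
    rr_maternal = get("rr_maternal", 1),
    rr_perinatal = get("rr_perinatal", 1),
    fertility = get("fertility", 6)
  )
}

#' Build a simulation config from a flat config file
#'
#' Required keys: `transition_generation`, `n_generations`. Optional keys
#' (with defaults): `initial_freq`, `generation_years`,
#' `transition_year`, `mode`, `pop_size`, `seed`, `gain`, `convention`;
#' schedule keys `pre_lmdr`, `pre_neonatal_rate`, `pre_rr_maternal`,
#' `pre_rr_perinatal`, `pre_fertility` and the `post_` equivalents;
#' architecture keys `arch_n_loci`, `arch_effect_per_allele`,
#' `arch_baseline_bmi`, `arch_reference_freq`, `arch_dosage`,
#' `arch_env_sd`, `arch_obesity_threshold`.
#'
#' @param path Config file path.
#' @param seed Optional seed overriding the file's `seed` key.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  cfg <- parse_config_file(path)
  for (key in c("transition_generation", "n_generations")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("invalid config: required key `%s` is missing", key),
           call. = FALSE)
    }
  }
  aget <- function(key, default) {
    v <- cfg[[paste0("arch_", key)]]
    if (is.null(v)) default else v
  }
  arch <- genetic_architecture(
    n_loci = aget("n_loci", 1000L),
    effect_per_allele = aget("effect_per_allele", 0.1),
    baseline_bmi = aget("baseline_bmi", 25),
    reference_freq = aget("reference_freq", 0.10),
    dosage = aget("dosage", "haploid"),
    env_sd = aget("env_sd", 3),
    obesity_threshold = aget("obesity_threshold", 30)
  )
  get <- function(key, default) {
    v <- cfg[[key]]
    if (is.null(v)) default else v
  }
  simulation_config(
    arch = arch,
    pre_schedule = config_schedule(cfg, "pre_"),
    post_schedule = config_schedule(cfg, "post_"),
    transition_generation = cfg$transition_generation,
    n_generations = cfg$n_generations,
    initial_freq = get("initial_freq", 0.10),
    generation_years = get("generation_years", 25),
    transition_year = get("transition_year", 1940),
    mode = get("mode", "deterministic"),
    pop_size = cfg$pop_size,
    seed = if (!is.null(seed)) seed else cfg$seed,
    gain = cfg$gain,
    convention = get("convention", "terminal")
  )
}

#' Run metadata for an output bundle
#'
#' Every numeric artifact the package writes is accompanied by one
#' metadata record sufficient to regenerate it: tool version, seed,
#' timestamp, input-file checksums, the configuration echo, and the
#' machine-readable warnings emitted during the run.
#'
#' @param seed Integer seed used (or `NA`).
#' @param config List echoing the run configuration.
#' @param inputs Character vector of input file paths (checksummed).
#' @param warnings Character vector of warnings emitted.
#' @return List of class `run_metadata`.
#' @export
run_metadata <- function(seed = NA_integer_, config = list(),
                         inputs = character(0),
                         warnings = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(
    list(tool = "obesim",
         version = as.character(utils::packageVersion("obesim")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         config = config,
         input_md5 = sums,
         warnings = warnings),
    class = "run_metadata"
  )
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

write_tsv_artifact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
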