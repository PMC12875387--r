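# CSV schemas and configuration files.
#
# All tables are UTF-8 CSV with a header row and ISO-8601 dates. Undefined
# metrics (IWP without irrigation, PFPN/EF without fertiliser) are written
# as an en dash and read back as NA, mirroring how such cells are printed
# in field-trial reports. Unknown extra columns are preserved on read.

UNDEF <- "–"

check_columns <- function(df, required, what, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

parse_date_col <- function(df, col, what, path) {
  raw <- df[[col]]
  if (inherits(raw, "Date")) return(df)
  parsed <- as.Date(as.character(raw), format = "%Y-%m-%d")
  bad <- which(!is.na(raw) & is.na(parsed))
  if (length(bad)) {
    stop(what, " file ", path, ": malformed date '", raw[bad[1]],
         "' in column ", col, ", row ", bad[1], call. = FALSE)
  }
  df[[col]] <- parsed
  df
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, na = c("", "NA", UNDEF), show_col_types = FALSE,
                  progress = FALSE)
}

#' Read / write a chamber concentration series table
#'
#' Long format, one row per syringe sample: `plot_id`, `gas`, `date`,
#' `chamber_temp_c`, `elapsed_min`, and `concentration` (or `peak_area`).
#'
#' @param path File path.
#' @param x Table to write.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
read_chamber_series <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("plot_id", "gas", "date", "chamber_temp_c", "elapsed_min"),
                "chamber series", path)
  if (!any(c("concentration", "peak_area") %in% names(df))) {
    stop("chamber series file ", path,
         " lacks required column(s): concentration or peak_area", call. = FALSE)
  }
  parse_date_col(df, "date", "chamber series", path)
}

#' @rdname read_chamber_series
#' @export
write_chamber_series <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read / write a flux record table
#'
#' Columns `plot_id`, `gas`, `date`, `flux`, `slope`, `r_squared`,
#' `n_points`, `qc_flag`; flux in the per-gas flux unit.
#'
#' @param path File path.
#' @param x Table to write.
#' @export
read_flux_records <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("plot_id", "gas", "date", "flux", "qc_flag"),
                "flux record", path)
  parse_date_col(df, "date", "flux record", path)
}

#' @rdname read_flux_records
#' @export
write_flux_records <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read / write cumulative-emission tables
#'
#' Plot- or treatment-keyed cumulative emissions with `gas`, `harvest`
#' (0 = whole season) and `gf` / `gf_mean` in kg N ha-1 (N2O) or
#' kg C ha-1 (CO2, CH4).
#'
#' @param path File path.
#' @param x Table to write.
#' @export
read_cumulative <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("gas", "harvest"), "cumulative emission", path)
  df
}

#' @rdname read_cumulative
#' @export
write_cumulative <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read / write per-harvest yield tables
#'
#' Columns `plot_id`, `treatment`, `harvest`, `yield_kg_ha`.
#'
#' @param path File path.
#' @param x Table to write.
#' @export
read_yields <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("plot_id", "treatment", "harvest", "yield_kg_ha"),
                "yield", path)
  df
}

#' @rdname read_yields
#' @export
write_yields <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read / write a treatment metrics table
#'
#' The Table-2/3-shaped report: undefined metrics are written as an en
#' dash and read back as `NA`.
#'
#' @param path File path.
#' @param x Metrics table from [treatment_metrics()].
#' @export
read_metrics <- function(path) {
  df <- read_csv_quiet(path)
  check_columns(df, c("treatment"), "metrics", path)
  df
}

#' @rdname read_metrics
#' @export
write_metrics <- function(x, path) {
  out <- x
  num <- vapply(out, is.numeric, logical(1))
  for (col in names(out)[num]) {
    v <- formatC(out[[col]], format = "fg", digits = 15)
    v <- trimws(v)
    v[is.na(out[[col]])] <- UNDEF
    out[[col]] <- v
  }
  readr::write_csv(out, path)
  invisible(path)
}

# ---- configuration files -------------------------------------------------

# named atomic vectors must serialize as YAML maps, not bare sequences
named_to_list <- function(x) {
  if (is.list(x)) return(lapply(x, named_to_list))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

config_to_list <- function(config) {
  list(
    design = lapply(as.list(config$design), unname),
    calendar = list(
      date = format(config$calendar$date, "%Y-%m-%d"),
      kind = config$calendar$kind,
      fraction = config$calendar$fraction,
      fraction_of = config$calendar$fraction_of
    ),
    season = format(config$season, "%Y-%m-%d"),
    inventory = lapply(as.list(config$inventory), unname),
    emission_factors = as.list(config$emission_factors),
    qc_r2 = config$qc_r2,
    chamber_height_m = config$chamber_height_m,
    gwp_basis = config$gwp_basis,
    flux_basis = config$flux_basis,
    reference_treatment = config$reference_treatment,
    seed = config$seed,
    sim = named_to_list(config$sim)
  )
}

config_from_list <- function(lst) {
  numvec <- function(x) {
    out <- unlist(x)
    storage.mode(out) <- "double"
    out
  }
  chr_na <- function(x) {
    out <- as.character(unlist(lapply(x, function(v) if (is.null(v) || is.na(v)) NA_character_ else v)))
    out
  }
  num_na <- function(x) {
    as.numeric(unlist(lapply(x, function(v) if (is.null(v) || is.na(v)) NA_real_ else v)))
  }
  design <- tibble::as_tibble(lst$design)
  design$replicates <- as.integer(design$replicates)
  calendar <- tibble::tibble(
    date = as.Date(unlist(lst$calendar$date)),
    kind = as.character(unlist(lst$calendar$kind)),
    fraction = num_na(lst$calendar$fraction),
    fraction_of = chr_na(lst$calendar$fraction_of)
  )
  s <- lst$sim
  sim <- sim_params(
    routine_interval_days = s$routine_interval_days,
    event_days = numvec(s$event_days),
    temp = lapply(s$temp, as.numeric),
    rain = lapply(s$rain, as.numeric),
    wfps = list(baseline = numvec(s$wfps$baseline),
                pulse_per_mm = as.numeric(s$wfps$pulse_per_mm),
                decay_rate = as.numeric(s$wfps$decay_rate),
                max = as.numeric(s$wfps$max),
                noise_sd = as.numeric(s$wfps$noise_sd)),
    navail = lapply(s$navail, as.numeric),
    flux = lapply(s$flux, function(b) lapply(b, as.numeric)),
    flux_noise_sd = as.numeric(s$flux_noise_sd),
    conc_noise_sd = numvec(s$conc_noise_sd),
    chamber = list(height_m = as.numeric(s$chamber$height_m),
                   sample_times = numvec(s$chamber$sample_times),
                   air_offset_c = as.numeric(s$chamber$air_offset_c)),
    yield = list(base_harvest = numvec(s$yield$base_harvest),
                 water_mult = numvec(s$yield$water_mult),
                 n_resp_low = numvec(s$yield$n_resp_low),
                 n_resp_high = numvec(s$yield$n_resp_high),
                 n_scale = as.numeric(s$yield$n_scale),
                 noise_sd = as.numeric(s$yield$noise_sd)),
    soil = lapply(s$soil, as.numeric)
  )
  campaign_config(
    design = design,
    calendar = calendar,
    season = as.Date(unlist(lst$season)),
    inventory = tibble::as_tibble(lst$inventory),
    emission_factors = numvec(lst$emission_factors),
    qc_r2 = as.numeric(lst$qc_r2),
    chamber_height_m = as.numeric(lst$chamber_height_m),
    gwp_basis = lst$gwp_basis,
    flux_basis = lst$flux_basis,
    reference_treatment = lst$reference_treatment,
    seed = as.integer(lst$seed),
    sim = sim
  )
}

#' Write / read a campaign configuration file (YAML)
#'
#' The configuration carries the factorial design, management calendar,
#' input inventory and emission factors, QC thresholds, unit-basis
#' switches, chamber geometry, the master seed and all simulation
#' parameters. Write followed by read reproduces the configuration
#' exactly.
#'
#' @param config A `campaign_config`.
#' @param path File path (YAML).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse config file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  config_from_list(lst)
}
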