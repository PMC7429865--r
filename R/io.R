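## Scenario configuration (YAML), report writing and logging.

# Canonical default configuration: reproduces the reference tables exactly.
default_config_list <- function() {
  list(
    roster = list(
      n_crew = 4L,
      sampler = "fixed",
      statures = REFERENCE_STATURES,
      lo = 1.50, hi = 1.90, mean = 1.70, sd = 0.07,
      seed = 1L
    ),
    crew = list(
      age = DEFAULT_AGE,
      bmi = DEFAULT_BMI,
      vo2max_rel = DEFAULT_VO2MAX_REL,
      vo2_rest_rel = DEFAULT_VO2_REST_REL,
      rer_rest = DEFAULT_RER_REST,
      rer_exercise = DEFAULT_RER_EXERCISE
    ),
    environment = list(
      air_temp = 22, relative_humidity = 0.55, barometric_pressure = 760,
      air_velocity = 0.5, core_temp = 37, skin_temp = 35,
      clothing_thermal_resistance = 0.06,
      clothing_evaporative_resistance = 0.01,
      hc_coef = 8.3, hc_exp = 0.6, hr = 4.7, fcl = 1.1, lewis = 16.5
    ),
    prescription = list(
      intensity_fraction = 0.75, bout_duration = 30, bouts_per_day = 2L,
      days_per_week = 6L, epoc_fraction = 0.06
    ),
    energy = list(pal = DEFAULT_PAL, tem_kcal = DEFAULT_TEM_KCAL),
    intake = list(
      protein = DEFAULT_PROTEIN_G,
      sodium = DEFAULT_SODIUM_MG,
      potassium = DEFAULT_POTASSIUM_MG
    ),
    durations = REFERENCE_DURATIONS,
    variant = list(
      heat = "basal",            # or "consistent": PAL factor on 24-h heat
      strict_schedule = FALSE,   # honour days_per_week < 7
      iwn_basis = "weir_rest"    # or "tee"
    )
  )
}

# internal: merge user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop(sprintf("config section `%s` must be a mapping",
                 paste(path, collapse = ".")), call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(c(path, unknown[1]), collapse = ".")), call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

# internal: validate a fully merged config by exercising the constructors
validate_config <- function(cfg) {
  if (!length(cfg$durations) || any(cfg$durations <= 0)) {
    stop_domain("durations", "must all be positive")
  }
  spec <- do.call(roster_spec, c(
    cfg$roster[c("n_crew", "sampler", "statures", "lo", "hi", "mean", "sd", "seed")],
    list(shared_params = cfg$crew)
  ))
  # probe member: surfaces invalid crew physiology (bmi, age, RERs) early
  do.call(crew_member, c(list(stature = 1.70), cfg$crew))
  env <- do.call(cabin_environment, cfg$environment)
  presc <- do.call(exercise_prescription, cfg$prescription)
  if (cfg$energy$pal < 1) stop_domain("energy.pal", "must be >= 1")
  check_nonnegative(cfg$energy$tem_kcal, "energy.tem_kcal")
  for (nm in c("protein", "sodium", "potassium")) {
    check_nonnegative(cfg$intake[[nm]], paste0("intake.", nm))
  }
  if (!cfg$variant$heat %in% c("basal", "consistent")) {
    stop_domain("variant.heat", "must be \"basal\" or \"consistent\"")
  }
  if (!cfg$variant$iwn_basis %in% c("weir_rest", "tee")) {
    stop_domain("variant.iwn_basis", "must be \"weir_rest\" or \"tee\"")
  }
  if (!is.logical(cfg$variant$strict_schedule)) {
    stop_domain("variant.strict_schedule", "must be true/false")
  }
  list(config = cfg, roster_spec = spec, environment = env, prescription = presc)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file, fills every omitted field with the package
#' default (the reference study conditions: BMI 26.5 kg/m^2, age 40 y,
#' 43.4 mL/kg/min, 22 degC / 55\% RH cabin, two 30-min bouts at 75\% VO2max,
#' ...), rejects unknown keys and validates values.  An empty file yields
#' the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated object of class `scenario_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(default_config_list(), user)
  parts <- validate_config(cfg)
  structure(parts, class = "scenario_config")
}

#' Write a scenario configuration back to YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config A `scenario_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(config$config, path)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<scenario_config> %d crew (%s), durations %s d, variant %s/%s%s\n",
    cfg$roster$n_crew, cfg$roster$sampler,
    paste(cfg$durations, collapse = "/"),
    cfg$variant$heat, cfg$variant$iwn_basis,
    if (cfg$variant$strict_schedule) ", strict schedule" else ""
  ))
  invisible(x)
}

# internal: md5 of the canonical YAML rendering of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config$config, tmp)
  unname(tools::md5sum(tmp))
}

# internal: write a data.frame as CSV with a provenance comment header
write_report_csv <- function(df, path, hash, seed) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# crewmet %s config_hash=%s seed=%d",
                     as.character(utils::packageVersion("crewmet")), hash, seed),
             con)
  utils::write.csv(df, con, row.names = FALSE)
}

round_cols <- function(df, digits) {
  for (nm in names(digits)) df[[nm]] <- round(df[[nm]], digits[[nm]])
  df
}

#' Run the full reporting pipeline
#'
#' Generates the roster, evaluates the per-person, per-bout, per-day and
#' per-mission tables under the configured variant flags, and writes
#' `table1.csv` ... `table4.csv`, `figure_series.csv`, `summary.json` and
#' `run.log` to the output directory.  Table CSVs are rounded to the
#' reference tables' printed precision; `figure_series.csv` and the JSON
#' summary carry unrounded values.  Every output embeds the configuration
#' hash, so identical configurations give byte-identical outputs.
#'
#' @param config A `scenario_config` from [load_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the computed tables and output paths.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config$config
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop(sprintf("cannot create output directory: %s", outdir), call. = FALSE)
    }
  }
  hash <- config_hash(config)
  seed <- cfg$roster$seed
  env <- config$environment
  presc <- config$prescription
  crew_args <- cfg$crew
  log_lines <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    n <- if (is.data.frame(value)) nrow(value) else length(value)
    log_lines <<- c(log_lines,
                    sprintf("stage=%s elapsed_s=%.3f rows=%d", name, dt, n))
    value
  }

  roster <- stage("roster", generate_roster(config$roster_spec))
  statures <- vapply(roster, `[[`, numeric(1), "stature")
  # per-person tables span the configured stature grid (not truncated by
  # crew size); stochastic samplers report the statures actually drawn
  grid_statures <- if (cfg$roster$sampler == "fixed") {
    sort(unique(cfg$roster$statures))
  } else {
    sort(unique(statures))
  }

  t1 <- stage("table1", do.call(characteristics_table, c(
    list(statures = grid_statures, env = env,
         intensity_fraction = presc$intensity_fraction,
         pal = cfg$energy$pal, tem_kcal = cfg$energy$tem_kcal,
         iwn_basis = cfg$variant$iwn_basis),
    crew_args
  )))
  t2 <- stage("table2", do.call(bout_table, c(
    list(statures = grid_statures, env = env, prescription = presc),
    crew_args
  )))
  t3 <- stage("table3", do.call(daily_table, c(
    list(statures = grid_statures, env = env, prescription = presc,
         heat_variant = cfg$variant$heat, iwn_basis = cfg$variant$iwn_basis),
    crew_args
  )))
  t4 <- stage("table4", delta_table(
    durations = range(cfg$durations), n_crew = cfg$roster$n_crew,
    env = env, prescription = presc,
    strict_schedule = cfg$variant$strict_schedule,
    heat_variant = cfg$variant$heat, iwn_basis = cfg$variant$iwn_basis
  ))
  fs <- stage("figure_series", figure_series(
    env = env,
    strict_schedule = cfg$variant$strict_schedule,
    heat_variant = cfg$variant$heat, iwn_basis = cfg$variant$iwn_basis
  ))

  paths <- list(
    table1 = file.path(outdir, "table1.csv"),
    table2 = file.path(outdir, "table2.csv"),
    table3 = file.path(outdir, "table3.csv"),
    table4 = file.path(outdir, "table4.csv"),
    figure_series = file.path(outdir, "figure_series.csv"),
    summary = file.path(outdir, "summary.json"),
    log = file.path(outdir, "run.log")
  )
  write_report_csv(round_cols(t1, c(
    body_mass = 1, bsa = 2, vo2max_abs = 2, rmr = 2, neat = 2,
    vo2_rest = 3, vco2_rest = 3, mprod_basal = 1, basal_fluid = 2,
    vo2_ex = 2, vco2_ex = 2, ee_ex = 1, mprod_ex = 0, sweat_rate = 1
  )), paths$table1, hash, seed)
  write_report_csv(round_cols(t2, c(
    energy_mj = 2, o2_l = 1, co2_l = 1, heat_kj = 0, sweat_ml = 0
  )), paths$table2, hash, seed)
  write_report_csv(round_cols(t3, c(
    tee_mj = 1, o2_l = 0, co2_l = 0, heat_mj = 1, water_l = 2
  )), paths$table3, hash, seed)
  write_report_csv(round_cols(t4, c(
    energy_mj = 0, o2_l = 0, co2_l = 0, heat_mj = 1, water_l = 1
  )), paths$table4, hash, seed)
  write_report_csv(fs, paths$figure_series, hash, seed)

  summary <- list(
    package = "crewmet",
    version = as.character(utils::packageVersion("crewmet")),
    config_hash = hash,
    seed = seed,
    variant = cfg$variant,
    n_crew = cfg$roster$n_crew,
    statures = statures,
    durations = cfg$durations,
    tables = list(table1 = t1, table2 = t2, table3 = t3, table4 = t4)
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("crewmet %s config_hash=%s seed=%d",
            summary$version, hash, seed),
    log_lines
  ), paths$log)

  invisible(list(
    tables = list(table1 = t1, table2 = t2, table3 = t3, table4 = t4,
                  figure_series = fs),
    paths = paths,
    config_hash = hash
  ))
}
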