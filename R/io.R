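# Shared IO plumbing: schema-validated CSV readers/writers, JSON configs and
# the end-to-end demo pipeline. CSV dialect: comma-separated, UTF-8, header
# row mandatory, '.' decimal; JSON for all nested structures.

# column schemas for the trace dialects used across modules
trace_schemas <- function() {
  list(
    force_trace = list(required = c("time_s", "dr_um", "force_pN"),
                       optional = "tension_pN_per_um", time = "time_s"),
    probe_response = list(required = c("time_s", "delta_sigma_pN_per_um"),
                          optional = character(), time = "time_s"),
    frap = list(required = c("time_s", "intensity_au"),
                optional = "F_norm", time = "time_s"),
    frames = list(required = c("time_s", "base_x_um", "base_y_um",
                               "bead_x_um", "bead_y_um", "force_pN"),
                  optional = character(), time = "time_s"),
    contours = list(required = c("frame", "idx", "x_um", "y_um"),
                    optional = character(), time = NULL),
    stimulus = list(required = c("time_s", "tension_pN_per_um", "dF_over_F"),
                    optional = character(), time = "time_s")
  )
}

#' Read a schema-validated trace CSV
#'
#' Reads a CSV and validates it against one of the package's named column
#' schemas: required columns present and numeric, time strictly increasing
#' where applicable, and no missing-value runs. Errors name the offending
#' field.
#'
#' @param path CSV file path.
#' @param schema Schema name: one of `"force_trace"`, `"probe_response"`,
#'   `"frap"`, `"frames"`, `"contours"`, `"stimulus"`.
#' @return A validated tibble.
#' @export
read_trace <- function(path, schema = names(trace_schemas())) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "memtide_io_error")
  }
  sc <- trace_schemas()[[schema]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, sc$required, path)
  for (col in intersect(c(sc$required, sc$optional), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("Column `%s` in %s is not numeric.", col, path),
            class = "memtide_schema_error")
    }
    if (anyNA(v)) {
      abort(sprintf("Column `%s` in %s contains missing values.", col, path),
            class = "memtide_schema_error")
    }
  }
  if (!is.null(sc$time)) check_time_monotone(df[[sc$time]], sc$time)
  df
}

#' Write a trace CSV
#'
#' Writes numeric columns serialized to 12 significant digits so that
#' read-write-read roundtrips are bit-stable.
#'
#' @param df Data frame to write.
#' @param path Output CSV path.
#' @param digits Significant digits; default 12.
#' @return `path`, invisibly.
#' @export
write_trace <- function(df, path, digits = 12) {
  out <- as_tibble(df) |>
    mutate(across(dplyr::where(is.numeric), ~ signif(.x, digits)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Validated bundle of package-wide constants, seed and logging verbosity
#' for [run_pipeline()]. Unknown constant names are rejected.
#'
#' @param seed Integer seed.
#' @param constants Named list overriding entries of [memtide_constants()].
#' @param scenario Default scenario for the generated experiments.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, constants = list(),
                       scenario = "bipolar_terminal") {
  base <- memtide_constants()
  unknown <- setdiff(names(constants), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown constant(s): %s.", paste(unknown, collapse = ", ")),
          class = "memtide_config_error")
  }
  merged <- modifyList(base, constants)
  for (nm in names(merged)) {
    check_number(merged[[nm]], nm, positive = TRUE, allow_vector = FALSE)
  }
  structure(list(seed = as.integer(seed), constants = merged,
                 scenario = scenario),
            class = "run_config")
}

#' Read a protocol JSON file
#'
#' Fields: `extend_speed_um_s`, `extend_distance_um`, `hold_s`,
#' `retract_speed_um_s`, `tether_radius_um`, `start_s` (all optional;
#' defaults from [pull_protocol()]).
#'
#' @param path JSON file path.
#' @return A [pull_protocol()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "memtide_io_error")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pull_protocol(
    extend_speed = j$extend_speed_um_s %||% 1,
    extend_distance = j$extend_distance_um %||% 40,
    hold_time = j$hold_s %||% 30,
    retract_speed = j$retract_speed_um_s %||% 1,
    tether_radius = j$tether_radius_um %||% radius_from_force(10),
    start_time = j$start_s %||% 0
  )
}

#' Run the full synthetic demo pipeline
#'
#' Generates one instance of each of the four synthetic experiments
#' (double-tether, FRAP, drag, stimulation) for the configured scenario,
#' runs the corresponding analysis on each, and collects stage results plus
#' provenance (seed, package version, config hash) into one document.
#'
#' @param config A [run_config()].
#' @param out_path Optional path to write the results JSON.
#' @return Results list with elements `provenance`, `double_tether`,
#'   `frap`, `drag`, `stimulus`.
#' @export
run_pipeline <- function(config = run_config(), out_path = NULL) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config().", class = "memtide_config_error")
  }
  sc <- config$scenario
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "memtide_pipeline_error")
    })
  }

  gcfg <- generator_config(seed = config$seed, scenario = sc)
  dt_stage <- stage("double_tether", {
    gen <- gen_double_tether(gcfg)
    meas <- tibble(
      time_s = gen$trace$time_s,
      delta_sigma_pN_per_um = gen$trace$tension_pN_per_um - gen$truth$sigma0
    )
    fit <- fit_dsigma(meas, pull_protocol(), membrane_model(D_sigma = 1),
                      d = gen$truth$d)
    list(truth_D_sigma = gen$truth$D_sigma, D_sigma_hat = fit$D_sigma_hat,
         identifiable = fit$identifiable, n = nrow(meas))
  })
  frap_stage <- stage("frap", {
    gen <- gen_frap(generator_config(seed = config$seed + 1, scenario = sc))
    fit <- fit_recovery(gen$curve, A_bleach = config$constants$A_bleach)
    list(truth = gen$truth[c("D_t", "immobile_fraction", "t_half")],
         D_t_hat = fit$D_t, immobile_hat = fit$immobile_fraction,
         t_half_hat = fit$t_half,
         phi_hat = obstacle_fraction(fit$immobile_fraction,
                                     config$constants$protein_area_coverage),
         n = nrow(gen$curve))
  })
  drag_stage <- stage("drag", {
    gen <- gen_drag_track(generator_config(seed = config$seed + 2, scenario = sc),
                          motif = "stick_slip")
    track <- drag_track(gen$frames, gen$contour)
    stalls <- stall_segments(track, v_noise = config$constants$v_noise)
    list(truth_peaks = gen$truth$stall_windows$f_peak,
         detected = stalls[stalls$reliable, ],
         n = nrow(gen$frames))
  })
  stim_stage <- stage("stimulus", {
    gen <- gen_stimulus(generator_config(seed = config$seed + 3, scenario = sc,
                                         sampling_rate = 1))
    rf <- recovered_fraction(gen$trace)
    r <- calcium_tension_anticorrelation(gen$trace)
    list(truth_efficiency = gen$truth$endo_efficiency,
         recovered_fraction = rf, ca_tension_cor = r,
         n = nrow(gen$trace))
  })

  results <- list(
    provenance = list(
      seed = config$seed,
      scenario = sc,
      package_version = as.character(packageVersion("memtide")),
      config_hash = hash(config)
    ),
    double_tether = dt_stage,
    frap = frap_stage,
    drag = drag_stage,
    stimulus = stim_stage
  )
  if (!is.null(out_path)) {
    jsonlite::write_json(results, out_path, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE)
  }
  results
}
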