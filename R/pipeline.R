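#' Configure the full ARDL analysis pipeline
#'
#' A serializable description of one complete run: data source, transforms,
#' decision levels, model orders, shock scenarios and seeds. The same config
#' and input always reproduce identical outputs; the single `seed` fans out
#' deterministically to per-scenario seeds.
#'
#' @param input Path to a monthly CSV (see [read_fire_csv()]), or `NULL` when
#'   `data` is supplied directly.
#' @param data Optional `fire_ts` used instead of reading `input`.
#' @param schema,window Passed to [read_fire_csv()].
#' @param apply_log Log-transform the series before analysis (set `FALSE`
#'   when the input is already on the log scale).
#' @param log_offset Named offsets for [log_transform()].
#' @param level Decision significance level for unit-root and bounds tests.
#' @param dependent Dependent variable of the headline model.
#' @param p,q ARDL error-correction orders (see [ecm_spec()]).
#' @param max_lag VAR lag-selection search bound.
#' @param scenarios List of [shock_scenario()]s to simulate (may be empty).
#' @param diagnostics_lags Lag count for ARCH / Breusch-Godfrey tests.
#' @param force_i2 Continue past an I(2) classification instead of stopping.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, data = NULL, schema = NULL,
                            window = NULL, apply_log = TRUE, log_offset = NULL,
                            level = 0.05, dependent = "area_burned",
                            p = 1, q = 1, max_lag = 3,
                            scenarios = list(), diagnostics_lags = 1,
                            force_i2 = FALSE, seed = 1) {
  if (is.null(input) && is.null(data)) {
    stop("either 'input' or 'data' must be given", call. = FALSE)
  }
  structure(list(input = input, data = data, schema = schema, window = window,
                 apply_log = apply_log, log_offset = log_offset, level = level,
                 dependent = dependent, p = p, q = q, max_lag = max_lag,
                 scenarios = scenarios, diagnostics_lags = diagnostics_lags,
                 force_i2 = force_i2, seed = seed),
            class = "pipeline_config")
}

#' Run the complete fire-climate ARDL workflow
#'
#' Executes, in order: data loading, log transform, integration-order
#' classification of every variable (halting if any series is I(2), since
#' bounds testing requires I(0)/I(1) variables), VAR lag selection, the
#' error-correction model rotation, bounds cointegration tests, long- and
#' short-run elasticities of the headline model, residual and stability
#' diagnostics, seasonal correlations, and any configured shock simulations.
#'
#' @param config A [pipeline_config()].
#' @return An `ardl_report` list with one element per stage and a `manifest`
#'   of logged events (dropped rows, excluded draws, flags).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  ds <- if (!is.null(config$data)) config$data else {
    read_fire_csv(config$input, schema = config$schema, window = config$window)
  }
  if (!is.null(attr(ds, "load_log"))) manifest$load <- attr(ds, "load_log")
  if (config$apply_log) ds <- log_transform(ds, offset = config$log_offset)

  vars <- setdiff(names(ds), "date")
  unit_roots <- unit_root_table(ds, level = config$level)
  i2 <- unit_roots$variable[unit_roots$i2_flag]
  if (length(i2) && !config$force_i2) {
    stop("I(2) variable(s) detected: ", paste(i2, collapse = ", "),
         "; bounds testing invalid (use force_i2 = TRUE to override)",
         call. = FALSE)
  }
  if (length(i2)) manifest$i2_override <- i2

  lag_sel <- var_lag_selection(ds, max_lag = config$max_lag)

  vars_ordered <- c(config$dependent, setdiff(vars, config$dependent))
  fits <- rotate_models(ds, variables = vars_ordered, p = config$p, q = config$q)
  bounds <- bounds_table(fits, level = config$level)
  main_fit <- fits[[config$dependent]]
  long_run <- long_run_coefficients(main_fit)
  short_run <- short_run_coefficients(main_fit)
  if (attr(long_run, "no_error_correction")) {
    manifest$no_error_correction <- TRUE
  }
  diagnostics <- diagnostics_report(main_fit, lags = config$diagnostics_lags)
  seasonal <- seasonal_correlations(ds, response = config$dependent)

  sims <- list()
  if (length(config$scenarios)) {
    for (i in seq_along(config$scenarios)) {
      sc <- config$scenarios[[i]]
      sc$seed <- (config$seed + 1000L * i) %% .Machine$integer.max
      sims[[sc$variable]] <- simulate_response(main_fit, ds, sc)
      if (sims[[sc$variable]]$exclusion_rate > 0) {
        manifest$excluded_draws[[sc$variable]] <-
          sims[[sc$variable]]$exclusion_rate
      }
    }
  }

  structure(list(data = ds, unit_roots = unit_roots, lag_selection = lag_sel,
                 fits = fits, bounds = bounds, long_run = long_run,
                 short_run = short_run, diagnostics = diagnostics,
                 seasonal = seasonal, simulations = sims,
                 config = config, manifest = manifest),
            class = "ardl_report")
}

#' @export
print.ardl_report <- function(x, ...) {
  cat("ARDL fire-climate analysis report\n")
  cat(sprintf("  %d months, %d variables; dependent: %s\n",
              nrow(x$data), ncol(x$data) - 1, x$config$dependent))
  cat(sprintf("  chosen VAR lag: %d\n", x$lag_selection$chosen))
  main <- x$bounds[x$bounds$dependent == x$config$dependent, ]
  cat(sprintf("  bounds test: F = %.2f -> %s\n", main$F, main$decision))
  cat(sprintf("  ECM(-1) = %.3f\n", attr(x$short_run, "ect")))
  cat(sprintf("  %d shock simulation(s)\n", length(x$simulations)))
  invisible(x)
}

#' Machine-readable summary of a pipeline report
#'
#' Deterministic JSON snapshot of every numeric result; identical configs and
#' inputs yield byte-identical summaries.
#'
#' @param report An `ardl_report`.
#' @param path Optional path to write the JSON to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_summary_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ardl_report"))
  sims <- lapply(report$simulations, function(s) {
    list(bands = s$bands, exclusion_rate = s$exclusion_rate,
         shock_period = s$shock_period)
  })
  obj <- list(
    n_obs = nrow(report$data),
    unit_roots = report$unit_roots,
    lag_selection = list(table = report$lag_selection$table,
                         chosen = report$lag_selection$chosen),
    bounds = report$bounds,
    long_run = as.data.frame(report$long_run),
    short_run = as.data.frame(report$short_run),
    ect = attr(report$short_run, "ect"),
    diagnostics = list(
      dw = report$diagnostics$dw,
      arch = report$diagnostics$arch, bg = report$diagnostics$bg,
      reset = report$diagnostics$reset, jb = report$diagnostics$jb,
      cusum_within = report$diagnostics$cusum$cusum_within,
      cusumsq_within = report$diagnostics$cusum$cusumsq_within),
    seasonal = report$seasonal,
    simulations = sims,
    manifest = report$manifest
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write the report's tables as CSV files
#'
#' One file per result table, with stable column ordering so reruns are
#' byte-identical: unit roots, lag selection, bounds, long- and short-run
#' coefficients, seasonal correlations, diagnostics, CUSUM paths, and one
#' band file per simulated scenario. Missing sections are skipped and
#' reported in the returned flag list.
#'
#' @param report An `ardl_report`.
#' @param dir Output directory (created if absent).
#' @return Invisible list with `files` written and `missing` sections.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "ardl_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  missing <- character(0)
  put(report$unit_roots, "unit_roots")
  put(report$lag_selection$table, "lag_selection")
  put(report$bounds, "bounds")
  put(as.data.frame(report$long_run), "long_run")
  put(as.data.frame(report$short_run), "short_run")
  put(report$seasonal, "seasonal_correlations")
  d <- report$diagnostics
  put(data.frame(test = c("durbin_watson", "arch_lm", "breusch_godfrey",
                          "ramsey_reset", "jarque_bera"),
                 statistic = c(d$dw, d$arch$statistic, d$bg$statistic,
                               d$reset$statistic, d$jb$statistic),
                 p.value = c(NA, d$arch$p.value, d$bg$p.value,
                             d$reset$p.value, d$jb$p.value)),
      "diagnostics")
  put(d$cusum$cusum, "cusum")
  put(d$cusum$cusumsq, "cusumsq")
  if (length(report$simulations)) {
    for (v in names(report$simulations)) {
      put(report$simulations[[v]]$bands, paste0("bands_", v))
    }
  } else {
    missing <- c(missing, "simulation bands (no scenarios configured)")
  }
  invisible(list(files = files, missing = missing))
}
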