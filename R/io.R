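#' Canonical variable names for a fire-climate dataset
#'
#' The monthly fire-climate table analysed by this package carries the burned
#' area response, the combined fire carbon-emission/biomass-burned series, and
#' six climate drivers. Input files may use arbitrary column headers; a schema
#' mapping (see [read_fire_csv()]) renames them onto these canonical names.
#'
#' @return Character vector of the eight canonical variable names.
#' @export
fire_variables <- function() {
  c("area_burned", "cem", "rel_humidity", "t_min", "t_max",
    "precip", "sunlight", "wind")
}

#' Construct a monthly fire-climate time-series dataset
#'
#' A `fire_ts` is a data frame with a `date` column (first day of each month)
#' and one or more numeric series, plus a per-variable record of the transform
#' applied so far (`"raw"`, `"log"` with an offset, or `"diff"`). Months must
#' be unique and strictly increasing, and no value may be missing.
#'
#' @param df Data frame with a `date` column (`Date`, or `"YYYY-MM"` strings)
#'   and numeric series columns.
#' @param transform Optional named list of per-variable transform records, as
#'   produced by [log_transform()]. Defaults to `"raw"` for every variable.
#' @return An object of class `fire_ts`.
#' @export
fire_ts <- function(df, transform = NULL) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("'df' must be a non-empty data frame", call. = FALSE)
  }
  if (!"date" %in% names(df)) stop("'df' must contain a 'date' column", call. = FALSE)
  date <- parse_month(df$date)
  if (anyNA(date)) stop("unparseable month in 'date' column", call. = FALSE)
  key <- format(date, "%Y-%m")
  if (anyDuplicated(key)) {
    stop("duplicate month(s): ", paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(date)
  df <- df[ord, , drop = FALSE]
  date <- date[ord]
  vars <- setdiff(names(df), "date")
  for (v in vars) {
    if (!is.numeric(df[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[v]])))))
      stop(sprintf("non-numeric value in column '%s' (row %s)", v,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (anyNA(df[[v]])) {
      stop(sprintf("missing value in column '%s'", v), call. = FALSE)
    }
  }
  out <- data.frame(date = date, df[vars], check.names = FALSE)
  rownames(out) <- NULL
  if (is.null(transform)) {
    transform <- stats::setNames(rep(list(list(type = "raw")), length(vars)), vars)
  }
  structure(out, class = c("fire_ts", "data.frame"), transform = transform)
}

parse_month <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  x <- as.character(x)
  as.Date(paste0(x, "-01"), format = "%Y-%m-%d")
}

#' @export
print.fire_ts <- function(x, ...) {
  vars <- setdiff(names(x), "date")
  tr <- transform_state(x)
  cat(sprintf("Monthly fire-climate series: %d months (%s to %s), %d variables\n",
              nrow(x), format(x$date[1], "%Y-%m"),
              format(x$date[nrow(x)], "%Y-%m"), length(vars)))
  lab <- vapply(vars, function(v) {
    s <- tr[[v]]
    if (is.null(s) || s$type == "raw") v
    else if (s$type == "log" && isTRUE(s$offset != 0)) sprintf("%s [log+%g]", v, s$offset)
    else sprintf("%s [%s]", v, s$type)
  }, character(1))
  cat("  ", paste(lab, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-variable transform state of a dataset
#'
#' @param x A `fire_ts`.
#' @return Named list with one record per variable (`type`, and `offset` for
#'   log-transformed series).
#' @export
transform_state <- function(x) {
  stopifnot(inherits(x, "fire_ts"))
  attr(x, "transform")
}

#' Read a monthly fire-climate CSV
#'
#' Expects a rectangular CSV with an ISO `"YYYY-MM"` date column plus numeric
#' series. Columns may be renamed onto the canonical variables through
#' `schema`; rows with any missing mapped value are dropped (no imputation)
#' and counted in the attached load log, as are rows outside the requested
#' date window.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical name to the
#'   file's column header, e.g. `c(t_max = "Tmax")`. Unmapped canonical names
#'   are looked up verbatim.
#' @param date_col Name of the date column in the file (default `"date"`).
#' @param window Optional length-2 character vector `c("YYYY-MM", "YYYY-MM")`
#'   retaining only months inside the closed interval. `NULL` keeps all rows.
#' @param variables Canonical variables to load; defaults to every mapped or
#'   canonical column present in the file.
#' @return A [fire_ts()] with attribute `"load_log"` recording dropped rows.
#' @export
read_fire_csv <- function(path, schema = NULL, date_col = "date",
                          window = NULL, variables = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty table: ", path, call. = FALSE)
  if (!date_col %in% names(raw)) {
    stop(sprintf("date column '%s' not found", date_col), call. = FALSE)
  }
  cols <- setdiff(names(raw), date_col)
  map <- stats::setNames(cols, cols)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src)) {
      stop("schema refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    map <- map[!map %in% schema]          # drop columns claimed by the schema
    map <- c(stats::setNames(unname(schema), names(schema)), map)
  }
  if (is.null(variables)) variables <- names(map)
  map <- map[variables]
  df <- data.frame(date = raw[[date_col]], check.names = FALSE)
  for (v in names(map)) {
    col <- raw[[map[[v]]]]
    if (is.numeric(col)) {
      df[[v]] <- col
    } else {
      chr <- as.character(col)
      num <- suppressWarnings(as.numeric(chr))
      bad <- which(!is.na(chr) & nzchar(chr) & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d ('%s')",
                     map[[v]], bad[1], chr[bad[1]]), call. = FALSE)
      }
      df[[v]] <- num
    }
  }
  n0 <- nrow(df)
  keep <- stats::complete.cases(df[names(map)])
  n_missing <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  date <- parse_month(df$date)
  if (anyNA(date)) stop("unparseable month in date column", call. = FALSE)
  n_window <- 0L
  if (!is.null(window)) {
    lo <- parse_month(window[1]); hi <- parse_month(window[2])
    inside <- date >= lo & date <= hi
    n_window <- sum(!inside)
    df <- df[inside, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no rows remain after filtering", call. = FALSE)
  out <- fire_ts(df)
  attr(out, "load_log") <- list(rows_in_file = n0, dropped_missing = n_missing,
                                dropped_outside_window = n_window)
  out
}

#' Write a fire-climate dataset as CSV
#'
#' Emits the same dialect [read_fire_csv()] reads: an ISO `"YYYY-MM"` date
#' column followed by the series at full double precision, so that a
#' write/read round trip reproduces the dataset exactly.
#'
#' @param x A `fire_ts`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fire_csv <- function(x, path) {
  stopifnot(inherits(x, "fire_ts"))
  df <- as.data.frame(x)
  df$date <- format(df$date, "%Y-%m")
  for (v in setdiff(names(df), "date")) {
    df[[v]] <- sprintf("%.17g", df[[v]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Natural-log transform with per-variable offsets
#'
#' Applies `ln(value + offset)` to each requested series. Offsets exist for
#' series with structural zeros: months with no fires record zero burned area
#' and zero emissions, so those two variables default to an offset of one unit
#' (making a no-fire month map to `ln(1) = 0`). All other variables default to
#' offset zero.
#'
#' @param x A `fire_ts`.
#' @param offset Named numeric vector of non-negative offsets; unnamed default
#'   applies 1 to `area_burned` and `cem`, 0 elsewhere.
#' @param variables Variables to transform (default: all currently raw).
#' @return The transformed `fire_ts`; `transform_state()` records the offsets.
#' @export
log_transform <- function(x, offset = NULL, variables = NULL) {
  stopifnot(inherits(x, "fire_ts"))
  tr <- transform_state(x)
  vars <- setdiff(names(x), "date")
  if (is.null(variables)) {
    variables <- vars[vapply(vars, function(v) tr[[v]]$type == "raw", logical(1))]
  }
  off <- stats::setNames(rep(0, length(variables)), variables)
  default_off <- c(area_burned = 1, cem = 1)
  hit <- intersect(names(default_off), variables)
  off[hit] <- default_off[hit]
  if (!is.null(offset)) {
    if (is.null(names(offset))) stop("'offset' must be named", call. = FALSE)
    off[intersect(names(offset), variables)] <-
      offset[intersect(names(offset), variables)]
  }
  if (any(off < 0)) stop("offsets must be non-negative", call. = FALSE)
  for (v in variables) {
    vals <- x[[v]] + off[[v]]
    if (any(vals <= 0)) {
      bad <- format(x$date[vals <= 0], "%Y-%m")
      stop(sprintf("log undefined for '%s' (value + offset <= 0) in: %s",
                   v, paste(bad, collapse = ", ")), call. = FALSE)
    }
    x[[v]] <- log(vals)
    tr[[v]] <- list(type = "log", offset = unname(off[[v]]))
  }
  attr(x, "transform") <- tr
  x
}

#' Invert the log transform of selected series
#'
#' @param x A `fire_ts` with log-transformed series.
#' @param variables Variables to back-transform (default: all logged ones).
#' @return `fire_ts` on the original scale.
#' @export
unlog_transform <- function(x, variables = NULL) {
  stopifnot(inherits(x, "fire_ts"))
  tr <- transform_state(x)
  vars <- setdiff(names(x), "date")
  if (is.null(variables)) {
    variables <- vars[vapply(vars, function(v) tr[[v]]$type == "log", logical(1))]
  }
  for (v in variables) {
    if (tr[[v]]$type != "log") stop("'", v, "' is not log-transformed", call. = FALSE)
    x[[v]] <- exp(x[[v]]) - tr[[v]]$offset
    tr[[v]] <- list(type = "raw")
  }
  attr(x, "transform") <- tr
  x
}

#' Difference a series
#'
#' First differences are adjacent differences; second differences are first
#' differences applied twice. The output is shorter than the input by `order`.
#'
#' @param x Numeric vector.
#' @param order 1 or 2.
#' @return Numeric vector of length `length(x) - order`.
#' @export
difference <- function(x, order = 1) {
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2", call. = FALSE)
  if (length(x) <= order) stop("series too short to difference", call. = FALSE)
  diff(x, differences = order)
}
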