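#' Read a schema-validated CSV table
#'
#' Shared reader for the package's tabular interfaces. Lines starting with
#' `#` are comments. Column names double as the unit declaration through
#' their suffix (`_M` molar, `_s` seconds, `_mP` millipolarization); a
#' missing or renamed column is a schema violation and raises a descriptive
#' error, as does a non-numeric cell in a numeric column (with its row
#' number).
#'
#' @param path CSV file path.
#' @param schema named character vector mapping required column names to
#'   `"numeric"`, `"logical"` or `"character"`.
#' @return Validated data frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(miss, collapse = ", ")))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric" && !is.numeric(df[[col]])) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad)) {
        stop(sprintf("%s: non-numeric value '%s' in column '%s' (row %d)",
                     basename(path), df[[col]][bad[1]], col, bad[1]))
      }
      df[[col]] <- v
    }
    if (schema[[col]] == "logical" && !is.logical(df[[col]])) {
      df[[col]] <- as.logical(df[[col]])
      if (anyNA(df[[col]])) {
        stop(sprintf("%s: column '%s' is not logical", basename(path), col))
      }
    }
  }
  df
}

# full-precision CSV writer with '#' metadata header lines
.write_table <- function(df, path, metadata = NULL) {
  lines <- character()
  if (!is.null(metadata)) {
    lines <- paste0("# ", names(metadata), ": ",
                    vapply(metadata, function(x) paste(format(x), collapse = " "),
                           character(1)))
  }
  fmt <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, , drop = FALSE], function(x) {
      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
    }, character(1)), collapse = ",")
  }, character(1))
  writeLines(c(lines, paste(names(df), collapse = ","), fmt), path)
  invisible(path)
}

#' Read / write FPCD plate time courses
#'
#' Long-form schema: `condition_id`, `competitor_M`, `replicate`, `time_s`,
#' `polarization_mP`. Numbers are written at full precision so a
#' write-then-read round trip is lossless.
#'
#' @param path CSV file path.
#' @return `read_fpcd_csv` returns the validated plate data frame.
#' @export
read_fpcd_csv <- function(path) {
  read_table(path, c(condition_id = "character", competitor_M = "numeric",
                     replicate = "character", time_s = "numeric",
                     polarization_mP = "numeric"))
}

#' @rdname read_fpcd_csv
#' @param plate plate data frame.
#' @param metadata optional named list written as `#` header comments.
#' @export
write_fpcd_csv <- function(plate, path, metadata = NULL) {
  .check_plate(plate)
  .write_table(plate, path, metadata)
}

#' Read / write single-molecule dwell-time lists
#'
#' Schema: `condition_id`, `competitor_M`, `duration_s`, `censored`.
#'
#' @param path CSV file path.
#' @return `read_dwell_csv` returns the validated dwell data frame.
#' @export
read_dwell_csv <- function(path) {
  read_table(path, c(condition_id = "character", competitor_M = "numeric",
                     duration_s = "numeric", censored = "logical"))
}

#' @rdname read_dwell_csv
#' @param dwells dwell data frame.
#' @param metadata optional named list written as `#` header comments.
#' @export
write_dwell_csv <- function(dwells, path, metadata = NULL) {
  need <- c("condition_id", "competitor_M", "duration_s", "censored")
  miss <- setdiff(need, names(dwells))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  .write_table(dwells, path, metadata)
}

#' Read an equilibrium isotherm CSV
#'
#' Schema: `protein_M`, `polarization_mP`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_isotherm_csv <- function(path) {
  read_table(path, c(protein_M = "numeric", polarization_mP = "numeric"))
}

#' Validated run configuration
#'
#' Key-value configuration for the analysis stages, with defaults matching
#' the documented stage defaults. Unknown keys are rejected; use
#' [write_config_snapshot()] to record the resolved configuration next to
#' run outputs.
#'
#' @param ... configuration overrides; see Details for the recognised keys.
#' @details Recognised keys: `koff_convention` ("initial_slope"/"rate"),
#'   `normalization` ("range"/"quantile"), `min_range_mP`, `dead_time_s`,
#'   `tie_margin`, `min_points`, `min_dwells`, `t_min_s`,
#'   `transfer_window_s`, `k_b`, `strict`, `seed`.
#' @return Object of class `dt_config` (a named list).
#' @export
dt_config <- function(...) {
  defaults <- list(koff_convention = "initial_slope",
                   normalization = "range", min_range_mP = 5,
                   dead_time_s = 90, tie_margin = 2, min_points = 5,
                   min_dwells = 20, t_min_s = 0, transfer_window_s = 0.15,
                   k_b = 0, strict = FALSE, seed = NULL)
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == ""))) {
    stop("all configuration entries must be named")
  }
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  structure(modifyList(defaults, args, keep.null = TRUE),
            class = "dt_config")
}

#' @rdname dt_config
#' @param config a `dt_config`.
#' @param path output JSON path.
#' @export
write_config_snapshot <- function(config, path) {
  stopifnot(inherits(config, "dt_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize a competition fit to JSON
#'
#' @param fit a `competition_fit`.
#' @param path output JSON path.
#' @export
write_competition_json <- function(fit, path) {
  stopifnot(inherits(fit, "competition_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Summarize the result files of a run directory
#'
#' Aggregates the competition-fit JSON files found in a results directory:
#' how many runs selected each model, which files are corrupt. The report is
#' `ok` only if at least one result parsed and nothing errored.
#'
#' @param dir results directory.
#' @return Object of class `run_report`: `n_results`, `model_counts`,
#'   `errors`, `results`, `ok`.
#' @export
run_report <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  files <- files[!grepl("config", basename(files))]
  if (!length(files)) stop("no result files in ", dir)
  results <- list()
  errors <- character()
  for (f in files) {
    parsed <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                       error = function(e) e)
    if (inherits(parsed, "error") || is.null(parsed$selected)) {
      errors <- c(errors, basename(f))
    } else {
      results[[basename(f)]] <- parsed
    }
  }
  counts <- table(vapply(results, `[[`, character(1), "selected"))
  structure(list(n_results = length(results),
                 model_counts = counts,
                 errors = errors, results = results,
                 ok = length(errors) == 0 && length(results) > 0),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: %d result(s), %d error(s)%s\n", x$n_results,
              length(x$errors), if (x$ok) " [ok]" else " [FAILED]"))
  if (x$n_results) {
    for (m in names(x$model_counts)) {
      cat(sprintf("  %s: %d\n", m, x$model_counts[[m]]))
    }
  }
  if (length(x$errors)) {
    cat("  corrupt:", paste(x$errors, collapse = ", "), "\n")
  }
  invisible(x)
}
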