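# Parameter documents and file formats.
#
# Three plain-text files in "key = value" dialect ('#' starts a comment,
# dot decimal separator):
#   simulation_parameters.txt             (14 parameters)
#   kinetic_parameters.txt                (18 parameters)
#   initial_configuration_parameters_<k>.txt (18 parameters, one per sample)
# plus an equivalent consolidated JSON document, experimental time-course
# TSVs (column 1: time in hours, column 2: percent conversion) and TSV
# output tables.

SIM_FILE <- "simulation_parameters.txt"
KIN_FILE <- "kinetic_parameters.txt"
CFG_FILE_FMT <- "initial_configuration_parameters_%d.txt"
FRACTION_GROUPS <- list(
  `substrate composition` = c("frac_cellulose", "frac_hemicellulose",
                              "frac_lignin"),
  `cocktail composition` = c("frac_EG", "frac_CBH", "frac_BGL", "frac_XYL"))

#' Default parameter document
#'
#' Builds a fully populated, validated parameter document from the schema
#' defaults: the full-size substrate (200 bonds per chain, `corn_stover`
#' cross-section) and the reference kinetic set.
#'
#' @param n_samples Number of initial-configuration sections (1-5).
#' @return A list of class `sacch_params` with elements `simulation`,
#'   `kinetic` and `samples` (list of per-sample configuration lists).
#' @export
#' @examples
#' p <- default_params()
#' lengths(list(p$simulation, p$kinetic, p$samples[[1]]))
default_params <- function(n_samples = 1) {
  stopifnot(n_samples >= 1, n_samples <= 5)
  samples <- lapply(seq_len(n_samples), function(k) {
    cfg <- schema_defaults("config")
    cfg$sample_name <- sprintf("sample_%d", k)
    cfg
  })
  doc <- structure(list(simulation = schema_defaults("simulation"),
                        kinetic = schema_defaults("kinetic"),
                        samples = samples), class = "sacch_params")
  validate_document(doc)
}

#' Reduced demonstration parameter document
#'
#' Same as [default_params()] but with the reduced `demo` substrate
#' (3x3 chains, 60 bonds per chain), sized so that multi-replicate runs and
#' fits complete in minutes.
#'
#' @inheritParams default_params
#' @return A `sacch_params` document.
#' @export
demo_params <- function(n_samples = 1) {
  doc <- default_params(n_samples)
  doc$simulation$n_bonds_per_chain <- 60L
  for (k in seq_along(doc$samples)) doc$samples[[k]]$species_preset <- "demo"
  validate_document(doc)
}

.coerce_param <- function(value, row) {
  if (row$type == "string") return(as.character(value))
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) {
    stop(sprintf("parameter '%s': value '%s' is not numeric",
                 row$name, value), call. = FALSE)
  }
  if (row$type %in% c("int", "flag")) {
    if (abs(v - round(v)) > 1e-9)
      stop(sprintf("parameter '%s': must be an integer (got %s)",
                   row$name, value), call. = FALSE)
    v <- as.integer(round(v))
  }
  v
}

.validate_section <- function(values, section, where = section) {
  sch <- schema_section(section)
  unknown <- setdiff(names(values), sch$name)
  if (length(unknown))
    stop(sprintf("%s: unknown parameter(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  missing <- setdiff(sch$name, names(values))
  if (length(missing))
    stop(sprintf("%s: missing parameter(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(sch))) {
    row <- sch[i, ]
    v <- .coerce_param(values[[row$name]], row)
    if (row$type == "string") {
      if (row$name == "species_preset" && !v %in% species_presets()$name)
        stop(sprintf(
          "parameter 'species_preset': '%s' is not a preset (legal values: %s)",
          v, paste(species_presets()$name, collapse = ", ")), call. = FALSE)
    } else if (v < row$min || v > row$max) {
      stop(sprintf("parameter '%s': value %s outside legal range [%s, %s]",
                   row$name, format(v), format(row$min), format(row$max)),
           call. = FALSE)
    }
    out[[row$name]] <- v
  }
  if (section == "config") {
    for (g in names(FRACTION_GROUPS)) {
      vals <- unlist(out[FRACTION_GROUPS[[g]]])
      rep <- validate_fractions(vals, g, stop_on_error = FALSE)
      if (!isTRUE(rep))
        stop(sprintf(
          "%s: %s {%s} must sum up to one: %s", where, g,
          paste(FRACTION_GROUPS[[g]], collapse = ", "),
          paste(rep$problems, collapse = "; ")), call. = FALSE)
    }
  }
  out
}

#' Validate a parameter document
#'
#' Checks every section against the 14/18/18 schema: unknown and missing
#' keys are rejected, every value must lie in its declared legal range, and
#' the substrate- and cocktail-composition fraction groups must each sum to
#' one.  Error messages name the offending parameter and its legal range.
#'
#' @param doc A `sacch_params` document (or plain list with the same shape).
#' @return The validated (type-coerced) document, invisibly classed
#'   `sacch_params`.
#' @export
validate_document <- function(doc) {
  stopifnot(is.list(doc), !is.null(doc$simulation), !is.null(doc$kinetic))
  if (is.null(doc$samples) || length(doc$samples) < 1)
    stop("document must contain at least one initial-configuration section",
         call. = FALSE)
  if (length(doc$samples) > 5)
    stop("at most five samples are supported", call. = FALSE)
  out <- list(
    simulation = .validate_section(doc$simulation, "simulation"),
    kinetic = .validate_section(doc$kinetic, "kinetic"),
    samples = lapply(seq_along(doc$samples), function(k)
      .validate_section(doc$samples[[k]], "config",
                        sprintf("initial configuration %d", k))))
  structure(out, class = "sacch_params")
}

.parse_kv_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3)
      stop(sprintf("%s: cannot parse line '%s'", basename(path), lines[i]),
           call. = FALSE)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Read the three plain-text parameter files
#'
#' @param path Either a directory containing `simulation_parameters.txt`,
#'   `kinetic_parameters.txt` and one or more
#'   `initial_configuration_parameters_<k>.txt`, or a named character
#'   vector/list with elements `simulation`, `kinetic` and `samples`
#'   (vector of config file paths).
#' @return A validated `sacch_params` document.
#' @export
read_parameter_files <- function(path) {
  if (is.character(path) && length(path) == 1 && dir.exists(path)) {
    sim <- file.path(path, SIM_FILE)
    kin <- file.path(path, KIN_FILE)
    cfgs <- sort(list.files(path, "^initial_configuration_parameters_[0-9]+\\.txt$",
                            full.names = TRUE))
    if (length(cfgs) == 0)
      stop(sprintf("no initial-configuration parameter file found in %s",
                   path), call. = FALSE)
  } else {
    sim <- path[["simulation"]]; kin <- path[["kinetic"]]
    cfgs <- path[["samples"]]
  }
  doc <- list(simulation = .parse_kv_file(sim),
              kinetic = .parse_kv_file(kin),
              samples = lapply(cfgs, .parse_kv_file))
  validate_document(doc)
}

.write_kv_file <- function(values, path, section) {
  sch <- schema_section(section)
  hdr <- sprintf("# %s parameters (%d)", section, nrow(sch))
  fmt_val <- function(v) {
    if (is.character(v)) v else format(v, digits = 17, scientific = FALSE)
  }
  body <- vapply(sch$name, function(nm) {
    sprintf("%s = %s", nm, fmt_val(values[[nm]]))
  }, character(1))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  path
}

#' Write a document to the three plain-text parameter files
#'
#' @param doc A `sacch_params` document.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_parameter_files <- function(doc, dir) {
  doc <- validate_document(doc)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    .write_kv_file(doc$simulation, file.path(dir, SIM_FILE), "simulation"),
    .write_kv_file(doc$kinetic, file.path(dir, KIN_FILE), "kinetic"),
    vapply(seq_along(doc$samples), function(k)
      .write_kv_file(doc$samples[[k]],
                     file.path(dir, sprintf(CFG_FILE_FMT, k)), "config"),
      character(1)))
  invisible(paths)
}

#' Read / write the consolidated JSON parameter document
#'
#' One JSON object with top-level keys `simulation`, `kinetic` and
#' `samples` (array of initial-configuration objects), semantically
#' equivalent to the three plain-text files; `write` then `read` is the
#' identity.
#'
#' @param path JSON file path.
#' @return A validated `sacch_params` document.
#' @export
read_consolidated <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (!is.list(raw) || is.null(raw$simulation) || is.null(raw$kinetic) ||
      is.null(raw$samples))
    stop(sprintf(
      "%s: consolidated document must have keys simulation, kinetic, samples",
      path), call. = FALSE)
  validate_document(list(simulation = raw$simulation, kinetic = raw$kinetic,
                         samples = raw$samples))
}

#' @rdname read_consolidated
#' @param doc A `sacch_params` document.
#' @export
write_consolidated <- function(doc, path) {
  doc <- validate_document(doc)
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an experimental time-course TSV
#'
#' Strict dialect: tab-separated UTF-8 text, column 1 time in hours,
#' column 2 percent glucan/xylan conversion, dot decimal separator, no
#' header required (a single leading line whose first token is not a number
#' is skipped).  Times must be strictly increasing and conversions within
#' \[0, 100\].
#'
#' @param path File path.
#' @param sugar Optional label (`"glucose"` or `"xylose"`) attached to the
#'   result.
#' @param sample Optional sample name attached to the result.
#' @return Data frame with columns `time` and `conversion`, attributes
#'   `sugar` and `sample`.
#' @export
read_timecourse_tsv <- function(path, sugar = NULL, sample = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("%s: empty file", path), call. = FALSE)
  first_tok <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][1]
  start <- if (is.na(suppressWarnings(as.numeric(first_tok)))) 2L else 1L
  if (start > length(lines))
    stop(sprintf("%s: no data lines", path), call. = FALSE)
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  n <- length(lines) - start + 1L
  tm <- numeric(n); cv <- numeric(n)
  for (i in seq_len(n)) {
    ln <- lines[start + i - 1L]
    parts <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (length(parts) < 2)
      stop(sprintf("%s: line %d: expected two tab-separated columns",
                   path, start + i - 1L), call. = FALSE)
    if (!grepl(num_re, parts[1]) || !grepl(num_re, parts[2]))
      stop(sprintf("%s: line %d: non-numeric cell", path, start + i - 1L),
           call. = FALSE)
    tm[i] <- as.numeric(parts[1]); cv[i] <- as.numeric(parts[2])
  }
  if (any(diff(tm) <= 0))
    stop(sprintf("%s: times must be strictly increasing", path),
         call. = FALSE)
  if (any(cv < -1e-9 | cv > 100 + 1e-9))
    stop(sprintf("%s: conversions must lie in [0, 100]", path),
         call. = FALSE)
  out <- data.frame(time = tm, conversion = pmin(pmax(cv, 0), 100))
  attr(out, "sugar") <- sugar
  attr(out, "sample") <- sample
  out
}

#' Write a time-course series as TSV (input dialect)
#'
#' @param series Data frame with columns `time` and `conversion`.
#' @param path Output path.
#' @param digits Significant digits.
#' @export
write_timecourse_tsv <- function(series, path, digits = 6) {
  lines <- sprintf("%s\t%s",
                   format(series$time, digits = digits, trim = TRUE,
                          scientific = FALSE),
                   format(series$conversion, digits = digits, trim = TRUE,
                          scientific = FALSE))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write simulation (and fit) outputs to a directory
#'
#' Writes one conversion table per sugar present (`glucose_conversion.tsv`,
#' `xylose_conversion.tsv`, in the same two-column dialect the readers
#' accept), the per-enzyme activity table (`enzyme_activity.tsv`), a
#' snapshot of the parameter files, and -- for fits -- the fit report
#' (`fit_report.tsv`: generation, best sub-generation, variance) and
#' per-series R-squared values (`r_squared.tsv`).
#'
#' @param timecourse A `sacch_timecourse` from [run_simulation()].
#' @param out_dir Output directory (created if needed).
#' @param params Optional `sacch_params` document to snapshot.
#' @param fit Optional `sacch_fit` object.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(timecourse, out_dir, params = NULL, fit = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.access(out_dir, 2) == 0
  if (!ok) stop(sprintf("cannot write to %s", out_dir), call. = FALSE)
  paths <- character(0)
  tc <- as.data.frame(timecourse)
  if (any(is.finite(tc$glucose_conversion))) {
    p <- file.path(out_dir, "glucose_conversion.tsv")
    write_timecourse_tsv(data.frame(time = tc$time,
                                    conversion = tc$glucose_conversion), p)
    paths <- c(paths, p)
  }
  if (any(is.finite(tc$xylose_conversion))) {
    p <- file.path(out_dir, "xylose_conversion.tsv")
    write_timecourse_tsv(data.frame(time = tc$time,
                                    conversion = tc$xylose_conversion), p)
    paths <- c(paths, p)
  }
  act <- tc[, c("time", grep("^events_", names(tc), value = TRUE))]
  p <- file.path(out_dir, "enzyme_activity.tsv")
  write.table(act, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(params)) {
    paths <- c(paths, write_parameter_files(params, out_dir))
    p <- file.path(out_dir, "parameters.json")
    write_consolidated(params, p)
    paths <- c(paths, p)
  }
  if (!is.null(fit)) {
    p <- file.path(out_dir, "fit_report.tsv")
    write.table(fit$trace, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "r_squared.tsv")
    r2 <- data.frame(series = names(fit$r_squared),
                     r_squared = unname(fit$r_squared))
    write.table(r2, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.sacch_params <- function(x, ...) {
  cat(sprintf("<sacch_params> %d simulation + %d kinetic + %d x %d sample parameters\n",
              length(x$simulation), length(x$kinetic),
              length(x$samples), length(x$samples[[1]])))
  cat(sprintf("  substrate: %s, %d bonds/chain; samples: %s\n",
              x$samples[[1]]$species_preset,
              x$simulation$n_bonds_per_chain,
              paste(vapply(x$samples, `[[`, "", "sample_name"),
                    collapse = ", ")))
  invisible(x)
}
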