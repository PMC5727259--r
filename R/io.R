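# Delimited-table interchange. All tables are UTF-8 text, comma- or
# tab-delimited (auto-detected), with a header row. Units are fixed by
# schema: sweep time in ms, bleach time in frames at a stated frame
# interval, current in pA, voltage in mV.

table_schemas <- list(
  sweeps = list(columns = c("sweep_id", "time_ms", "current_pA"),
                numeric = c("time_ms", "current_pA"),
                key = c("sweep_id", "time_ms")),
  bleach = list(columns = c("molecule_id", "frame", "intensity"),
                numeric = c("frame", "intensity"),
                key = c("molecule_id", "frame")),
  dose_response = list(columns = c("x", "y", "sem"),
                       numeric = c("x", "y", "sem"),
                       key = "x"),
  gating = list(columns = c("voltage_mv", "response"),
                numeric = c("voltage_mv", "response"),
                key = "voltage_mv"),
  iv = list(columns = c("voltage_mv", "peak_pA"),
            numeric = c("voltage_mv", "peak_pA"),
            key = "voltage_mv"),
  fret = list(columns = c("roi_id", "fret", "cfp", "yfp"),
              numeric = c("fret", "cfp", "yfp"),
              key = "roi_id"))

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (grepl("\t", first)) "\t" else ","
}

#' Read and validate a delimited data table
#'
#' Reads one of the package's interchange tables with schema validation.
#' Supported schemas: `"sweeps"` (`sweep_id`, `time_ms`, `current_pA`),
#' `"bleach"` (`molecule_id`, `frame`, `intensity`), `"dose_response"`
#' (`x`, `y`, `sem`), `"gating"` (`voltage_mv`, `response`), `"iv"`
#' (`voltage_mv`, `peak_pA`), `"fret"` (`roi_id`, `fret`, `cfp`, `yfp`).
#' Comma and tab delimiters are auto-detected. Missing columns,
#' non-numeric cells and duplicated key rows are rejected with messages
#' naming the offending column and row.
#'
#' @param path file path.
#' @param schema_name one of the schema names above.
#'
#' @return A validated data frame.
#' @export
load_table <- function(path, schema_name) {
  if (!schema_name %in% names(table_schemas))
    stop(sprintf("unknown schema '%s'", schema_name), call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  schema <- table_schemas[[schema_name]]
  df <- read.table(path, header = TRUE, sep = detect_sep(path),
                   stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(schema$columns, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  df <- df[schema$columns]
  for (col in schema$numeric) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) || anyNA(df[[col]]))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, c(bad, which(is.na(df[[col]])))[1]),
           call. = FALSE)
    df[[col]] <- vals
  }
  key <- do.call(paste, c(df[schema$key], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicated key (%s) at data row %d",
                 paste(schema$key, collapse = ", "), dup[1]),
         call. = FALSE)
  df
}

#' Write a sweep set as a long-format table with metadata sidecar
#'
#' The table holds `sweep_id`, `time_ms`, `current_pA` at 6 significant
#' digits; the sidecar (`<path>.meta.json`) records the protocol, the
#' generating model when known, and the seed, sufficient to regenerate the
#' data.
#'
#' @param sweeps a [sweep_set()].
#' @param path output table path.
#' @param model optional [gating_model()] echoed in the sidecar.
#' @param seed optional seed echoed in the sidecar.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(sweeps, path, model = NULL, seed = NULL,
                         sep = ",") {
  stopifnot(inherits(sweeps, "sweep_set"))
  tm <- sweep_times(sweeps)
  long <- data.frame(
    sweep_id = rep(seq_len(nrow(sweeps$sweeps)), each = length(tm)),
    time_ms = rep(signif(tm, 9), nrow(sweeps$sweeps)),
    current_pA = signif(as.vector(t(sweeps$sweeps)), 6))
  write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  meta <- list(protocol = unclass(sweeps$protocol))
  if (!is.null(model)) meta$model <- unclass(model)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sweep table (plus sidecar) back into a sweep set
#'
#' @param path table path written by [write_sweeps()]; the sidecar
#'   `<path>.meta.json` must exist to recover the protocol.
#' @return A [sweep_set()] (without ground truth).
#' @export
read_sweeps <- function(path) {
  df <- load_table(path, "sweeps")
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("missing metadata sidecar: %s", meta_path), call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  protocol <- do.call(step_protocol, meta$protocol[
    c("holding_mv", "step_mv", "step_ms", "sample_rate_hz", "n_sweeps")])
  ids <- unique(df$sweep_id)
  ns <- n_samples(protocol)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = ns)
  for (i in seq_along(ids)) {
    sub <- df[df$sweep_id == ids[i], ]
    sub <- sub[order(sub$time_ms), ]
    if (nrow(sub) != ns)
      stop(sprintf("sweep '%s' has %d samples, protocol expects %d",
                   ids[i], nrow(sub), ns), call. = FALSE)
    mat[i, ] <- sub$current_pA
  }
  sweep_set(mat, protocol)
}

#' Write photobleaching traces as a long-format table
#'
#' @param traces list of [bleach_trace()] objects.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_bleach_traces <- function(traces, path, sep = ",") {
  rows <- lapply(traces, function(tr)
    data.frame(molecule_id = tr$molecule_id,
               frame = seq_along(tr$intensity) - 1L,
               intensity = signif(tr$intensity, 6)))
  write.table(do.call(rbind, rows), path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read photobleaching traces from a long-format table
#'
#' @param path table path.
#' @param frame_interval_s frame period (s) to attach to each trace.
#' @return A list of [bleach_trace()] objects.
#' @export
read_bleach_traces <- function(path, frame_interval_s = 0.1) {
  df <- load_table(path, "bleach")
  lapply(split(df, df$molecule_id), function(sub) {
    sub <- sub[order(sub$frame), ]
    bleach_trace(sub$molecule_id[1], sub$intensity, frame_interval_s)
  })
}

#' Write a generic analysis table
#'
#' @param df data frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(df, path, sep = ",") {
  write.table(as.data.frame(df), path, sep = sep, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
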