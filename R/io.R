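#' Read a raw gaze sample table
#'
#' Reads a delimited sample table (CSV/TSV with header) into a
#' [gaze_recording()].  Column names are never guessed: `schema` maps the
#' recording fields onto the file's columns, so exports from any binocular
#' or monocular system can be ingested.  Rows whose coordinates do not
#' parse as numbers become missing samples; known vendor sentinel
#' coordinates (e.g. `-1` or `0,0` for "no eye found") can be mapped to
#' missing via `na_values`.
#'
#' @param path path to the delimited file.
#' @param schema named list/vector mapping field names to column names.
#'   Recognised fields: `time` (required), `left_x`, `left_y`, `right_x`,
#'   `right_y`, `left_valid`, `right_valid`, `pupil_left`, `pupil_right`.
#'   At least one eye's `x`/`y` pair must be mapped.  May also be the path
#'   of a JSON file holding such a mapping.
#' @param sampling_rate sampling rate in Hz.
#' @param sep field separator; default `","`, use `"\t"` for TSV.
#' @param na_values numeric coordinate values to treat as missing
#'   (vendor sentinels), e.g. `c(-1)`.
#'
#' @return A [gaze_recording()].  The attribute `n_unparseable` counts
#'   coordinate cells that failed to parse.
#' @export
read_gaze <- function(path, schema, sampling_rate, sep = ",",
                      na_values = NULL) {
  if (!file.exists(path)) {
    stop("gazefix_error_missing_file: no such file: ", path, call. = FALSE)
  }
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  schema <- as.list(schema)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(tab) == 0L) {
    stop("gazefix_error_empty: empty sample table: ", path, call. = FALSE)
  }
  if (is.null(schema$time)) {
    stop("gazefix_error_schema: schema must map 'time'", call. = FALSE)
  }
  has_left <- !is.null(schema$left_x) && !is.null(schema$left_y)
  has_right <- !is.null(schema$right_x) && !is.null(schema$right_y)
  if (!has_left && !has_right) {
    stop("gazefix_error_schema: schema must map at least one eye's x/y",
         call. = FALSE)
  }
  mapped <- unlist(schema, use.names = FALSE)
  absent <- setdiff(mapped, names(tab))
  if (length(absent)) {
    stop("gazefix_error_schema: column(s) not in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  n_unparseable <- 0L
  numcol <- function(field, count = FALSE) {
    col <- schema[[field]]
    if (is.null(col)) return(NULL)
    raw <- tab[[col]]
    v <- suppressWarnings(as.numeric(as.character(raw)))
    if (count) {
      bad <- is.na(v) & !is.na(raw) & trimws(as.character(raw)) != "" &
        !toupper(trimws(as.character(raw))) %in% c("NA", "NAN")
      n_unparseable <<- n_unparseable + sum(bad)
    }
    if (!is.null(na_values)) v[v %in% na_values] <- NA_real_
    v
  }
  logcol <- function(field) {
    col <- schema[[field]]
    if (is.null(col)) return(NULL)
    v <- tab[[col]]
    if (is.logical(v)) return(v)
    if (is.numeric(v)) return(v != 0)
    vs <- tolower(trimws(as.character(v)))
    vs %in% c("1", "true", "t", "yes", "valid")
  }

  time <- numcol("time")
  if (anyNA(time)) {
    stop("gazefix_error_timestamps: unparseable timestamps in ", path,
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("gazefix_error_timestamps: timestamps not strictly increasing in ",
         path, call. = FALSE)
  }
  rec <- gaze_recording(
    time = time,
    left_x = numcol("left_x", count = TRUE),
    left_y = numcol("left_y", count = TRUE),
    right_x = numcol("right_x", count = TRUE),
    right_y = numcol("right_y", count = TRUE),
    left_valid = logcol("left_valid"),
    right_valid = logcol("right_valid"),
    pupil_left = numcol("pupil_left"),
    pupil_right = numcol("pupil_right"),
    sampling_rate = sampling_rate
  )
  if (n_unparseable > 0L) {
    message("read_gaze: ", n_unparseable,
            " unparseable coordinate cell(s) treated as missing")
  }
  attr(rec, "n_unparseable") <- n_unparseable
  rec
}

#' Write a raw gaze recording to CSV
#'
#' Inverse of [read_gaze()] under the default schema (field names as
#' column names).
#'
#' @param rec a [gaze_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  utils::write.csv(rec$samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default column schema
#'
#' The identity mapping used by [write_gaze()] output and the simulator.
#' @return A named list usable as the `schema` argument of [read_gaze()].
#' @export
default_schema <- function() {
  list(time = "time", left_x = "left_x", left_y = "left_y",
       right_x = "right_x", right_y = "right_y",
       left_valid = "left_valid", right_valid = "right_valid",
       pupil_left = "pupil_left", pupil_right = "pupil_right")
}

fixation_columns <- c(
  "id", "onset", "offset", "duration", "centroid_x", "centroid_y",
  "centroid_x_deg", "centroid_y_deg", "rms", "n_samples", "n_interpolated",
  "single_eye_fraction", "pupil_mean", "merged", "rejected_rms",
  "rejected_duration", "label"
)

#' Write a fixation table to CSV
#'
#' Serializes the surviving fixations of a [posthoc_validate()] result (or
#' a bare fixation data.frame) as a delimited table, one row per fixation,
#' temporally ordered and non-overlapping.  Reading the file back with
#' [read_fixations()] reproduces integer fields exactly and reals to
#' printed precision.
#'
#' @param fixations a `fixation_set` or a fixation data.frame.
#' @param path output path.
#' @param which for a `fixation_set`, `"surviving"` (default) or
#'   `"rejected"`.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path, which = "surviving") {
  df <- if (inherits(fixations, "fixation_set")) fixations[[which]]
        else fixations
  df <- as_fixation_df(df)
  if (nrow(df) > 1L &&
      any(df$onset[-1] < df$offset[-nrow(df)] - 1e-9)) {
    stop("gazefix_error_fixations: fixation intervals overlap", call. = FALSE)
  }
  utils::write.csv(df[, fixation_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a fixation table written by [write_fixations()]
#'
#' @param path path to the CSV.
#' @return A fixation data.frame (possibly 0-row).
#' @export
read_fixations <- function(path) {
  if (!file.exists(path)) {
    stop("gazefix_error_missing_file: no such file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(fixation_columns, names(df))
  if (length(missing)) {
    stop("gazefix_error_fixations: not a fixation table, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$label <- as.character(df$label)
  for (f in c("merged", "rejected_rms", "rejected_duration")) {
    df[[f]] <- as.logical(df[[f]])
  }
  as_fixation_df(df)
}

# normalize a fixation data.frame: all columns present, ordered, typed
as_fixation_df <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(
      id = integer(), onset = numeric(), offset = numeric(),
      duration = numeric(), centroid_x = numeric(), centroid_y = numeric(),
      centroid_x_deg = numeric(), centroid_y_deg = numeric(),
      rms = numeric(), n_samples = integer(), n_interpolated = integer(),
      single_eye_fraction = numeric(), pupil_mean = numeric(),
      merged = logical(), rejected_rms = logical(),
      rejected_duration = logical(), label = character(),
      stringsAsFactors = FALSE
    )
    return(df)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  defaults <- list(
    id = seq_len(n), duration = df$offset - df$onset,
    centroid_x_deg = NA_real_, centroid_y_deg = NA_real_,
    rms = 0, n_samples = NA_integer_, n_interpolated = 0L,
    single_eye_fraction = 0, pupil_mean = NA_real_,
    merged = FALSE, rejected_rms = FALSE, rejected_duration = FALSE,
    label = "fixation"
  )
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  }
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  df[, fixation_columns]
}
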