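# CSV dialects: UTF-8, header row, dot decimal, values rounded to 6
# significant digits on write.

fmt6 <- function(df) {
  mutate(df, across(dplyr::where(is.double), ~ signif(.x, 6)))
}

write_csv_strict <- function(df, path) {
  utils::write.csv(fmt6(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_strict <- function(path, required, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s (%s) is missing column(s): %s",
                  what, basename(path), paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read and write pipeline tables
#'
#' CSV round trips for the three table dialects of the pipeline: long rating
#' streams (`clip_id,role,rater_id,t_s,value`), participants, and EA scores.
#' Files are UTF-8 with a header row and dot decimals; doubles are written to
#' 6 significant digits. Readers validate the header and, for streams, that
#' timestamps increase strictly within each stream.
#'
#' @param streams,participants,ea Tibbles to write.
#' @param path File path.
#' @return Readers return tibbles; writers return the path invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_streams <- function(streams, path) {
  require_columns(streams, c("clip_id", "role", "rater_id", "t_s", "value"),
                  "`streams`")
  write_csv_strict(
    select(streams, "clip_id", "role", "rater_id", "t_s", "value"), path)
}

#' @rdname pipeline_io
#' @export
read_streams <- function(path) {
  df <- read_csv_strict(path, c("clip_id", "role", "rater_id", "t_s",
                                "value"), "streams file")
  bad <- df |>
    group_by(.data$clip_id, .data$rater_id) |>
    summarise(mono = all(diff(.data$t_s) > 0) || dplyr::n() == 1,
              .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-monotone timestamps in stream(s): %s",
      paste(sprintf("%s/%s", bad$clip_id, bad$rater_id), collapse = ", ")))
  }
  df
}

#' @rdname pipeline_io
#' @export
write_participants <- function(participants, path) {
  require_columns(participants, c("participant_id", "condition"),
                  "`participants`")
  write_csv_strict(participants, path)
}

#' @rdname pipeline_io
#' @export
read_participants <- function(path) {
  df <- read_csv_strict(path, c("participant_id", "condition"),
                        "participants file")
  df$hazard_flag <- as.logical(df$hazard_flag %||% NA)
  df
}

#' @rdname pipeline_io
#' @export
write_ea <- function(ea, path) {
  write_csv_strict(ea, path)
}

#' @rdname pipeline_io
#' @export
read_ea <- function(path) {
  df <- read_csv_strict(path, c("perceiver_id", "clip_id", "r", "z",
                                "excluded"), "EA file")
  df$excluded <- as.logical(df$excluded)
  df
}

#' Write or read a full synthetic study dataset
#'
#' Serializes a `study_dataset` to a directory as `streams.csv`,
#' `clips.csv`, `participants.csv`, `assignments.csv`, and a `truth.json`
#' sidecar holding the ground-truth effect structure and the seed.
#'
#' @param dataset A `study_dataset` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `study_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_streams(dataset$streams, file.path(dir, "streams.csv"))
  write_csv_strict(dataset$clips, file.path(dir, "clips.csv"))
  write_participants(dataset$participants,
                     file.path(dir, "participants.csv"))
  write_csv_strict(dataset$assignments, file.path(dir, "assignments.csv"))
  jsonlite::write_json(
    list(truth = unclass(dataset$truth), seed = dataset$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  effects <- do.call(effect_spec, truth$truth)
  structure(
    list(
      streams = read_streams(file.path(dir, "streams.csv")),
      clips = read_csv_strict(file.path(dir, "clips.csv"),
                              c("clip_id", "target_id", "valence"),
                              "clips file"),
      participants = read_participants(file.path(dir, "participants.csv")),
      assignments = read_csv_strict(file.path(dir, "assignments.csv"),
                                    c("perceiver_id", "clip_id"),
                                    "assignments file"),
      truth = effects,
      seed = as.integer(truth$seed)
    ),
    class = "study_dataset"
  )
}
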