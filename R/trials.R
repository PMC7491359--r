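#' Column and label mapping for trial-level input files
#'
#' Recognition data arrive in many layouts; a dialect maps the columns and
#' labels of a particular file to the canonical long format used here
#' (`participant`, `lexicality`, `status`, `response`). The default dialect
#' reads canonical column names and accepts common label abbreviations,
#' including the confidence-rating variant in which *sure* plays the role of
#' *remember* and *unsure* the role of *know*.
#'
#' @param participant,lexicality,status,response Names of the corresponding
#'   columns in the source file.
#' @param lexicality_labels,status_labels,response_labels Named character
#'   vectors mapping source labels (names) to canonical labels (values).
#'   Matching is case-insensitive.
#' @return A `rkn_dialect` list usable by [read_trials()] and [as_trials()].
#' @export
rkn_dialect <- function(participant = "participant",
                        lexicality = "lexicality",
                        status = "status",
                        response = "response",
                        lexicality_labels = c(
                          word = "word", w = "word",
                          nonword = "nonword", nw = "nonword", "non-word" = "nonword"
                        ),
                        status_labels = c(
                          old = "old", o = "old", target = "old",
                          new = "new", n = "new", lure = "new"
                        ),
                        response_labels = c(
                          remember = "remember", r = "remember", rem = "remember",
                          sure = "remember", s = "remember",
                          know = "know", k = "know",
                          unsure = "know", u = "know",
                          new = "new", n = "new"
                        )) {
  structure(
    list(
      columns = c(
        participant = participant, lexicality = lexicality,
        status = status, response = response
      ),
      labels = list(
        lexicality = lexicality_labels,
        status = status_labels,
        response = response_labels
      )
    ),
    class = "rkn_dialect"
  )
}

recode_labels <- function(x, map, field) {
  key <- tolower(trimws(as.character(x)))
  names(map) <- tolower(names(map))
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(paste0(
      "Unknown ", field, " label ", encodeString(as.character(x)[bad], quote = '"'),
      " in row ", bad, "."
    ))
  }
  out
}

#' Coerce a data frame of trials to the canonical format
#'
#' Validates and relabels an in-memory data frame of trial-level responses.
#' Row order is preserved. Unknown labels and missing columns are hard errors
#' that name the offending row or column.
#'
#' @param data A data frame with one row per recognition-test trial.
#' @param dialect A column/label mapping from [rkn_dialect()].
#' @return A tibble with columns `participant` (character), `lexicality`
#'   (`"word"`/`"nonword"`), `status` (`"old"`/`"new"`) and `response`
#'   (`"remember"`/`"know"`/`"new"`).
#' @export
as_trials <- function(data, dialect = rkn_dialect()) {
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing column(s) in input: ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  tibble::tibble(
    participant = as.character(data[[cols[["participant"]]]]),
    lexicality  = recode_labels(data[[cols[["lexicality"]]]],
                                dialect$labels$lexicality, "lexicality"),
    status      = recode_labels(data[[cols[["status"]]]],
                                dialect$labels$status, "status"),
    response    = recode_labels(data[[cols[["response"]]]],
                                dialect$labels$response, "response")
  )
}

#' Read trial-level recognition data from a delimited text file
#'
#' Reads a CSV or TSV file (header row required, delimiter guessed) and
#' validates it into the canonical trial format.
#'
#' @param file Path to a delimited text file, one row per trial.
#' @inheritParams as_trials
#' @return A tibble of validated trials; see [as_trials()].
#' @export
read_trials <- function(file, dialect = rkn_dialect()) {
  if (is.character(file) && !file.exists(file)) {
    abort(paste0("Input file not found: ", file))
  }
  raw <- readr::read_delim(file, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  as_trials(raw, dialect)
}

#' Write trials in the canonical long format
#'
#' @param trials A trials tibble from [as_trials()] or [generate_experiment()].
#' @param file Output path; written as comma-separated text with a header.
#' @return `file`, invisibly.
#' @export
write_trials <- function(trials, file) {
  readr::write_csv(trials[, c("participant", "lexicality", "status", "response")],
                   file, progress = FALSE)
  invisible(file)
}
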