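## Reading/writing the song table (RFC-4180 CSV) with validation.

.SONG_COLUMNS <- c("individual_id", "recording_id", "recording_order", "year",
                   "date", "age", "context", "song_order", "position")

#' Read and validate a song table
#'
#' Expects a CSV with one row per song and the documented header
#' (individual_id, recording_id, recording_order, year, date, age, context,
#' song_order, position, plus one column per trait).  Contexts are restricted
#' to male / female / none, positions to [0, 100] or missing, and song orders
#' must be consecutive from 1 within each recording.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readSongTable <- function(path) {
  songs <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SONG_COLUMNS, names(songs))
  if (length(missing_cols))
    stop("song table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!songs$context %in% .CONTEXTS)
  if (length(bad))
    stop("unknown context at row(s): ", paste(head(bad, 10), collapse = ", "))
  bad <- which(!is.na(songs$position) &
                 (songs$position < 0 | songs$position > 100))
  if (length(bad))
    stop("singing position outside [0, 100] at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  for (rid in unique(songs$recording_id)) {
    so <- sort(songs$song_order[songs$recording_id == rid])
    if (!identical(as.integer(so), seq_along(so)))
      stop("song orders not consecutive from 1 in recording ", rid)
  }
  songs
}

#' Write a song table
#'
#' @param songs song data.frame.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeSongTable <- function(songs, path) {
  write.csv(songs, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
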