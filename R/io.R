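#' Write / read a ventral-root recording as TSV plus a YAML sidecar
#'
#' Recordings are stored as tab-separated columnar text with header
#' `time_s lL2 rL2 lL5 rL5` (or whichever channel subset is present); the
#' sampling rate and any annotations (drug, CNO or light times) go in a
#' key-value YAML sidecar next to the table.
#'
#' @param recording Tibble with `time_s` plus channel columns.
#' @param path Path of the `.tsv` file to write.
#' @param fs Sampling rate (Hz).
#' @param annotations Optional named list of annotation times (seconds),
#'   written into the sidecar.
#' @param meta_path Sidecar path; defaults to `path` with a `.yaml`
#'   extension.
#' @return `write_recording` invisibly returns `path`; `read_recording`
#'   returns a list with `recording`, `fs`, `annotations`.
#' @export
write_recording <- function(recording, path, fs, annotations = NULL,
                            meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.tsv$", ".yaml", path)
  readr::write_tsv(recording, path)
  yaml::write_yaml(c(list(fs = fs), annotations %||% list()), meta_path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.tsv$", ".yaml", path)
  rec <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- yaml::read_yaml(meta_path)
  fs <- meta$fs
  meta$fs <- NULL
  list(recording = rec, fs = fs, annotations = meta)
}

#' Write / read a calcium movie as multi-page TIFF plus a JSON sidecar
#'
#' Frames are written as 16-bit multi-page TIFF; the frame rate, landmark
#' annotations and the intensity scaling used for the 16-bit quantisation go
#' in a JSON sidecar so the movie can be restored losslessly up to the
#' quantisation step.
#'
#' @param movie A `calcium_movie`.
#' @param path Path of the `.tif` file.
#' @param json_path Sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return `write_calcium_movie` invisibly returns `path`;
#'   `read_calcium_movie` returns a `calcium_movie`.
#' @export
write_calcium_movie <- function(movie, path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.tiff?$", ".json", path)
  lo <- min(movie$frames); hi <- max(movie$frames)
  scale <- if (hi > lo) hi - lo else 1
  T <- dim(movie$frames)[3]
  pages <- lapply(seq_len(T), function(tt) {
    (movie$frames[, , tt] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  lm <- movie$landmarks
  if (!is.null(lm$canal)) {
    lm$canal <- as.list(lm$canal)  # keep names through JSON
  }
  jsonlite::write_json(
    list(fs = movie$fs, offset = lo, scale = scale,
         normalized = isTRUE(movie$normalized),
         landmarks = lm),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calcium_movie
#' @export
read_calcium_movie <- function(path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.tiff?$", ".json", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (tt in seq_along(pages)) {
    frames[, , tt] <- pages[[tt]] * meta$scale + meta$offset
  }
  lm <- meta$landmarks
  if (!is.null(lm$canal)) {
    lm$canal <- c(row = as.numeric(lm$canal["row"]),
                  col = as.numeric(lm$canal["col"]))
  }
  calcium_movie(frames, meta$fs, landmarks = lm,
                normalized = isTRUE(meta$normalized))
}
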