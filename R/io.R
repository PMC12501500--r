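#' Write an epoch set to a plain-text session directory
#'
#' Stores the `trials x channels x samples` array as whitespace-delimited
#' text (`data.txt`, one row per trial x channel), the channel table as
#' CSV and the metadata (sampling rate, task, epoch start, keep flags,
#' optional seed/group attributes) as JSON.
#'
#' @param epochs an [epoch_set()].
#' @param dir output directory (created if needed).
#' @param meta extra metadata fields to record (e.g. seed, group).
#' @return `dir`, invisibly.
#' @export
write_session <- function(epochs, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3])
  utils::write.table(t(flat), file.path(dir, "data.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(epochs$channels, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  info <- c(list(fs = epochs$fs, task = epochs$task,
                 t_start = epochs$time[1], n_trials = d[1],
                 n_channels = d[2], n_samples = d[3],
                 keep = epochs$keep), meta)
  writeLines(jsonlite::toJSON(info, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read an epoch set written by [write_session()]
#'
#' @param dir session directory.
#' @return an [epoch_set()]; extra metadata is attached as attribute
#'   `"meta"`.
#' @export
read_session <- function(dir) {
  info <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  channels <- utils::read.csv(file.path(dir, "channels.csv"),
                              stringsAsFactors = FALSE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.txt")))
  data <- aperm(array(t(flat), c(info$n_samples, info$n_channels,
                                 info$n_trials)), c(3, 2, 1))
  ep <- epoch_set(data, info$fs, channels, task = info$task,
                  t_start = info$t_start, keep = info$keep)
  attr(ep, "meta") <- info
  ep
}
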