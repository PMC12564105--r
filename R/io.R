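# Persistence for recordings, datasets and models. Objects are stored as
# RDS files keeping the same logical layout throughout (data matrix,
# channel roles, sampling rate; sources and trigger onsets for ground
# truth). A CSV export is provided for score tables and training histories.

#' Write / read a recording (with optional ground truth)
#'
#' @param x a [recording()] or the list returned by [simulate_session()].
#' @param path file path (`.rds`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the stored object.
#' @export
write_recording <- function(x, path) {
  ok <- inherits(x, "recording") ||
    (is.list(x) && inherits(x$recording, "recording"))
  if (!ok) stop("`x` must be a recording or a simulate_session() result",
                call. = FALSE)
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) readRDS(path)

#' Write / read an artifact dataset
#'
#' @param dataset an `artifact_dataset`.
#' @param path file path (`.rds`).
#' @return `write_dataset` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "artifact_dataset")) {
    stop("`dataset` must be an artifact_dataset", call. = FALSE)
  }
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) readRDS(path)

#' Write / read a CA-SeqNet model checkpoint
#'
#' The checkpoint holds the parameters, the full architecture and the
#' training history (including the seed).
#'
#' @param model a `ca_seqnet`.
#' @param path file path (`.rds`).
#' @return `save_model` returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ca_seqnet")) stop("`model` must be a ca_seqnet",
                                          call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
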