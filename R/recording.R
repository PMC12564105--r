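#' Multichannel OPM-MEG recording container
#'
#' A `recording` bundles a channels-by-samples data matrix with its sampling
#' rate and one role per channel. Roles follow the acquisition layout of a
#' wearable OPM-MEG session: an array of MEG magnetometers plus one ocular
#' magnetic reference (`MOG_REF`), one cardiac magnetic reference (`MCG_REF`)
#' and one stimulus trigger line (`TRIGGER`).
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_roles character vector, one of `"MEG"`, `"MOG_REF"`,
#'   `"MCG_REF"`, `"TRIGGER"` per row of `data`. Exactly one of each
#'   reference/trigger role must be present.
#' @return an object of class `recording`.
#' @export
recording <- function(data, sampling_rate, channel_roles) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  stopifnot_scalar(sampling_rate, "sampling_rate")
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != nrow(data)) {
    stop("one channel role per data row is required", call. = FALSE)
  }
  allowed <- c("MEG", "MOG_REF", "MCG_REF", "TRIGGER")
  if (!all(channel_roles %in% allowed)) {
    stop("channel roles must be MEG, MOG_REF, MCG_REF or TRIGGER",
         call. = FALSE)
  }
  for (role in c("MOG_REF", "MCG_REF", "TRIGGER")) {
    if (sum(channel_roles == role) != 1L) {
      stop(sprintf("exactly one %s channel is required", role), call. = FALSE)
    }
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_roles = channel_roles),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz (%d MEG, refs: MOG, MCG, trigger)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    sum(x$channel_roles == "MEG")))
  invisible(x)
}

#' Extract channels of a given role
#'
#' @param rec a [recording()].
#' @param role a channel role string.
#' @return for `"MEG"` a matrix (channels x samples); for the unique
#'   reference/trigger roles a numeric vector.
#' @export
channel_data <- function(rec, role = c("MEG", "MOG_REF", "MCG_REF", "TRIGGER")) {
  role <- match.arg(role)
  idx <- which(rec$channel_roles == role)
  if (role == "MEG") {
    rec$data[idx, , drop = FALSE]
  } else {
    rec$data[idx, ]
  }
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate
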