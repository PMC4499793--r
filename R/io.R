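# Plain-text readers/writers for the pipeline's interchange formats:
# event trains and step annotations as CSV, traces as CSV with a JSON
# sidecar carrying sampling metadata, frame stacks as multi-page TIFF.

#' Write / read an event train as CSV
#'
#' Columns `time_s` and (when present) `amplitude_pA`.
#'
#' @param train An [event_train()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); an [event_train()] (reader).
#' @export
write_event_train <- function(train, path) {
  df <- data.frame(time_s = train$times)
  if (!is.null(train$amps)) df$amplitude_pA <- train$amps
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_train
#' @param modality,duration Passed to [event_train()] on read.
#' @export
read_event_train <- function(path, modality = "generic", duration = NULL) {
  df <- utils::read.csv(path)
  event_train(df$time_s, df$amplitude_pA, modality = modality,
              duration = duration)
}

#' Write / read a sampled trace as CSV plus JSON sidecar
#'
#' The CSV holds one `value` column; `<path>.json` records `fs_hz`,
#' `units` and `t0_s`.
#'
#' @param trace A [ts_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [ts_trace()] (reader).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(value = trace$values), path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = trace$fs, units = trace$units,
                            t0_s = trace$t0),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ts_trace(utils::read.csv(path)$value, meta$fs_hz, meta$units, meta$t0_s)
}

#' Write / read a step annotation as per-frame CSV
#'
#' Long format `frame,limb,phase` with phase in `{swing, stance, quiet}`;
#' the reader reconstitutes intervals from runs of equal phase.
#'
#' @param ann A [step_annotation()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [step_annotation()] (reader).
#' @export
write_step_annotation <- function(ann, path) {
  st <- frame_states(ann)
  df <- data.frame(frame = rep(seq_len(nrow(st)), ncol(st)),
                   limb = rep(colnames(st), each = nrow(st)),
                   phase = as.vector(st))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_step_annotation
#' @param fps Frame rate of the annotation, Hz.
#' @export
read_step_annotation <- function(path, fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- list()
  for (lb in unique(df$limb)) {
    sub <- df[df$limb == lb, ]
    sub <- sub[order(sub$frame), ]
    r <- rle(sub$phase)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == "quiet") next
      rows[[length(rows) + 1L]] <- data.frame(
        limb = lb, phase = r$values[j],
        start_s = (starts[j] - 1) / fps, end_s = ends[j] / fps,
        stringsAsFactors = FALSE)
    }
  }
  iv <- if (length(rows)) do.call(rbind, rows)
        else data.frame(limb = character(0), phase = character(0),
                        start_s = numeric(0), end_s = numeric(0))
  step_annotation(iv, fps, max(df$frame) / fps)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly (writer); a [frame_stack()] (reader).
#' @export
write_frames_tiff <- function(stack, path) {
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(i) stack$frames[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @param fps Frame rate to attach on read, Hz.
#' @export
read_frames_tiff <- function(path, fps = 30) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * 255)
  frame_stack(arr, fps)
}
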