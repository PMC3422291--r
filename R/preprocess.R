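#' Construct a multichannel recording
#'
#' Container for a continuous recording: a channels x samples matrix in
#' microvolts, the sampling rate, channel labels, optional 2-D scalp
#' positions, and an event table. Sample indices in `events` are 1-based.
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (default `ch1..chN`).
#' @param events Data frame with integer columns `sample` and `code`.
#' @param positions Optional n_channels x 2 matrix of scalp coordinates.
#' @param participant_id Identifier carried through epoching.
#' @return A `recording` object.
#' @export
as_recording <- function(data, fs, labels = NULL,
                         events = data.frame(sample = integer(0),
                                             code = integer(0)),
                         positions = NULL, participant_id = 1L) {
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("got ", length(labels), " labels for ", nrow(data), " channels")
  }
  events <- as.data.frame(events)
  stopifnot(all(c("sample", "code") %in% names(events)))
  events$sample <- as.integer(events$sample)
  events$code <- as.integer(events$code)
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  storage.mode(data) <- "double"
  structure(list(data = data, fs = fs, labels = labels, events = events,
                 positions = positions, participant_id = participant_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channels x %d samples @ %g Hz, %d events>\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Default event code table
#'
#' @param f1_onset,f1_keypress,f2_onset,resp_left,resp_right Integer codes
#'   marking first-face onset, the keypress ending the first face, the
#'   second-face onset, and the left/right preference responses.
#' @return Named list of codes.
#' @export
event_codes <- function(f1_onset = 1L, f1_keypress = 2L, f2_onset = 3L,
                        resp_left = 4L, resp_right = 5L) {
  list(f1_onset = f1_onset, f1_keypress = f1_keypress, f2_onset = f2_onset,
       resp_left = resp_left, resp_right = resp_right)
}

#' Load a recording from disk
#'
#' Supported dialects: `"matrix"`, the package's own plain-text layout (a
#' directory with `header.json` and `data.tsv`, see [write_recording()]);
#' `"bdf"` and `"edf"`, the standard 24-bit / 16-bit polygraphic exchange
#' formats. For BDF/EDF, events are taken from a `Status` trigger channel
#' when present (lower 16 bits, change-to-nonzero onsets), otherwise from
#' the `events` argument.
#'
#' @param path File (BDF/EDF) or directory (matrix).
#' @param format One of `"matrix"`, `"bdf"`, `"edf"`; default guesses from
#'   the file extension.
#' @param events Optional event data frame overriding any embedded events.
#' @return A `recording`.
#' @export
load_recording <- function(path, format = NULL, events = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "matrix"
              else tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("matrix", "bdf", "edf"))
  rec <- switch(format,
    matrix = read_recording_matrix(path),
    bdf = read_edf_bdf(path, bits = 24L),
    edf = read_edf_bdf(path, bits = 16L)
  )
  if (!is.null(events)) {
    rec$events <- as.data.frame(events)[order(events$sample), , drop = FALSE]
  }
  if (nrow(rec$events) == 0L) {
    stop("no events in recording ", path,
         " (no Status channel triggers and no `events` supplied)")
  }
  rec
}

#' Write a recording in the matrix dialect
#'
#' The matrix dialect is a directory holding `header.json` (fs, labels,
#' events, participant id, optional positions) and `data.tsv` (samples in
#' rows, one column per channel).
#'
#' @param rec A `recording`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(fs = rec$fs, labels = rec$labels,
                 participant_id = rec$participant_id,
                 events = rec$events,
                 positions = rec$positions)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(t(rec$data), file.path(path, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_recording_matrix <- function(path) {
  hfile <- file.path(path, "header.json")
  dfile <- file.path(path, "data.tsv")
  if (!file.exists(hfile) || !file.exists(dfile)) {
    stop("not a matrix-dialect recording: ", path,
         " (need header.json and data.tsv)")
  }
  h <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  data <- t(as.matrix(utils::read.table(dfile, sep = "\t", header = FALSE)))
  dimnames(data) <- NULL
  if (nrow(data) != length(h$labels)) {
    stop("header declares ", length(h$labels), " channels but data.tsv has ",
         nrow(data))
  }
  ev <- if (is.null(h$events) || length(h$events) == 0L) {
    data.frame(sample = integer(0), code = integer(0))
  } else as.data.frame(h$events)
  pos <- if (is.null(h$positions)) NULL else as.matrix(h$positions)
  as_recording(data, h$fs, h$labels, ev, pos,
               if (is.null(h$participant_id)) 1L else h$participant_id)
}

#' Re-reference to linked mastoids
#'
#' Subtracts the sample-wise average of the two mastoid channels from every
#' other channel and drops the mastoids.
#'
#' @param rec A `recording`.
#' @param mastoid_labels Labels of the two mastoid channels.
#' @return A `recording` without the mastoid channels.
#' @export
rereference_to_mastoids <- function(rec, mastoid_labels = c("M1", "M2")) {
  stopifnot(inherits(rec, "recording"), length(mastoid_labels) == 2L)
  miss <- setdiff(mastoid_labels, rec$labels)
  if (length(miss) > 0L) {
    stop("mastoid channel(s) not found in recording: ",
         paste(miss, collapse = ", "))
  }
  mi <- match(mastoid_labels, rec$labels)
  ref <- (rec$data[mi[1L], ] + rec$data[mi[2L], ]) / 2
  keep <- setdiff(seq_len(nrow(rec$data)), mi)
  data <- rec$data[keep, , drop = FALSE] -
    matrix(ref, length(keep), ncol(rec$data), byrow = TRUE)
  as_recording(data, rec$fs, rec$labels[keep], rec$events,
               if (is.null(rec$positions)) NULL
               else rec$positions[keep, , drop = FALSE],
               rec$participant_id)
}

#' Epoch a recording and label trials by final choice
#'
#' Cuts one epoch of (1 s + `tail_samples`) from each face onset and labels
#' both epochs of a trial by the final preference response: choosing face 1
#' yields (F1 chosen, F2 not chosen), choosing face 2 the reverse. Epochs
#' that would run past the end of the recording drop their trial with a
#' warning.
#'
#' @param rec A `recording` (already re-referenced / cleaned).
#' @param tail_samples Embedding tail in samples beyond the analysis second
#'   (default [embedding_tail()]).
#' @param codes Event code table from [event_codes()].
#' @param face1_response Which response code means "face 1 chosen":
#'   `"left"` or `"right"` (counterbalanced across participants).
#' @param reject_uv Optional absolute-amplitude artifact threshold in
#'   microvolts; trials whose either epoch exceeds it are dropped (default
#'   `NULL`, off).
#' @return List with `trialset` elements `F1` and `F2`.
#' @export
epoch_and_label <- function(rec, tail_samples = embedding_tail(),
                            codes = event_codes(),
                            face1_response = c("left", "right"),
                            reject_uv = NULL) {
  stopifnot(inherits(rec, "recording"))
  face1_response <- match.arg(face1_response)
  face1_code <- if (face1_response == "left") codes$resp_left
                else codes$resp_right
  fs <- rec$fs
  n1s <- round(fs)
  n_samp <- n1s + tail_samples
  windows <- window_grid(fs)
  ev <- rec$events
  resp_codes <- c(codes$resp_left, codes$resp_right)

  f1_at <- ev$sample[ev$code == codes$f1_onset]
  epochs_f1 <- list(); epochs_f2 <- list(); labels_f1 <- character(0)
  dropped <- 0L
  for (t in seq_along(f1_at)) {
    lo <- f1_at[t]
    hi <- if (t < length(f1_at)) f1_at[t + 1L] else Inf
    within <- ev[ev$sample > lo & ev$sample < hi, , drop = FALSE]
    f2 <- within$sample[within$code == codes$f2_onset][1L]
    if (is.na(f2)) next                       # not a complete trial
    resp <- within$code[within$code %in% resp_codes & within$sample > f2][1L]
    if (is.na(resp)) next
    if (f2 + n_samp - 1L > ncol(rec$data) ||
        lo + n_samp - 1L > ncol(rec$data)) {
      dropped <- dropped + 1L
      next
    }
    e1 <- rec$data[, lo:(lo + n_samp - 1L), drop = FALSE]
    e2 <- rec$data[, f2:(f2 + n_samp - 1L), drop = FALSE]
    if (!is.null(reject_uv) &&
        (max(abs(e1)) > reject_uv || max(abs(e2)) > reject_uv)) next
    epochs_f1[[length(epochs_f1) + 1L]] <- e1
    epochs_f2[[length(epochs_f2) + 1L]] <- e2
    labels_f1 <- c(labels_f1,
                   if (resp == face1_code) "chosen" else "not_chosen")
  }
  if (dropped > 0L) {
    warning(dropped, " trial(s) dropped: epoch extends past end of recording")
  }
  n <- length(epochs_f1)
  nch <- nrow(rec$data)
  to_array <- function(lst) {
    a <- array(0, c(n, nch, n_samp))
    for (i in seq_len(n)) a[i, , ] <- lst[[i]]
    a
  }
  lv <- c("chosen", "not_chosen")
  f1_labels <- factor(labels_f1, levels = lv)
  f2_labels <- factor(ifelse(labels_f1 == "chosen", "not_chosen", "chosen"),
                      levels = lv)
  pid <- rep(rec$participant_id, n)
  list(
    F1 = new_trialset(to_array(epochs_f1), f1_labels, pid, fs, windows,
                      face = "F1", n_analysis = n1s),
    F2 = new_trialset(to_array(epochs_f2), f2_labels, pid, fs, windows,
                      face = "F2", n_analysis = n1s)
  )
}

#' Synthetic concentric-ring electrode layout
#'
#' Generic 2-D scalp coordinates (unit head circle) for plotting when no
#' measured montage is available: electrodes on concentric rings, vertex
#' first. This is a synthetic layout, not a standard montage.
#'
#' @param n Number of electrodes.
#' @return n x 2 matrix of (x, y) positions.
#' @export
radial_layout <- function(n) {
  pos <- matrix(0, n, 2L)
  # ring k holds up to 6k electrodes; count rings needed first
  n_rings <- 0L; cap <- 1L
  while (cap < n) {
    n_rings <- n_rings + 1L
    cap <- cap + 6L * n_rings
  }
  placed <- 1L                     # electrode 1 at the vertex
  ring <- 1L
  while (placed < n) {
    r <- ring / max(n_rings, 1L)
    k <- min(n - placed, 6L * ring)
    ang <- 2 * pi * (seq_len(k) - 1L) / k + pi / 2
    pos[(placed + 1L):(placed + k), ] <- cbind(r * cos(ang), r * sin(ang))
    placed <- placed + k
    ring <- ring + 1L
  }
  pos
}
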