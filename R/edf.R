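# Minimal reader/writer for the EDF (16-bit) and BDF (24-bit) polygraphic
# exchange formats: fixed 256-byte ASCII header, 256 bytes per signal of
# per-channel metadata, then data records of little-endian integers scaled
# to physical units. Trigger events follow the BioSemi convention: a channel
# labelled "Status" whose lower 16 bits carry the trigger code; an event is
# a change of that code to a nonzero value.

read_ascii_field <- function(con, nbytes) {
  trimws(rawToChar(readBin(con, "raw", nbytes)))
}

read_edf_bdf <- function(path, bits = c(24L, 16L)) {
  bits <- bits[1L]
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readBin(con, "raw", 8L)
  if (bits == 24L) {
    if (magic[1L] != as.raw(255L) ||
        rawToChar(magic[2:8]) != "BIOSEMI") {
      stop(path, " is not a BDF file (bad magic bytes)")
    }
  } else {
    if (trimws(rawToChar(magic)) != "0") {
      stop(path, " is not an EDF file (bad version field)")
    }
  }
  invisible(read_ascii_field(con, 160L))     # patient + recording id
  invisible(read_ascii_field(con, 16L))      # start date/time
  invisible(read_ascii_field(con, 8L))       # header byte count
  invisible(read_ascii_field(con, 44L))      # reserved
  n_records <- as.integer(read_ascii_field(con, 8L))
  rec_dur <- as.numeric(read_ascii_field(con, 8L))
  ns <- as.integer(read_ascii_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed header: no signals declared")

  fld <- function(nb) vapply(seq_len(ns), function(i) read_ascii_field(con, nb), "")
  labels <- fld(16L)
  invisible(fld(80L))                        # transducer
  invisible(fld(8L))                         # physical dimension
  phys_min <- as.numeric(fld(8L))
  phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L))
  dig_max <- as.numeric(fld(8L))
  invisible(fld(80L))                        # prefilter
  spr <- as.integer(fld(8L))                 # samples per record
  invisible(fld(32L))                        # reserved
  if (length(unique(spr)) != 1L) {
    stop("signals with differing samples-per-record are not supported (got ",
         paste(unique(spr), collapse = ", "), ")")
  }
  spr1 <- spr[1L]
  fs <- spr1 / rec_dur

  n_total <- n_records * spr1
  dig <- matrix(0, ns, n_total)
  bytes_per <- bits %/% 8L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      at <- ((r - 1L) * spr1 + 1L):(r * spr1)
      if (bits == 16L) {
        dig[s, at] <- readBin(con, "integer", spr1, size = 2L,
                              signed = TRUE, endian = "little")
      } else {
        raw3 <- readBin(con, "raw", spr1 * 3L)
        b <- matrix(as.integer(raw3), 3L, spr1)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        v <- ifelse(v >= 8388608L, v - 16777216L, v)
        dig[s, at] <- v
      }
    }
  }

  status <- which(labels == "Status")
  events <- data.frame(sample = integer(0), code = integer(0))
  if (length(status) == 1L) {
    trig <- bitwAnd(as.integer(dig[status, ]), 65535L)
    changed <- which(diff(c(0L, trig)) != 0L & trig != 0L)
    events <- data.frame(sample = changed, code = trig[changed])
  }
  keep <- setdiff(seq_len(ns), status)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- dig[keep, , drop = FALSE] * gain[keep] +
    (phys_min[keep] - dig_min[keep] * gain[keep])
  as_recording(data, fs, labels[keep], events)
}

pad_field <- function(x, nb) {
  x <- as.character(x)
  vapply(x, function(s) {
    if (nchar(s) > nb) s <- substr(s, 1L, nb)
    formatC(s, width = -nb)
  }, "", USE.NAMES = FALSE)
}

# Writer used for fixtures and round-trip checks. Data are quantized to the
# digital grid (identity scaling by default, so integer-valued microvolt
# data round-trip exactly). A Status channel is appended when events are
# present.
write_edf_bdf <- function(rec, path, bits = c(24L, 16L)) {
  bits <- bits[1L]
  stopifnot(inherits(rec, "recording"))
  data <- rec$data
  labels <- rec$labels
  nch <- nrow(data)
  spr <- round(rec$fs)               # 1-second records
  n_records <- ceiling(ncol(data) / spr)
  n_total <- n_records * spr
  if (n_total > ncol(data)) {
    data <- cbind(data, matrix(0, nch, n_total - ncol(data)))
  }
  has_status <- nrow(rec$events) > 0L
  if (has_status && max(rec$events$sample) > n_total) {
    stop("event at sample ", max(rec$events$sample),
         " lies beyond the recording (", n_total, " samples)")
  }
  if (has_status) {
    trig <- integer(n_total)
    trig[rec$events$sample] <- rec$events$code
    # hold each code for 10 samples so change-detection round-trips
    for (i in seq_len(nrow(rec$events))) {
      at <- rec$events$sample[i]
      trig[at:min(n_total, at + 9L)] <- rec$events$code[i]
    }
    data <- rbind(data, trig)
    labels <- c(labels, "Status")
    nch <- nch + 1L
  }
  dmax <- if (bits == 24L) 8388607 else 32767
  dmin <- if (bits == 24L) -8388608 else -32768

  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 24L) {
    writeBin(as.raw(255L), con)
    writeBin(charToRaw("BIOSEMI"), con)
  } else {
    writeBin(charToRaw(pad_field("0", 8L)), con)
  }
  w <- function(x, nb) writeBin(charToRaw(paste(pad_field(x, nb),
                                                collapse = "")), con)
  w("local patient", 80L)
  w("local recording", 80L)
  w("01.01.26", 8L); w("00.00.00", 8L)
  w(as.character(256L * (nch + 1L)), 8L)
  w(if (bits == 24L) "24BIT" else "", 44L)
  w(as.character(n_records), 8L)
  w("1", 8L)
  w(as.character(nch), 4L)
  w(labels, 16L)
  w(rep("", nch), 80L)
  w(rep("uV", nch), 8L)
  w(rep(as.character(dmin), nch), 8L)
  w(rep(as.character(dmax), nch), 8L)
  w(rep(as.character(dmin), nch), 8L)
  w(rep(as.character(dmax), nch), 8L)
  w(rep("", nch), 80L)
  w(rep(as.character(spr), nch), 8L)
  w(rep("", nch), 32L)

  dig <- round(data)
  dig[dig > dmax] <- dmax
  dig[dig < dmin] <- dmin
  for (r in seq_len(n_records)) {
    at <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(nch)) {
      v <- as.integer(dig[s, at])
      if (bits == 16L) {
        writeBin(v, con, size = 2L, endian = "little")
      } else {
        vv <- ifelse(v < 0L, v + 16777216L, v)
        b <- rbind(vv %% 256L, (vv %/% 256L) %% 256L, vv %/% 65536L)
        writeBin(as.raw(b), con)
      }
    }
  }
  invisible(path)
}
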