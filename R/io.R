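#' Read an EEG record from an EDF file
#'
#' Minimal reader for the European Data Format (EDF): fixed-width ASCII
#' header, 16-bit little-endian samples, physical scaling per signal.
#' EDF+ annotation channels are not interpreted. All signals must share one
#' sampling rate. Returned records carry all-zero fine-grained labels
#' (EDF stores no per-step seizure annotation).
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel names to select, in
#'   order (e.g. the 19-name 10-20 list). Each name is matched
#'   case-insensitively against EDF signal labels on token boundaries
#'   (`"EEG FP1-REF"` matches `"Fp1"`); a name with no match raises an
#'   error naming the missing channel.
#' @return An [eeg_record].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_str(8)                               # version
  rd_str(80); rd_str(80)                  # patient, recording
  rd_str(8); rd_str(8)                    # start date, time
  rd_str(8)                               # header bytes
  rd_str(44)                              # reserved
  n_rec <- as.integer(rd_str(8))
  rec_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  if (!is.finite(ns) || ns < 1L) stop("unreadable EDF header", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) rd_str(w), "")
  labels <- fld(16)
  fld(80)                                 # transducer
  fld(8)                                  # physical dimension
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)                                 # prefiltering
  spr <- as.integer(fld(8))               # samples per record
  fld(32)                                 # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals with mixed sampling rates are not supported",
         call. = FALSE)
  n_per <- spr[1L]
  fs <- n_per / rec_dur
  sig <- matrix(0, nrow = n_rec * n_per, ncol = ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw16 <- readBin(con, "integer", n = n_per, size = 2L,
                       signed = TRUE, endian = "little")
      scale <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      rows <- ((r - 1L) * n_per + 1L):(r * n_per)
      sig[rows, s] <- pmin_[s] + (raw16 - dmin_[s]) * scale
    }
  }
  if (!is.null(channels)) {
    idx <- vapply(channels, function(nm) {
      pat <- paste0("(^|[^A-Za-z0-9])", nm, "([^A-Za-z0-9]|$)")
      hit <- grep(pat, labels, ignore.case = TRUE)
      if (!length(hit)) hit <- grep(toupper(nm), toupper(labels),
                                    fixed = TRUE)
      if (!length(hit))
        stop(sprintf("EDF file lacks channel '%s'", nm), call. = FALSE)
      hit[1L]
    }, integer(1))
    sig <- sig[, idx, drop = FALSE]
    labels <- channels
  }
  eeg_record(sig, fs, channel_names = labels,
             record_id = sub("\\.edf$", "", basename(path),
                             ignore.case = TRUE))
}

#' Write an EEG record to an EDF file
#'
#' Companion writer used to build test fixtures and export synthetic
#' records. Samples are quantised to 16 bits over each channel's observed
#' physical range, so a read-back agrees to quantisation precision (about
#' 1/65000 of the per-channel range), not bitwise. The record length must be
#' a whole number of seconds at an integer sampling rate.
#'
#' @param record an [eeg_record] with integer `fs` and `N_total` divisible
#'   by `fs`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (fs != round(fs)) stop("write_edf requires integer fs", call. = FALSE)
  n <- nrow(record$signal); ns <- ncol(record$signal)
  if (n %% fs != 0)
    stop("record length must be a whole number of seconds", call. = FALSE)
  n_rec <- n %/% fs
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) {
    s <- substr(sprintf(paste0("%-", w, "s"), x), 1L, w)
    writeBin(charToRaw(s), con)
  }
  pmin_ <- apply(record$signal, 2, min)
  pmax_ <- apply(record$signal, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  wr("0", 8); wr("X X X X", 80); wr(paste("Startdate X", record$record_id), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(format(256L * (ns + 1L)), 8); wr("", 44)
  wr(format(n_rec), 8); wr("1", 8); wr(format(ns), 4)
  for (nm in record$channel_names) wr(paste0("EEG ", nm, "-REF"), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(formatC(v, digits = 6, format = "g"), 8)
  for (v in pmax_) wr(formatC(v, digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(format(as.integer(fs)), 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- vapply(seq_len(ns), function(s) {
    v <- (record$signal[, s] - pmin_[s]) / (pmax_[s] - pmin_[s])
    as.integer(round(-32768 + v * 65535))
  }, integer(n))
  dig <- matrix(dig, nrow = n)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns))
      writeBin(dig[rows, s], con, size = 2L, endian = "little")
  }
  invisible(path)
}

CLIPSET_MAGIC <- "DTGCNCS1"

#' Read / write a clip set as a flat binary container
#'
#' Lossless container for a list of [eeg_clip] objects. The layout is a
#' documented little-endian flat binary format (no HDF5 binding is assumed):
#' an 8-byte magic `"DTGCNCS1"`, `int32` clip count and channel count,
#' `double` fs and clip_seconds, length-prefixed UTF-8 channel names, then
#' per clip: `int32` N, `int32` seizure-class index, length-prefixed parent
#' id, `N x M` doubles in column-major order, and `N` single-byte labels.
#' Doubles round-trip bitwise.
#'
#' @param clips list of [eeg_clip] objects sharing fs, channel count and
#'   duration.
#' @param path file path.
#' @return `write_clipset` returns `path` invisibly; `read_clipset` returns
#'   the list of clips.
#' @export
write_clipset <- function(clips, path) {
  stopifnot(length(clips) > 0L, all(vapply(clips, inherits, TRUE, "eeg_clip")))
  fs <- clips[[1L]]$fs; m <- ncol(clips[[1L]]$signal)
  secs <- clips[[1L]]$clip_seconds
  ok <- vapply(clips, function(cl)
    cl$fs == fs && ncol(cl$signal) == m && cl$clip_seconds == secs, TRUE)
  if (!all(ok)) stop("clips must share fs, channels and duration", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  wstr <- function(s) {
    b <- charToRaw(enc2utf8(s))
    writeBin(length(b), con, size = 4L, endian = "little")
    writeBin(b, con)
  }
  writeBin(charToRaw(CLIPSET_MAGIC), con)
  writeBin(c(length(clips), m), con, size = 4L, endian = "little")
  writeBin(c(fs, secs), con, size = 8L, endian = "little")
  for (nm in clips[[1L]]$channel_names) wstr(nm)
  cls <- seizure_classes()
  for (cl in clips) {
    writeBin(c(nrow(cl$signal), match(cl$seizure_class, cls) - 1L),
             con, size = 4L, endian = "little")
    wstr(cl$parent_id)
    writeBin(as.vector(cl$signal), con, size = 8L, endian = "little")
    writeBin(as.raw(cl$fine_labels), con)
  }
  invisible(path)
}

#' @rdname write_clipset
#' @export
read_clipset <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(CLIPSET_MAGIC)))
  if (!identical(magic, CLIPSET_MAGIC))
    stop("not a clip-set file (bad magic)", call. = FALSE)
  rint <- function(k) readBin(con, "integer", k, size = 4L, endian = "little")
  rstr <- function() rawToChar(readBin(con, "raw", rint(1L)))
  hd <- rint(2L); n_clips <- hd[1L]; m <- hd[2L]
  num <- readBin(con, "double", 2L, size = 8L, endian = "little")
  fs <- num[1L]; secs <- num[2L]
  ch <- vapply(seq_len(m), function(i) rstr(), "")
  cls <- seizure_classes()
  lapply(seq_len(n_clips), function(i) {
    meta <- rint(2L)
    n <- meta[1L]; klass <- cls[meta[2L] + 1L]
    pid <- rstr()
    sig <- matrix(readBin(con, "double", n * m, size = 8L,
                          endian = "little"), nrow = n)
    lab <- as.integer(readBin(con, "raw", n))
    eeg_clip(sig, fs, lab, klass, clip_seconds = secs, parent_id = pid,
             channel_names = ch)
  })
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the full model configuration (JSON) together with all
#' learnable parameters as raw doubles, so a loaded model reproduces
#' bit-identical forward passes.
#'
#' @param model a [dtgcn_model].
#' @param path file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the restored [dtgcn_model].
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dtgcn_model"))
  con <- file(path, "wb")
  on.exit(close(con))
  shapes <- lapply(model$params, dim)
  header <- jsonlite::toJSON(
    list(config = unclass(model$config), tau = model$tau,
         param_names = names(model$params),
         param_shapes = shapes,
         layout_names = model$layout$names),
    auto_unbox = TRUE, digits = NA)
  hb <- charToRaw(header)
  writeBin(charToRaw("DTGCNCK1"), con)
  writeBin(length(hb), con, size = 4L, endian = "little")
  writeBin(hb, con)
  # layout coordinates and parameters as raw doubles (bitwise round trip)
  writeBin(as.vector(model$layout$coords), con, size = 8L,
           endian = "little")
  for (p in model$params)
    writeBin(as.vector(p), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "DTGCNCK1"))
    stop("not a checkpoint file", call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hd <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                           simplifyVector = TRUE)
  cfg <- do.call(model_config, hd$config)
  m <- length(hd$layout_names)
  coords <- matrix(readBin(con, "double", 3L * m, size = 8L,
                           endian = "little"), m, 3L)
  layout <- electrode_layout(hd$layout_names, coords)
  model <- dtgcn_model(cfg, layout = layout)
  for (nm in hd$param_names) {
    shp <- hd$param_shapes[[nm]]
    v <- readBin(con, "double", prod(shp), size = 8L, endian = "little")
    model$params[[nm]] <- matrix(v, nrow = shp[1L], ncol = shp[2L])
  }
  model$tau <- if (is.null(hd$tau)) NA_real_ else hd$tau
  model
}
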