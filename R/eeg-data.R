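#' EEG record container
#'
#' An `eeg_record` holds a multichannel EEG signal as an N x M real matrix
#' (time steps in rows, channels in columns, microvolts), its sampling
#' frequency, channel names, a per-time-step binary seizure annotation
#' ("fine-grained" labels), and an optional seizure class for the record.
#'
#' @param signal numeric matrix, `N_total x M`.
#' @param fs sampling frequency in Hz, positive scalar.
#' @param channel_names character vector of length `M`.
#' @param fine_labels integer/numeric vector of 0/1, length `N_total`.
#'   Defaults to all zeros.
#' @param seizure_class one of `"none"`, `"CF"`, `"GN"`, `"AB"`, `"CT"`.
#' @param record_id character scalar identifying the record.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, channel_names = NULL,
                       fine_labels = NULL,
                       seizure_class = "none",
                       record_id = "record") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar", call. = FALSE)
  m <- ncol(signal)
  if (m < 1L) stop("signal must have at least one channel", call. = FALSE)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(m))
  if (length(channel_names) != m)
    stop("length(channel_names) must equal ncol(signal)", call. = FALSE)
  if (is.null(fine_labels)) fine_labels <- integer(nrow(signal))
  fine_labels <- as.integer(fine_labels)
  if (length(fine_labels) != nrow(signal))
    stop("fine_labels length must equal nrow(signal)", call. = FALSE)
  if (length(fine_labels) && !all(fine_labels %in% c(0L, 1L)))
    stop("fine_labels must be binary 0/1", call. = FALSE)
  seizure_class <- match.arg(seizure_class, seizure_classes())
  structure(
    list(signal = signal, fs = fs,
         channel_names = as.character(channel_names),
         fine_labels = fine_labels,
         seizure_class = seizure_class,
         record_id = as.character(record_id)),
    class = "eeg_record")
}

#' Seizure class levels
#'
#' The four seizure classes plus `"none"`: combined focal (CF), generalized
#' non-specific (GN), absence (AB), and tonic-clonic/tonic (CT).
#' @return Character vector of the five levels.
#' @export
seizure_classes <- function() c("none", "CF", "GN", "AB", "CT")

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s'>  %d steps x %d channels @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  cat(sprintf("  seizure_class: %s; seizure steps: %d/%d\n",
              x$seizure_class, sum(x$fine_labels), length(x$fine_labels)))
  invisible(x)
}

#' EEG clip container
#'
#' A fixed-length slice of a record used as one model input. The
#' coarse-grained label is 1 iff any fine-grained label inside the clip is 1,
#' and a clip with coarse label 0 is always of class `"none"` even when its
#' parent record carries a seizure class.
#'
#' @param signal numeric matrix `N x M` with `N = clip_seconds * fs`.
#' @param fs sampling frequency (Hz).
#' @param fine_labels binary vector of length `N`.
#' @param seizure_class seizure class of the parent record.
#' @param clip_seconds clip duration in seconds (12 or 60 in the study
#'   protocol; any positive value is accepted).
#' @param parent_id identifier of the parent record.
#' @param channel_names optional channel names.
#' @return An object of class `eeg_clip`; its `coarse_label` element is
#'   derived, never supplied.
#' @export
eeg_clip <- function(signal, fs, fine_labels, seizure_class = "none",
                     clip_seconds = nrow(as.matrix(signal)) / fs,
                     parent_id = "record", channel_names = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  fine_labels <- as.integer(fine_labels)
  if (length(fine_labels) != nrow(signal))
    stop("fine_labels length must equal nrow(signal)", call. = FALSE)
  if (abs(nrow(signal) - clip_seconds * fs) > 1e-8)
    stop("nrow(signal) must equal clip_seconds * fs", call. = FALSE)
  coarse <- derive_coarse_label(fine_labels)
  seizure_class <- match.arg(seizure_class, seizure_classes())
  if (coarse == 0L) seizure_class <- "none"
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(signal)))
  structure(
    list(signal = signal, fs = fs, fine_labels = fine_labels,
         coarse_label = coarse, seizure_class = seizure_class,
         clip_seconds = clip_seconds, parent_id = as.character(parent_id),
         channel_names = as.character(channel_names)),
    class = "eeg_clip")
}

#' @export
print.eeg_clip <- function(x, ...) {
  cat(sprintf("<eeg_clip of '%s'>  %d x %d @ %g Hz, label %d (%s)\n",
              x$parent_id, nrow(x$signal), ncol(x$signal), x$fs,
              x$coarse_label, x$seizure_class))
  invisible(x)
}

#' Derive the coarse-grained label from fine-grained labels
#'
#' The coarse label of a clip is 1 iff at least one of its per-time-step
#' labels is 1 (equivalently, `max(fine_labels)`).
#'
#' @param fine_labels binary vector.
#' @return Integer 0 or 1.
#' @export
derive_coarse_label <- function(fine_labels) {
  if (length(fine_labels) == 0L)
    stop("fine_labels must be non-empty", call. = FALSE)
  fine_labels <- as.integer(fine_labels)
  if (!all(fine_labels %in% c(0L, 1L)))
    stop("fine_labels must be binary 0/1", call. = FALSE)
  as.integer(any(fine_labels == 1L))
}

#' Resample an EEG record to a new sampling frequency
#'
#' The signal is resampled by linear interpolation onto the new uniform time
#' grid (no anti-alias filtering is applied; band-pass filtering is outside
#' the scope of this package). Fine-grained labels are mapped by
#' nearest-neighbour index lookup so they remain strictly binary.
#'
#' @param record an [eeg_record].
#' @param target_fs target sampling frequency (Hz).
#' @return A new [eeg_record] with `round(N_total * target_fs / fs)` rows.
#' @export
resample_signal <- function(record, target_fs) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0)
    stop("`target_fs` must be a positive scalar", call. = FALSE)
  if (target_fs == record$fs) return(record)
  n_in <- nrow(record$signal)
  n_out <- round(n_in * target_fs / record$fs)
  if (n_out < 1L) stop("resampled record would be empty", call. = FALSE)
  # sample i (0-based) sits at time i / fs
  t_in <- (seq_len(n_in) - 1) / record$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  sig <- apply(record$signal, 2L, function(col)
    stats::approx(t_in, col, xout = t_out, rule = 2)$y)
  sig <- matrix(sig, nrow = n_out)
  nn <- pmin(pmax(round(t_out * record$fs) + 1L, 1L), n_in)
  eeg_record(sig, target_fs, record$channel_names,
             record$fine_labels[nn], record$seizure_class, record$record_id)
}

#' Slice a record into fixed-length clips
#'
#' Produces consecutive non-overlapping clips of exactly
#' `clip_seconds * fs` time steps; a trailing remainder shorter than one clip
#' is dropped (with a warning when the whole record is shorter than a single
#' clip, in which case an empty list is returned). Clips are half-open
#' intervals `[start, start + N)` in 0-based time-step indexing.
#'
#' @param record an [eeg_record].
#' @param clip_seconds clip duration in seconds (the study protocol uses 12
#'   or 60).
#' @return List of [eeg_clip] objects.
#' @export
slice_clips <- function(record, clip_seconds = 12) {
  stopifnot(inherits(record, "eeg_record"))
  n_clip <- round(clip_seconds * record$fs)
  if (n_clip < 1L) stop("clip_seconds * fs must be >= 1", call. = FALSE)
  n_total <- nrow(record$signal)
  k <- n_total %/% n_clip
  if (k == 0L) {
    warning(sprintf("record '%s' (%d steps) shorter than one %g s clip (%d steps); no clips produced",
                    record$record_id, n_total, clip_seconds, n_clip))
    return(list())
  }
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * n_clip + 1L):(i * n_clip)
    eeg_clip(record$signal[idx, , drop = FALSE], record$fs,
             record$fine_labels[idx], record$seizure_class,
             clip_seconds = clip_seconds, parent_id = record$record_id,
             channel_names = record$channel_names)
  })
}

#' Electrode layout
#'
#' Scalp electrode positions on the unit sphere, one row per electrode.
#'
#' @param names unique electrode names, length `M`.
#' @param coords `M x 3` matrix of unit-norm 3-D positions.
#' @return An object of class `electrode_layout`.
#' @seealso [standard_1020_layout()]
#' @export
electrode_layout <- function(names, coords) {
  names <- as.character(names)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (anyDuplicated(names)) stop("electrode names must be unique", call. = FALSE)
  if (nrow(coords) != length(names) || ncol(coords) != 3L)
    stop("coords must be length(names) x 3", call. = FALSE)
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("electrode coordinates must lie on the unit sphere", call. = FALSE)
  rownames(coords) <- names
  colnames(coords) <- c("x", "y", "z")
  structure(list(names = names, coords = coords), class = "electrode_layout")
}

#' Read / write an electrode layout as a plain-text table
#'
#' Tab-separated columns `name`, `x`, `y`, `z`, one row per electrode.
#'
#' @param path file path.
#' @param layout an [electrode_layout] (for writing).
#' @return `read_layout` returns an [electrode_layout]; `write_layout`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  electrode_layout(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "electrode_layout"))
  df <- data.frame(name = layout$names, layout$coords,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Predefined distance graph over electrodes ("Dist-Graph")
#'
#' Static weighted adjacency computed from physical electrode distances with
#' a thresholded Gaussian kernel:
#' `w(i,j) = exp(-d(i,j)^2 / sigma^2)` when that value is at least `kappa`,
#' else 0, with `d` the Euclidean distance between unit-sphere positions.
#' The matrix is symmetric by construction with entries in `[0, 1]`.
#'
#' @param layout an [electrode_layout] with `M >= 2` electrodes.
#' @param sigma kernel bandwidth; defaults to the maximum pairwise
#'   electrode distance, which at the default `kappa = 0.9` keeps exactly
#'   the nearest spatial neighbours of each electrode (a smaller bandwidth
#'   such as the distance standard deviation empties the graph at that
#'   threshold).
#' @param kappa sparsification threshold in `[0, 1)` below which weights are
#'   zeroed; default 0.9.
#' @param diag one of `"unit"` (default; self-weight `exp(0) = 1`) or
#'   `"zero"`.
#' @return An object of class `dist_graph` with elements `weights`
#'   (`M x M`), `kernel_sigma`, `threshold_kappa`, `names`.
#' @export
build_dist_graph <- function(layout, sigma = NULL, kappa = 0.9,
                             diag = c("unit", "zero")) {
  stopifnot(inherits(layout, "electrode_layout"))
  diag <- match.arg(diag)
  m <- length(layout$names)
  if (m < 2L) stop("need at least 2 electrodes", call. = FALSE)
  d <- as.matrix(stats::dist(layout$coords))
  if (is.null(sigma)) sigma <- max(d)
  if (!is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  w <- exp(-d^2 / sigma^2)
  w[w < kappa] <- 0
  if (diag == "zero") base::diag(w) <- 0 else base::diag(w) <- 1
  off <- w; base::diag(off) <- 0
  if (all(off == 0))
    stop("kappa leaves no edges between distinct electrodes (empty graph)",
         call. = FALSE)
  dimnames(w) <- list(layout$names, layout$names)
  structure(list(weights = w, kernel_sigma = sigma, threshold_kappa = kappa,
                 names = layout$names),
            class = "dist_graph")
}

#' @export
print.dist_graph <- function(x, ...) {
  off <- x$weights; diag(off) <- 0
  cat(sprintf("<dist_graph>  %d nodes, %d edges (sigma %.3f, kappa %.2f)\n",
              nrow(x$weights), sum(off > 0) / 2, x$kernel_sigma,
              x$threshold_kappa))
  invisible(x)
}
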