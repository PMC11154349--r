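#' The 19-channel 10-20 electrode layout
#'
#' Canonical 19 electrodes of the international 10-20 system with
#' idealised unit-sphere positions: circumferential electrodes sit 18
#' degrees above the equatorial plane spaced 36 degrees apart, midline and
#' central electrodes follow the 20%-arc rule, and F3/F4/P3/P4 are geodesic
#' midpoints of their neighbouring standard sites (the 10-20 construction).
#' Coordinates: x to the right ear, y to the nasion, z to the vertex.
#'
#' @return An [electrode_layout] with the 19 names Fp1, Fp2, F3, F4, C3,
#'   C4, P3, P4, O1, O2, F7, F8, T3, T4, T5, T6, Fz, Cz, Pz.
#' @export
standard_1020_layout <- function() {
  sph <- function(incl, azim) {             # degrees: incl from vertex,
    b <- incl * pi / 180; l <- azim * pi / 180  # azim from nasion, +right
    c(sin(b) * sin(l), sin(b) * cos(l), cos(b))
  }
  mid <- function(a, b) { v <- a + b; v / sqrt(sum(v^2)) }
  pos <- list(
    Fp1 = sph(72, -18), Fp2 = sph(72, 18),
    F7 = sph(72, -54), F8 = sph(72, 54),
    T3 = sph(72, -90), T4 = sph(72, 90),
    T5 = sph(72, -126), T6 = sph(72, 126),
    O1 = sph(72, -162), O2 = sph(72, 162),
    Fz = sph(36, 0), Cz = sph(0, 0), Pz = sph(36, 180),
    C3 = sph(36, -90), C4 = sph(36, 90))
  pos$F3 <- mid(pos$Fz, pos$F7); pos$F4 <- mid(pos$Fz, pos$F8)
  pos$P3 <- mid(pos$Pz, pos$T5); pos$P4 <- mid(pos$Pz, pos$T6)
  names_1020 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                  "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                  "Fz", "Cz", "Pz")
  electrode_layout(names_1020, do.call(rbind, pos[names_1020]))
}

#' Synthetic-EEG generator configuration
#'
#' The generator emulates the structure of annotated clinical recordings:
#' 19-channel 10-20 montage, 1/f-shaped background with a 10 Hz posterior
#' rhythm, channels mixed through a baseline distance-based coupling, and
#' (for seizure records) one contiguous seizure interval whose activity and
#' inter-channel coupling depend on the seizure class: CF plants a
#' high-amplitude 3 Hz oscillation on a focal channel subset; GN plants it
#' on all channels with globally strengthened coupling; AB plants a brief
#' spike-and-wave (3 Hz with sharp harmonics) on all channels; CT plants a
#' 10 Hz tonic segment followed by 3 Hz clonic bursting. Fine-grained
#' labels are 1 exactly on the seizure interval.
#'
#' @param fs sampling frequency (Hz). Desk-scale default 64; 200 matches
#'   the clinical protocol.
#' @param record_seconds record duration (s).
#' @param class_probs named probabilities over
#'   `c("none","CF","GN","AB","CT")`, summing to 1.
#' @param seizure_duration length-2 range (s) of the seizure interval
#'   (AB seizures use a third of it, floored at 1 s); must fit inside the
#'   record.
#' @param focal_channels number of channels involved in a CF seizure.
#' @param coupling_strength global common-signal mixing weight planted
#'   during GN seizures, in `[0, 1)`.
#' @param background_amplitude background standard deviation (microvolts).
#' @param snr_db seizure-to-background amplitude ratio in dB (amplitude
#'   ratio `10^(snr_db/20)`).
#' @param seed integer seed; generation is deterministic given the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 64, record_seconds = 12,
                         class_probs = c(none = 0.5, CF = 0.125, GN = 0.125,
                                         AB = 0.125, CT = 0.125),
                         seizure_duration = c(4, 8),
                         focal_channels = 4L, coupling_strength = 0.6,
                         background_amplitude = 20, snr_db = 10,
                         seed = 1L) {
  stopifnot(fs > 0, record_seconds > 0,
            length(seizure_duration) == 2L,
            seizure_duration[1L] <= seizure_duration[2L],
            focal_channels >= 1L, focal_channels <= 19L,
            coupling_strength >= 0, coupling_strength < 1,
            background_amplitude > 0)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1", call. = FALSE)
  if (!setequal(names(class_probs), seizure_classes()))
    stop("class_probs must be named over none/CF/GN/AB/CT", call. = FALSE)
  if (seizure_duration[2L] >= record_seconds)
    stop("seizure_duration must be shorter than the record", call. = FALSE)
  structure(list(fs = fs, record_seconds = record_seconds,
                 class_probs = class_probs[seizure_classes()],
                 seizure_duration = seizure_duration,
                 focal_channels = as.integer(focal_channels),
                 coupling_strength = coupling_strength,
                 background_amplitude = background_amplitude,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f-ish background: AR(1) low-frequency drift plus white noise, unit sd.
pinkish_noise <- function(n) {
  x <- as.vector(stats::filter(stats::rnorm(n), 0.98, method = "recursive"))
  x <- 0.7 * x / stats::sd(x) + 0.3 * stats::rnorm(n)
  x / stats::sd(x)
}

#' Generate one synthetic EEG record
#'
#' Deterministic given `cfg` (the RNG is seeded with `cfg$seed`). See
#' [synth_config()] for the generative model.
#'
#' @param cfg a [synth_config].
#' @param seizure_class force a class; `NULL` samples from
#'   `cfg$class_probs`.
#' @param record_id record identifier.
#' @return A `synth_record` (an [eeg_record] subclass) with ground-truth
#'   metadata: `seizure_interval` (1-based `[start, end]` step indices, or
#'   `NULL`), `involved_channels`, and the planted `coupling` matrices per
#'   regime.
#' @export
generate_record <- function(cfg, seizure_class = NULL, record_id = "synth") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  layout <- standard_1020_layout()
  m <- length(layout$names)
  n <- round(cfg$record_seconds * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs
  if (is.null(seizure_class)) {
    seizure_class <- sample(seizure_classes(), 1L, prob = cfg$class_probs)
  } else {
    seizure_class <- match.arg(seizure_class, seizure_classes())
  }
  amp <- cfg$background_amplitude
  sz_amp <- amp * 10^(cfg$snr_db / 20)
  # background: pink-ish noise + per-channel 10 Hz rhythm
  sig <- vapply(seq_len(m), function(ch) {
    amp * pinkish_noise(n) +
      0.5 * amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
  }, numeric(n))
  # baseline coupling: weak mixing along the distance graph
  g0 <- build_dist_graph(layout, kappa = 0.9)$weights
  diag(g0) <- 0
  w0 <- 0.8 * diag(m) + 0.2 * g0 / pmax(rowSums(g0), 1e-12)
  sig <- sig %*% t(w0)
  fine <- integer(n)
  interval <- NULL
  involved <- integer(0)
  w_seiz <- w0
  if (seizure_class != "none") {
    dur_rng <- cfg$seizure_duration
    if (seizure_class == "AB") dur_rng <- pmax(dur_rng / 3, 1)
    dur <- round(stats::runif(1, dur_rng[1L], dur_rng[2L]) * cfg$fs)
    dur <- min(dur, n - 1L)
    start <- sample.int(n - dur, 1L)
    idx <- start:(start + dur - 1L)
    ts <- tt[idx]
    phase <- stats::runif(1, 0, 2 * pi)
    osc3 <- sin(2 * pi * 3 * ts + phase)
    spikewave <- osc3 + 0.6 * sin(2 * pi * 6 * ts + 2 * phase) +
      0.3 * sin(2 * pi * 9 * ts + 3 * phase)
    involved <- seq_len(m)
    if (seizure_class == "CF") {
      involved <- sort(sample.int(m, cfg$focal_channels))
      sig[idx, involved] <- sig[idx, involved] + sz_amp * osc3
    } else if (seizure_class == "GN") {
      sig[idx, ] <- sig[idx, ] + sz_amp * osc3
      g <- cfg$coupling_strength
      w_seiz <- (1 - g) * diag(m) + g / m
      sig[idx, ] <- sig[idx, ] %*% t(w_seiz)
    } else if (seizure_class == "AB") {
      sig[idx, ] <- sig[idx, ] + sz_amp * spikewave
    } else if (seizure_class == "CT") {
      half <- length(idx) %/% 2L
      tonic <- idx[seq_len(half)]
      clonic <- idx[(half + 1L):length(idx)]
      sig[tonic, ] <- sig[tonic, ] +
        sz_amp * sin(2 * pi * 10 * tt[tonic] + phase)
      burst <- as.numeric(sin(2 * pi * 1.5 * tt[clonic]) > 0)
      sig[clonic, ] <- sig[clonic, ] +
        sz_amp * burst * sin(2 * pi * 3 * tt[clonic] + phase)
    }
    fine[idx] <- 1L
    interval <- c(start, start + dur)      # half-open [start, end)
  }
  rec <- eeg_record(sig, cfg$fs, layout$names, fine, seizure_class,
                    record_id)
  rec$seizure_interval <- interval
  rec$involved_channels <- involved
  rec$coupling <- list(baseline = w0, seizure = w_seiz)
  class(rec) <- c("synth_record", class(rec))
  rec
}

#' Generate a record-level split synthetic dataset of clips
#'
#' Classes are allocated deterministically in proportion to
#' `cfg$class_probs` (largest-remainder rounding) and shuffled across
#' records; each record gets its own derived seed. Records are split at
#' record level — first a disjoint test set, then the remaining pool is
#' split `split_ratio : (1 - split_ratio)` into train and validation — and
#' sliced into clips with [slice_clips()]; no record contributes to two
#' splits.
#'
#' @param cfg a [synth_config].
#' @param n_records total number of records (>= 10).
#' @param split_ratio train share of the train+validation pool
#'   (default 0.9).
#' @param test_fraction share of records held out as the test set.
#' @param clip_seconds clip length passed to [slice_clips()]; defaults to
#'   the record length (one clip per record).
#' @return List with clip lists `train`, `val`, `test`, the per-split
#'   record ids (`train_ids`, `val_ids`, `test_ids`), and `records` (all
#'   generated `synth_record`s, named by id).
#' @export
generate_dataset <- function(cfg, n_records, split_ratio = 0.9,
                             test_fraction = 0.2,
                             clip_seconds = cfg$record_seconds) {
  stopifnot(inherits(cfg, "synth_config"), n_records >= 10L,
            split_ratio > 0, split_ratio <= 1, test_fraction >= 0,
            test_fraction < 1)
  counts <- floor(cfg$class_probs * n_records)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    frac <- cfg$class_probs * n_records - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  classes <- rep(names(counts), counts)
  set.seed(cfg$seed)
  classes <- sample(classes)
  records <- lapply(seq_len(n_records), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + 7919L * i      # independent per-record streams
    generate_record(ci, seizure_class = classes[i],
                    record_id = sprintf("synth-%04d", i))
  })
  names(records) <- vapply(records, `[[`, "", "record_id")
  set.seed(cfg$seed + 1L)
  ids <- names(records)
  n_test <- round(test_fraction * n_records)
  test_ids <- if (n_test > 0) sample(ids, n_test) else character(0)
  pool <- setdiff(ids, test_ids)
  n_val <- max(1L, round((1 - split_ratio) * length(pool)))
  val_ids <- sample(pool, n_val)
  train_ids <- setdiff(pool, val_ids)
  clips_of <- function(sel)
    unlist(lapply(records[sel], slice_clips, clip_seconds = clip_seconds),
           recursive = FALSE, use.names = FALSE)
  list(train = clips_of(train_ids), val = clips_of(val_ids),
       test = clips_of(test_ids), train_ids = train_ids,
       val_ids = val_ids, test_ids = test_ids, records = records)
}
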