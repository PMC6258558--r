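# Plain-text file formats: every file is a delimited table with '#'-prefixed
# metadata lines. The data are small; diffable text beats binary here.

write_meta <- function(con, meta) {
  for (k in names(meta)) {
    cat(sprintf("# %s=%s\n", k, format(meta[[k]], digits = 15)), file = con)
  }
}

read_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^=]+)=(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
}

#' Write and read stimulus-sequence files
#'
#' One event per row with columns `onset_s`, `duration_s`, `kind`,
#' `truncated`; plume parameters, seed and whiff cap are carried in
#' `#`-prefixed metadata lines. Times are quantized to 1 ms on writing (the
#' valve resolution); onsets are rebuilt cumulatively from the rounded
#' durations so events remain contiguous.
#'
#' @param sequence A [generate_sequence()] result.
#' @param path File path.
#' @return `write_sequence()` returns `path` invisibly; `read_sequence()`
#'   returns a `stimulus_sequence`.
#' @export
write_sequence <- function(sequence, path) {
  ev <- sequence$events
  dur <- round(ev$duration, 3)
  onset <- round(cumsum(c(0, dur[-length(dur)])), 3)
  con <- file(path, "w")
  on.exit(close(con))
  p <- sequence$params
  write_meta(con, list(
    format = "stimulus_sequence", d = p$d, U = p$U, dU = p$dU, a = p$a,
    chi = p$chi, tau = sequence$bounds$tau,
    total_duration = sequence$total_duration, seed = sequence$seed,
    whiff_cap = sequence$whiff_cap))
  cat("onset_s\tduration_s\tkind\ttruncated\n", file = con)
  cat(sprintf("%.6f\t%.6f\t%s\t%d", onset, dur, ev$kind,
              as.integer(ev$truncated)),
      sep = "\n", file = con)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  meta <- read_meta(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  params <- plume_params(d = meta_num(meta, "d"), U = meta_num(meta, "U"),
                         dU = meta_num(meta, "dU"), a = meta_num(meta, "a"),
                         chi = meta_num(meta, "chi"))
  bounds <- derive_timescales(params, tau = meta_num(meta, "tau"))
  structure(list(
    events = data.frame(onset = tab$onset_s, duration = tab$duration_s,
                        kind = tab$kind,
                        truncated = as.logical(tab$truncated),
                        stringsAsFactors = FALSE),
    total_duration = meta_num(meta, "total_duration"),
    params = params, bounds = bounds,
    seed = as.integer(meta_num(meta, "seed")),
    whiff_cap = meta_num(meta, "whiff_cap", Inf)
  ), class = "stimulus_sequence")
}

#' Write and read spike-train recording files
#'
#' One spike time (s) per row at microsecond precision, with neuron id,
#' distance, dose, seed and the paired stimulus-sequence file in metadata
#' lines — one file per neuron, as in single-sensillum recordings. The
#' reader tolerates spike-only files by requiring the paired stimulus file
#' (given explicitly or via the `sequence_file` metadata entry, resolved
#' relative to the recording's directory).
#'
#' @param recording A `spike_train_recording`.
#' @param path Recording file path.
#' @param sequence_path Where the paired stimulus sequence is (or should be)
#'   stored. Default: same name with suffix `_seq.tsv`. Set `NULL` to skip
#'   writing the sequence file.
#' @param sequence For `read_recording()`: an already-loaded
#'   `stimulus_sequence` overriding the metadata pairing.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `spike_train_recording`.
#' @export
write_recording <- function(recording, path,
                            sequence_path = sub("\\.tsv$", "", path)) {
  if (!is.null(sequence_path)) {
    if (identical(sequence_path, sub("\\.tsv$", "", path))) {
      sequence_path <- paste0(sequence_path, "_seq.tsv")
    }
    write_sequence(recording$sequence, sequence_path)
    seq_ref <- basename(sequence_path)
  } else {
    seq_ref <- ""
  }
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(
    format = "spike_train_recording", neuron_id = recording$neuron_id,
    distance_m = recording$distance, dose_ng = recording$dose,
    seed = recording$seed, sequence_file = seq_ref))
  cat("spike_time_s\n", file = con)
  if (length(recording$spikes)) {
    cat(sprintf("%.6f", recording$spikes), sep = "\n", file = con)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, sequence = NULL) {
  lines <- readLines(path)
  meta <- read_meta(lines)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  header_at <- body_idx[1L]
  if (is.na(header_at) || lines[header_at] != "spike_time_s") {
    stop("not a recording file (missing 'spike_time_s' header): ", path,
         call. = FALSE)
  }
  data_idx <- body_idx[-1L]
  spikes <- numeric(length(data_idx))
  for (i in seq_along(data_idx)) {
    val <- suppressWarnings(as.numeric(lines[data_idx[i]]))
    if (is.na(val)) {
      stop(sprintf("malformed spike time at line %d of %s", data_idx[i], path),
           call. = FALSE)
    }
    if (val < 0) {
      stop(sprintf("negative spike time at line %d of %s", data_idx[i], path),
           call. = FALSE)
    }
    spikes[i] <- val
  }
  if (is.null(sequence)) {
    seq_file <- meta[["sequence_file"]]
    if (is.null(seq_file) || !nzchar(seq_file)) {
      stop("recording file names no paired stimulus sequence; pass 'sequence'",
           call. = FALSE)
    }
    seq_path <- file.path(dirname(path), seq_file)
    if (!file.exists(seq_path)) {
      stop("paired stimulus-sequence file not found: ", seq_path,
           call. = FALSE)
    }
    sequence <- read_sequence(seq_path)
  }
  structure(list(spikes = sort(spikes), sequence = sequence,
                 distance = meta_num(meta, "distance_m"),
                 dose = meta_num(meta, "dose_ng"),
                 neuron_id = if (is.null(meta$neuron_id)) "orn" else meta$neuron_id,
                 seed = as.integer(meta_num(meta, "seed"))),
            class = "spike_train_recording")
}

#' Experimental-condition key
#'
#' Validates a (distance, dose) pair against the study design: distances 8,
#' 16, 32, 64, 128 m and decadic doses from 1e-6 to 1 ng. The combination of
#' 128 m with the 1 ng dose is rejected: at that distance extremely long
#' whiffs at the highest dose silence the neuron, so the condition is not
#' part of the design.
#'
#' @param distance_m Virtual distance (m).
#' @param dose_ng Pheromone dose (ng).
#' @return An object of class `group_key`.
#' @export
group_key <- function(distance_m, dose_ng) {
  if (!distance_m %in% c(8, 16, 32, 64, 128)) {
    stop("'distance_m' must be one of 8, 16, 32, 64, 128", call. = FALSE)
  }
  if (!any(abs(dose_ng - 10^(-6:0)) < 1e-12 * max(dose_ng, 1e-12))) {
    stop("'dose_ng' must be a decadic dose between 1e-6 and 1 ng",
         call. = FALSE)
  }
  if (distance_m == 128 && dose_ng == 1) {
    stop("the 128 m / 1 ng condition is excluded from the design",
         call. = FALSE)
  }
  structure(list(distance_m = distance_m, dose_ng = dose_ng),
            class = "group_key")
}

#' Pipeline run configuration
#'
#' Collects every parameter of a full synthetic-pipeline run. All stochastic
#' stages derive their seeds from the single `seed`, making reruns
#' byte-identical. `write_config()`/`read_config()` round-trip the
#' configuration through a key-value text file.
#'
#' @param distances Virtual distances (m).
#' @param doses Dose labels (ng).
#' @param n_neurons Recordings per (distance, dose) group.
#' @param duration_s Recording length (s).
#' @param seed Master seed (integer).
#' @param window Response-window length (s).
#' @param analysis_start,analysis_end Analysis interval (s).
#' @param target_trace Spline smoother-trace target.
#' @param segment_size Responses per variance segment.
#' @param span_fraction Tricube kernel span.
#' @param grid_n Evaluation-grid size.
#' @param mu_min,c_scale,r0,theta Encoder parameters (Jeffreys-matched
#'   family; the dose label scales `c_scale`, see [dose_gain()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(distances = c(8, 16, 32, 64, 128), doses = 1e-2,
                       n_neurons = 5, duration_s = 500, seed = 1L,
                       window = 0.150, analysis_start = 100,
                       analysis_end = 500, target_trace = 3,
                       segment_size = 10L, span_fraction = 0.9,
                       grid_n = 201L, mu_min = 1, c_scale = 4, r0 = 5,
                       theta = 0.026) {
  cfg <- structure(as.list(environment()), class = "run_config")
  for (d in cfg$distances) for (dn in cfg$doses) group_key(d, dn)
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Key-value text file path.
#' @export
write_config <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config)) {
    cat(sprintf("%s=%s\n", k,
                paste(format(config[[k]], digits = 15), collapse = ",")),
        file = con)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    as.numeric(strsplit(x[2], ",", fixed = TRUE)[[1]])
  })
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  do.call(run_config, vals)
}

config_hash <- function(config) {
  fnv1a(paste(names(config),
              vapply(config, function(x) paste(format(x, digits = 15),
                                               collapse = ","),
                     character(1)),
              sep = "=", collapse = ";"))
}

#' Dose-dependent encoder gain
#'
#' Synthetic recordings represent the pheromone dose only as a label that
#' scales the Fisher-information scale of the encoder: the gain rises
#' linearly in log10 dose from 0.6 at 1e-6 ng to 1 at 1 ng, a coarse stand-in
#' for the weaker modulation at lower doses.
#'
#' @param dose_ng Dose label (ng).
#' @return A multiplier in `[0.6, 1]`.
#' @export
dose_gain <- function(dose_ng) 0.6 + 0.4 * (log10(dose_ng) + 6) / 6
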