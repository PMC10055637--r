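# Reading and writing EEG recordings and subject tables.  The canonical
# fixture format is a plain TSV matrix (channels as rows) with a JSON
# sidecar carrying id, labels and sampling rate; BrainVision and EDF
# readers cover the acquisition formats the field actually uses.

#' EEG recording container
#'
#' @param subject_id Subject identifier.
#' @param channel_labels Character vector of channel names, one per row of
#'   `samples`; matched case-sensitively everywhere.
#' @param sample_rate Sampling rate in Hz, > 0.
#' @param samples Numeric matrix, channels x time, all finite.
#' @return An object of class `eeg_recording`; `duration` (seconds) is
#'   derived.
#' @export
eeg_recording <- function(subject_id, channel_labels, sample_rate, samples) {
  if (!is.matrix(samples)) stop_leapd("samples must be a matrix")
  check_finite_numeric(samples, "samples")
  if (nrow(samples) != length(channel_labels)) {
    stop_leapd("samples has %d rows but %d channel labels given",
               nrow(samples), length(channel_labels))
  }
  if (anyDuplicated(channel_labels)) stop_leapd("duplicate channel labels")
  check_scalar(sample_rate, "sample_rate", lo = 1e-9)
  structure(
    list(subject_id = as.character(subject_id),
         channel_labels = as.character(channel_labels),
         sample_rate = sample_rate,
         samples = samples,
         duration = ncol(samples) / sample_rate),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<EEG recording %s: %d channels, %.1f s @ %g Hz>\n",
              x$subject_id, length(x$channel_labels), x$duration,
              x$sample_rate))
  invisible(x)
}

#' Extract one channel from a recording
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label (exact, case-sensitive match).
#' @return Numeric vector of samples.
#' @export
get_channel <- function(rec, channel) {
  i <- match(channel, rec$channel_labels)
  if (is.na(i)) stop_leapd("channel '%s' not present in recording '%s'",
                           channel, rec$subject_id)
  rec$samples[i, ]
}

#' Write a recording as a TSV matrix with JSON sidecar
#'
#' Channels as rows, tab-separated, full double precision (`%.17g`); the
#' sidecar `<path>.json` carries subject id, labels and sampling rate.
#'
#' @param rec An [eeg_recording()].
#' @param path Destination for the matrix file (e.g. `"S001.tsv"`).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stop_leapd("rec must be an eeg_recording")
  if (nrow(rec$samples) == 0L) stop_leapd("recording has no channels")
  check_finite_numeric(rec$samples, "samples")
  lines <- apply(rec$samples, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(lines, path)
  meta <- list(subject_id = rec$subject_id,
               channel_labels = rec$channel_labels,
               sample_rate = rec$sample_rate)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_matrix_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_leapd("matrix recording '%s' is missing its sidecar metadata '%s'",
               path, sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("channel_labels", "sample_rate")) {
    if (is.null(meta[[field]])) {
      stop_leapd("sidecar '%s' is missing required field '%s'", sidecar, field)
    }
  }
  rows <- readLines(path)
  samples <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE),
                                   as.numeric))
  if (any(!is.finite(samples))) {
    stop_leapd("non-finite sample values in '%s'", path)
  }
  eeg_recording(subject_id = meta$subject_id %||% basename(path),
                channel_labels = meta$channel_labels,
                sample_rate = meta$sample_rate,
                samples = samples)
}

# BrainVision: INI-style .vhdr naming a binary multiplexed data file.
read_brainvision_recording <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  get_kv <- function(key) {
    line <- grep(sprintf("^%s=", key), hdr, value = TRUE)
    if (length(line) == 0L) stop_leapd("BrainVision header lacks '%s'", key)
    sub(sprintf("^%s=", key), "", line[1L])
  }
  data_file <- file.path(dirname(path), get_kv("DataFile"))
  n_ch <- as.integer(get_kv("NumberOfChannels"))
  samp_int_us <- as.numeric(get_kv("SamplingInterval"))
  fmt <- get_kv("BinaryFormat")
  orient <- toupper(get_kv("DataOrientation"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE)
  labels <- vapply(parts, `[`, character(1), 1L)
  resol <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(r) || r == 0) 1 else r
  }, numeric(1))
  if (length(labels) != n_ch) {
    stop_leapd("BrainVision header: %d channel entries, NumberOfChannels=%d",
               length(labels), n_ch)
  }
  sz <- file.size(data_file)
  if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(data_file, "numeric", n = sz / 4, size = 4,
                        endian = "little")
  } else if (fmt == "INT_16") {
    raw_vals <- readBin(data_file, "integer", n = sz / 2, size = 2,
                        signed = TRUE, endian = "little")
  } else {
    stop_leapd("unsupported BrainVision BinaryFormat '%s'", fmt)
  }
  n_samp <- length(raw_vals) %/% n_ch
  raw_vals <- raw_vals[seq_len(n_samp * n_ch)]
  samples <- if (orient == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_ch)            # channel-fastest
  } else {
    t(matrix(raw_vals, ncol = n_ch))         # VECTORIZED: sample-fastest
  }
  samples <- samples * resol
  eeg_recording(subject_id = sub("\\.vhdr$", "", basename(path)),
                channel_labels = labels,
                sample_rate = 1e6 / samp_int_us,
                samples = samples)
}

# EDF: 256-byte fixed header + 256 bytes per signal, 16-bit little-endian
# data records scaled from digital to physical range.
read_edf_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fread <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  fread(8)                         # version
  fread(80); fread(80)             # patient / recording id
  fread(8); fread(8)               # start date / time
  as.integer(fread(8))             # header bytes
  fread(44)                        # reserved
  n_rec <- as.integer(fread(8))
  rec_dur <- as.numeric(fread(8))
  ns <- as.integer(fread(4))
  field <- function(nc) vapply(seq_len(ns), function(i) fread(nc), character(1))
  labels <- field(16)
  field(80); field(8)              # transducer, dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8));  dig_max <- as.numeric(field(8))
  field(80)                        # prefiltering
  n_per_rec <- as.integer(field(8))
  field(32)                        # reserved
  if (length(unique(n_per_rec)) != 1L) {
    stop_leapd("EDF with heterogeneous per-signal rates is not supported")
  }
  npr <- n_per_rec[1L]
  samples <- matrix(0, nrow = ns, ncol = n_rec * npr)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * npr, size = 2, signed = TRUE,
                     endian = "little")
    cols <- ((r - 1L) * npr + 1L):(r * npr)
    for (s in seq_len(ns)) {
      vals <- block[((s - 1L) * npr + 1L):(s * npr)]
      samples[s, cols] <- phys_min[s] + gain[s] * (vals - dig_min[s])
    }
  }
  eeg_recording(subject_id = sub("\\.edf$", "", basename(path),
                                 ignore.case = TRUE),
                channel_labels = labels,
                sample_rate = npr / rec_dur,
                samples = samples)
}

#' Read an EEG recording
#'
#' @param path Path to the recording: the `.tsv` matrix file, the
#'   BrainVision `.vhdr` header, or an `.edf` file.
#' @param format One of `"matrix"`, `"brainvision"`, `"edf"`; guessed from
#'   the file extension when omitted.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("guess", "matrix", "brainvision",
                                      "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_leapd("file '%s' does not exist", path)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision",
                     edf = "edf",
                     "matrix")
  }
  switch(format,
         matrix = read_matrix_recording(path),
         brainvision = read_brainvision_recording(path),
         edf = read_edf_recording(path))
}

#' Load a subject table
#'
#' CSV with header `id,group,age,<score...>`; every column after `age` is
#' treated as a cognitive score. Age is required for every subject because
#' the evaluation statistics control for it; a MoCA column (named `moca`,
#' any case) must be integer-valued in [0, 30].
#'
#' @param path CSV file path.
#' @return data.frame with columns `id`, `group`, `age` and the score
#'   columns, one row per subject.
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) stop_leapd("file '%s' does not exist", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "group", "age")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop_leapd("subject table lacks required column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  score_cols <- setdiff(names(tab), needed)
  if (length(score_cols) == 0L) {
    stop_leapd("subject table has no score columns")
  }
  tab$id <- as.character(tab$id)
  dups <- tab$id[duplicated(tab$id)]
  if (length(dups) > 0L) {
    stop_leapd("duplicate subject id(s): %s",
               paste(unique(dups), collapse = ", "))
  }
  if (any(is.na(tab$age)) || !is.numeric(tab$age) || any(tab$age <= 0)) {
    stop_leapd("every subject needs a positive numeric age (required for age-controlled statistics)")
  }
  moca_col <- score_cols[tolower(score_cols) == "moca"]
  for (mc in moca_col) {
    v <- tab[[mc]][!is.na(tab[[mc]])]
    if (any(v < 0 | v > 30 | v != round(v))) {
      stop_leapd("MoCA scores must be integers in [0, 30]")
    }
  }
  tab
}

#' Analysis dataset: subject table plus recordings
#'
#' @param subjects data.frame with columns `id`, `group`, `age` and score
#'   columns.
#' @param recordings Named list of [eeg_recording()], names matching
#'   subject ids.
#' @return An object of class `leapd_dataset`.
#' @export
leapd_dataset <- function(subjects, recordings) {
  if (anyDuplicated(subjects$id)) stop_leapd("duplicate subject ids")
  structure(list(subjects = subjects, recordings = recordings),
            class = "leapd_dataset")
}

#' @export
print.leapd_dataset <- function(x, ...) {
  cat(sprintf("<dataset: %d subjects, %d recordings>\n",
              nrow(x$subjects), length(x$recordings)))
  invisible(x)
}

#' Validate dataset integrity
#'
#' Checks that every subject has a recording, ids are unique, and all
#' recordings share sampling rate and channel labels. Violations are
#' reported, not thrown.
#'
#' @param ds A [leapd_dataset()].
#' @return Character vector of violation messages; empty when the dataset
#'   is consistent.
#' @export
validate_dataset <- function(ds) {
  report <- character(0)
  ids <- ds$subjects$id
  dups <- unique(ids[duplicated(ids)])
  if (length(dups) > 0L) {
    report <- c(report, sprintf("duplicate subject id: %s", dups))
  }
  missing_rec <- setdiff(ids, names(ds$recordings))
  if (length(missing_rec) > 0L) {
    report <- c(report, sprintf("subject %s has no recording", missing_rec))
  }
  present <- intersect(ids, names(ds$recordings))
  if (length(present) > 1L) {
    ref <- ds$recordings[[present[1L]]]
    for (id in present[-1L]) {
      rec <- ds$recordings[[id]]
      if (!isTRUE(all.equal(rec$sample_rate, ref$sample_rate))) {
        report <- c(report, sprintf(
          "recording %s sample rate %g differs from %s (%g)",
          id, rec$sample_rate, present[1L], ref$sample_rate))
      }
      if (!identical(rec$channel_labels, ref$channel_labels)) {
        report <- c(report, sprintf(
          "recording %s channel labels differ from %s", id, present[1L]))
      }
    }
  }
  report
}

#' Write a cohort to disk in the matrix fixture format
#'
#' One TSV + JSON sidecar per recording plus `subjects.csv`.
#'
#' @param cohort A `synthetic_cohort` or `leapd_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    write_matrix(cohort$recordings[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `subjects.csv` and one `<id>.tsv` (+
#'   sidecar) per subject.
#' @return A [leapd_dataset()].
#' @export
read_cohort <- function(dir) {
  subjects <- load_subject_table(file.path(dir, "subjects.csv"))
  recordings <- lapply(subjects$id, function(id) {
    read_eeg(file.path(dir, paste0(id, ".tsv")), format = "matrix")
  })
  names(recordings) <- subjects$id
  leapd_dataset(subjects, recordings)
}
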