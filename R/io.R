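#' Write a recording to disk
#'
#' Two formats are supported. `"delimited"` writes one CSV per modality
#' (`<stem>_eeg.csv`, `<stem>_emg.csv`), each with a `# fs: <Hz>` comment
#' header and one column per channel. `"edf"` writes a single EDF file
#' (`<stem>.edf`, 16-bit; EDF natively supports per-signal sampling rates, so
#' EEG and EMG live in one file) with channel labels prefixed by their
#' modality (`EEG Cz`, `EMG ExO`).
#'
#' @param rec A [recording()].
#' @param stem Path stem (without extension).
#' @param format `"delimited"` or `"edf"`.
#' @return The written file path(s), invisibly.
#' @export
write_recording <- function(rec, stem, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "cmc_recording"))
  if (format == "delimited") {
    paths <- c(eeg = paste0(stem, "_eeg.csv"), emg = paste0(stem, "_emg.csv"))
    write_one <- function(m, fs, path) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("# fs: %g", fs), con)
      utils::write.csv(as.data.frame(m), con, row.names = FALSE)
    }
    write_one(rec$eeg, rec$fs_eeg, paths["eeg"])
    write_one(rec$emg, rec$fs_emg, paths["emg"])
    invisible(paths)
  } else {
    path <- paste0(stem, ".edf")
    write_edf(rec, path)
    invisible(path)
  }
}

#' Read a recording from disk
#'
#' @param path For `format = "delimited"`, the path stem used by
#'   [write_recording()]; for `format = "edf"`, the `.edf` file.
#' @param format `"delimited"` or `"edf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "delimited") {
    read_delimited_recording(path)
  } else {
    read_edf(path)
  }
}

read_delimited_block <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "cmcwave_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    abort(sprintf("file %s is empty or truncated", path), class = "cmcwave_io_error")
  }
  m_fs <- regmatches(lines[1], regexec("^# fs: *([0-9.]+)", lines[1]))[[1]]
  if (length(m_fs) < 2L) {
    abort(sprintf("file %s: missing '# fs:' header", path), class = "cmcwave_io_error")
  }
  fs <- as.numeric(m_fs[2])
  header <- strsplit(lines[2], ",")[[1]]
  header <- gsub('^"|"$', "", header)
  if (!length(header) || any(header == "")) {
    abort(sprintf("file %s: missing channel labels", path), class = "cmcwave_io_error")
  }
  body <- lines[-(1:2)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(header))
  if (length(bad)) {
    abort(sprintf("file %s: malformed row %d (expected %d fields, got %d)",
                  path, bad[1] + 2L, length(header), nf[bad[1]]),
          class = "cmcwave_io_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = length(header), byrow = TRUE)
  if (anyNA(m)) {
    bad_row <- which(apply(m, 1, anyNA))[1]
    abort(sprintf("file %s: non-numeric value in row %d", path, bad_row + 2L),
          class = "cmcwave_io_error")
  }
  colnames(m) <- header
  list(samples = m, fs = fs)
}

read_delimited_recording <- function(stem) {
  eeg <- read_delimited_block(paste0(stem, "_eeg.csv"))
  emg <- read_delimited_block(paste0(stem, "_emg.csv"))
  recording(eeg = eeg$samples, emg = emg$samples,
            fs_eeg = eeg$fs, fs_emg = emg$fs)
}

# ---- minimal EDF (16-bit, one data record per second) ---------------------

pad_ascii <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1, width)
  formatC(s, width = -width)
}

write_edf <- function(rec, path) {
  dur <- recording_duration(rec)
  if (abs(dur - round(dur)) > 1e-9) {
    abort("EDF export requires a whole number of seconds", class = "cmcwave_io_error")
  }
  n_rec <- as.integer(round(dur))
  labels <- c(paste("EEG", colnames(rec$eeg)), paste("EMG", colnames(rec$emg)))
  spr <- c(rep(rec$fs_eeg, ncol(rec$eeg)), rep(rec$fs_emg, ncol(rec$emg)))
  ns <- length(labels)
  # physical range per signal, symmetric, non-degenerate
  sig <- c(lapply(seq_len(ncol(rec$eeg)), function(j) rec$eeg[, j]),
           lapply(seq_len(ncol(rec$emg)), function(j) rec$emg[, j]))
  pmaxs <- vapply(sig, function(v) max(abs(v), 1e-6), numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("synthetic", 80), pad_ascii("cmcwave", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 + ns * 256, 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) writeChar(paste0(pad_ascii(vals, width), collapse = ""), con, eos = NULL)
  field(labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(sprintf("%.6g", -pmaxs), 8)            # physical min
  field(sprintf("%.6g", pmaxs), 8)             # physical max
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(spr, 8)
  field(rep("", ns), 32)

  bv <- 2 * pmaxs / (32767 - (-32768))   # physical units per digital step
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      idx <- seq.int((r - 1L) * spr[s] + 1L, r * spr[s])
      dig <- as.integer(round((sig[[s]][idx] + pmaxs[s]) / bv[s])) - 32768L
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "cmcwave_io_error")
  }
  if (file.info(path)$size < 256) {
    abort(sprintf("file %s is not a valid EDF (truncated header)", path),
          class = "cmcwave_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(n_rec, ns, spr)) || is.null(labels) || any(labels == "")) {
    abort(sprintf("file %s: malformed EDF header", path), class = "cmcwave_io_error")
  }
  sig <- lapply(spr, function(k) numeric(k * n_rec))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[s]) {
        abort(sprintf("file %s: truncated data record %d", path, r),
              class = "cmcwave_io_error")
      }
      phys <- (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s]) + pmin_[s]
      sig[[s]][seq.int((r - 1L) * spr[s] + 1L, r * spr[s])] <- phys
    }
  }
  role <- sub(" .*$", "", labels)
  name <- sub("^[A-Z]+ +", "", labels)
  build <- function(which) {
    i <- which(role == which)
    if (!length(i)) {
      abort(sprintf("file %s: no %s signals found", path, which), class = "cmcwave_io_error")
    }
    if (length(unique(spr[i])) != 1) {
      abort(sprintf("file %s: inconsistent %s sampling rates", path, which),
            class = "cmcwave_io_error")
    }
    m <- do.call(cbind, sig[i])
    colnames(m) <- name[i]
    list(m = m, fs = spr[i[1]] / rec_dur)
  }
  eeg <- build("EEG"); emg <- build("EMG")
  recording(eeg = eeg$m, emg = emg$m, fs_eeg = eeg$fs, fs_emg = emg$fs)
}
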