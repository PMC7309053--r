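#' Read a WFDB-format record
#'
#' Parses a WFDB header (`.hea`) plus signal (`.dat`) pair — the format the
#' PhysioNet MIT-BIH databases are distributed in — and returns one channel
#' in physical units, `(digital - baseline) / gain`. Supported signal
#' dialects: format 212 (two 12-bit samples packed into 3 bytes, the MIT-BIH
#' packing) and format 16 (little-endian 16-bit integers). All signals must
#' live in a single interleaved `.dat` file, which is how both target
#' databases are packed.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param channel 0-based channel index.
#' @return An [ecg_record()]; `subject_id` is the record name.
#' @export
read_wfdb_record <- function(path, channel = 0L) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path))
    stop(sprintf("read_wfdb_record: header not found: %s", hea_path))
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L)
    stop(sprintf("read_wfdb_record: malformed header: %s", hea_path))

  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*$", "", hdr[1])
  nsig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3L) as.numeric(sub("/.*$", "", hdr[3])) else 250
  nsamp <- if (length(hdr) >= 4L) as.numeric(hdr[4]) else NA
  if (is.na(nsig) || nsig < 1L)
    stop(sprintf("read_wfdb_record: bad signal count in %s", hea_path))
  if (channel < 0L || channel >= nsig)
    stop(sprintf("read_wfdb_record: channel %d out of range (record has %d)",
                 channel, nsig))

  sig <- lapply(lines[2:(1L + nsig)], parse_wfdb_signal_line)
  dat_files <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(dat_files) != 1L)
    stop("read_wfdb_record: multi-file signal layouts are not supported")
  fmts <- unique(vapply(sig, `[[`, numeric(1), "format"))
  if (length(fmts) != 1L || !fmts %in% c(212, 16))
    stop(sprintf("read_wfdb_record: unsupported signal format (%s); only 212 and 16",
                 paste(fmts, collapse = ",")))

  dat_path <- file.path(dirname(hea_path), dat_files)
  if (!file.exists(dat_path))
    stop(sprintf("read_wfdb_record: signal file not found: %s", dat_path))
  raw_bytes <- readBin(dat_path, "raw", n = file.size(dat_path))
  digital <- if (fmts == 212) decode_fmt212(raw_bytes) else
    readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L, size = 2L,
            signed = TRUE, endian = "little")

  n_frames <- length(digital) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) n_frames <- min(n_frames, nsamp)
  ch <- sig[[channel + 1L]]
  d <- digital[seq.int(channel + 1L, by = nsig, length.out = n_frames)]
  ecg_record((d - ch$baseline) / ch$gain, fs, record_name, channel)
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 2L) stop("read_wfdb_record: malformed signal line")
  fmt <- as.numeric(sub("x.*$", "", tok[2]))  # strip samples-per-frame
  gain <- 200; baseline <- NA
  if (length(tok) >= 3L) {
    m <- regmatches(tok[3],
                    regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?(/.*)?$", tok[3]))[[1]]
    if (length(m)) {
      gain <- as.numeric(m[2])
      if (nzchar(m[4])) baseline <- as.numeric(m[4])
    }
  }
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB convention: 0 means default
  adczero <- if (length(tok) >= 5L) as.numeric(tok[5]) else 0
  if (is.na(baseline)) baseline <- adczero
  list(file = tok[1], format = fmt, gain = gain, baseline = baseline)
}

# format 212: 3 bytes hold two 12-bit two's-complement samples
decode_fmt212 <- function(raw_bytes) {
  n3 <- (length(raw_bytes) %/% 3L) * 3L
  b <- as.integer(raw_bytes[seq_len(n3)])
  b1 <- b[seq(1L, n3, by = 3L)]
  b2 <- b[seq(2L, n3, by = 3L)]
  b3 <- b[seq(3L, n3, by = 3L)]
  s1 <- b1 + bitwAnd(b2, 15L) * 256L
  s2 <- b3 + bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L
  out <- numeric(2L * length(s1))
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  ifelse(out > 2047, out - 4096, out)
}

#' Write a record as a WFDB header/signal pair
#'
#' Writes a single-channel record in the plain 16-bit WFDB dialect
#' (format 16), quantizing with the given gain so a round trip through
#' [read_wfdb_record()] reproduces the samples within one quantization step
#' (`1/gain`).
#'
#' @param record An [ecg_record()].
#' @param path Output path without extension; `.hea` and `.dat` are created.
#' @param gain Analog-to-digital units per physical unit (default 200).
#' @param units Unit label written to the header.
#' @return Invisibly, the header path.
#' @export
write_wfdb_record <- function(record, path, gain = 200, units = "mV") {
  stopifnot_record(record)
  d <- as.integer(round(record$samples * gain))
  if (any(abs(d) > 32767L))
    stop("write_wfdb_record: samples exceed the 16-bit range at this gain")
  name <- basename(path)
  cksum <- sum(d) %% 65536L
  if (cksum > 32767L) cksum <- cksum - 65536L
  hea <- c(sprintf("%s 1 %g %d", name, record$sampling_rate_hz, length(d)),
           sprintf("%s.dat 16 %g(0)/%s 16 0 %d %d 0 ECG", name, gain, units,
                   d[1], cksum))
  writeLines(hea, paste0(path, ".hea"))
  writeBin(d, paste0(path, ".dat"), size = 2L, endian = "little")
  invisible(paste0(path, ".hea"))
}
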