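#' Read an ECG record
#'
#' Dispatches on format: the package CSV dialect (header
#' `time_s,ch1_mv[,ch2_mv]`, decimal point, comma separator, UTF-8) or a
#' minimal WFDB record (format-16 single .dat).
#'
#' @param path file path (for WFDB, the `.hea` path or the record base name).
#' @param format `"csv"` or `"wfdb"`.
#' @return an [ecg_record].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_ecg_csv(path) else read_wfdb(path)
}

#' Write an ECG record
#'
#' @param record an [ecg_record].
#' @param path output path (for WFDB, the record base name; `.hea` and
#'   `.dat` are created).
#' @param format `"csv"` or `"wfdb"`.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") write_ecg_csv(record, path) else write_wfdb(record, path)
}

read_ecg_csv <- function(path) {
  if (!file.exists(path)) ecgph_stop(paste("no such file:", path), "ecgph_io_error")
  df <- read.csv(path, check.names = FALSE)
  nm <- names(df)
  if (nm[1] != "time_s")
    ecgph_stop(sprintf("malformed ECG CSV header: expected first column 'time_s', found '%s'", nm[1]),
               "ecgph_parse_error")
  chan <- grep("^ch[0-9]+_mv$", nm, value = TRUE)
  if (!length(chan))
    ecgph_stop("malformed ECG CSV header: no 'chN_mv' channel columns found",
               "ecgph_parse_error")
  bad <- setdiff(nm, c("time_s", chan))
  if (length(bad))
    ecgph_stop(sprintf("malformed ECG CSV header: unexpected column '%s'", bad[1]),
               "ecgph_parse_error")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) ecgph_stop("time_s must be strictly increasing", "ecgph_parse_error")
  fs <- 1 / median(dt)
  samples <- as.matrix(df[chan])
  colnames(samples) <- sub("_mv$", "", chan)
  ecg_record(samples, fs = fs, start = df$time_s[1],
             id = sub("\\.csv$", "", basename(path)))
}

write_ecg_csv <- function(record, path) {
  n <- nrow(record$samples)
  df <- data.frame(time_s = record$start + (seq_len(n) - 1) / record$fs)
  for (ch in seq_len(ncol(record$samples)))
    df[[sprintf("ch%d_mv", ch)]] <- record$samples[, ch]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a blood-gas event table
#'
#' CSV with header `time_s,ph`. Non-numeric entries are reported with their
#' row number.
#'
#' @param path file path.
#' @return data.frame with numeric columns `time_s`, `ph`.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) ecgph_stop(paste("no such file:", path), "ecgph_io_error")
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df)[1:2], c("time_s", "ph")))
    ecgph_stop(sprintf("malformed events CSV header: expected 'time_s,ph', found '%s'",
                       paste(names(df), collapse = ",")), "ecgph_parse_error")
  for (col in c("time_s", "ph")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      ecgph_stop(sprintf("non-numeric %s '%s' in events CSV at row %d",
                         col, df[[col]][bad[1]], bad[1]), "ecgph_parse_error")
    df[[col]] <- v
  }
  df
}

#' Write events CSV
#' @param events data.frame with `time_s`, `ph`.
#' @param path output file.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events[, c("time_s", "ph")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal WFDB (format 16) support -------------------------------------
# Single-segment records, one .dat in format 16 (interleaved little-endian
# int16), fixed gain per channel. Covers round-tripping this package's
# records and reading similarly simple external records.

WFDB_GAIN <- 1000  # adu per mV

write_wfdb <- function(record, path) {
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  nsig <- ncol(record$samples)
  n <- nrow(record$samples)
  hea <- c(sprintf("%s %d %g %d", name, nsig, record$fs, n),
           sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 %s", name, WFDB_GAIN,
                   colnames(record$samples)))
  writeLines(hea, paste0(base, ".hea"))
  adu <- round(record$samples * WFDB_GAIN)
  adu <- pmax(pmin(adu, 32767), -32768)
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adu)), con, size = 2, endian = "little")
  invisible(base)
}

read_wfdb <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) ecgph_stop(paste("no such file:", hea_path), "ecgph_io_error")
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[2:(1 + nsig)]
  fields <- strsplit(trimws(sig), "\\s+")
  dat_file <- fields[[1]][1]
  fmt <- sub("x.*", "", fields[[1]][2])
  if (fmt != "16")
    ecgph_stop(sprintf("unsupported WFDB format '%s' (only format 16)", fmt),
               "ecgph_parse_error")
  gains <- vapply(fields, function(f) {
    g <- suppressWarnings(as.numeric(sub("\\(.*", "", sub("/.*", "", f[3]))))
    if (!is.finite(g) || g == 0) 200 else g  # WFDB default gain
  }, numeric(1))
  chn <- vapply(fields, function(f) if (length(f) >= 9) f[9] else NA_character_,
                character(1))
  dat_path <- file.path(dirname(hea_path), dat_file)
  raw <- readBin(dat_path, integer(), n = file.size(dat_path) / 2, size = 2,
                 endian = "little")
  if (!is.na(nsamp)) raw <- raw[seq_len(nsamp * nsig)]
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  samples <- sweep(m, 2, gains, "/")
  if (!anyNA(chn)) colnames(samples) <- chn
  ecg_record(samples, fs = fs, start = 0, id = basename(base))
}

#' Write the feature table as TSV
#'
#' One row per accepted segment with the exact column set
#' `segment_id, t_qrs, t_amplitude, tslope, tslope_t, tslope_abs_t,
#' tslope_sqrt_abs_t, hr, qt, qtc, rravg, ph, group`.
#'
#' @param features feature data.frame.
#' @param path output file.
#' @export
write_features <- function(features, path) {
  cols <- c("segment_id", feature_columns(), "ph", "group")
  write.table(features[, cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_features <- function(path) {
  read.csv(path, sep = "\t", stringsAsFactors = FALSE)
}
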