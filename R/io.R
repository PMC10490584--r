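#' Multi-channel physiological record
#'
#' @param signals Named list of [sampled_signal()] channels sharing the same
#'   sampling rate and length (e.g. `ECG`, `RESP`).
#' @param metadata Free-form key/value list.
#' @return An object of class `record`.
#' @export
record <- function(signals, metadata = list()) {
  if (!length(signals) || is.null(names(signals)) ||
      anyDuplicated(names(signals)))
    stop_invalid("'signals' must be a non-empty uniquely named list")
  for (s in signals)
    if (!inherits(s, "sampled_signal"))
      stop_invalid("every channel must be a 'sampled_signal'")
  fs <- vapply(signals, function(s) s$fs, numeric(1))
  len <- vapply(signals, function(s) length(s$values), integer(1))
  if (length(unique(fs)) != 1L || length(unique(len)) != 1L)
    stop_invalid("all channels must share one sampling rate and length")
  structure(list(signals = signals, fs = fs[[1]],
                 duration = len[[1]] / fs[[1]], metadata = metadata),
            class = "record")
}

#' @export
print.record <- function(x, ...) {
  cat(sprintf("<record> %s @ %g Hz, %.1f s\n",
              paste(names(x$signals), collapse = " + "), x$fs, x$duration))
  invisible(x)
}

#' Read a WFDB record (.hea + .dat)
#'
#' Parses a PhysioNet WFDB header and the associated signal file. Formats
#' 16 (16-bit little-endian) and 212 (packed 12-bit pairs) are supported —
#' these cover the Fantasia records. Samples are converted to physical
#' units via `(adc - baseline) / gain` where the header provides a gain.
#'
#' @param path Path to the `.hea` file (with or without the extension).
#' @return A [record()] with channels named from the header.
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop_format("header file not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop_format("empty header: %s", hea)
  head_f <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_f) < 3) stop_format("malformed header line in %s", hea)
  nsig <- as.integer(head_f[2])
  fs <- as.numeric(sub("/.*", "", head_f[3]))   # strip counter freq if any
  nsamp <- if (length(head_f) >= 4) as.integer(head_f[4]) else NA_integer_
  if (length(lines) < 1 + nsig)
    stop_format("header %s declares %d signals but lists fewer", hea, nsig)

  sig <- vector("list", nsig)
  dat_files <- character(nsig); fmts <- integer(nsig)
  gains <- numeric(nsig); baselines <- numeric(nsig)
  names_ <- character(nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(f) < 2) stop_format("malformed signal line %d in %s", i, hea)
    dat_files[i] <- f[1]
    fmts[i] <- as.integer(sub("x.*|:.*|\\+.*", "", f[2]))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    units <- sub("^[^/]*/?", "", gain_field)
    g <- sub("/.*", "", gain_field)
    baseline <- NA_real_
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", g))
      g <- sub("\\(.*", "", g)
    }
    gains[i] <- as.numeric(g)
    if (is.na(gains[i]) || gains[i] == 0) gains[i] <- 200
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    baselines[i] <- if (is.na(baseline)) adczero else baseline
    names_[i] <- if (length(f) >= 9)
      paste(f[9:length(f)], collapse = "_") else sprintf("sig%d", i)
  }
  if (length(unique(dat_files)) != 1L)
    stop_format("multi-file records not supported (%s)", hea)
  dat <- file.path(dirname(hea), dat_files[1])
  if (!file.exists(dat)) stop_format("signal file not found: %s", dat)
  fmt <- unique(fmts)
  if (length(fmt) != 1L || !fmt %in% c(16L, 212L))
    stop_format("unsupported signal format(s) %s in %s",
                paste(fmts, collapse = ","), hea)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- if (fmt == 16L) {
    readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
            signed = TRUE, endian = "little")
  } else {
    decode_212(raw)
  }
  total <- (length(adc) %/% nsig) * nsig
  adc <- adc[seq_len(total)]
  nread <- total %/% nsig
  if (!is.na(nsamp) && nread < nsamp)
    stop_format("signal file %s truncated: %d of %d samples per channel",
                dat, nread, nsamp)
  if (!is.na(nsamp)) { adc <- adc[seq_len(nsamp * nsig)]; nread <- nsamp }
  m <- matrix(adc, ncol = nsig, byrow = TRUE)
  signals <- lapply(seq_len(nsig), function(i)
    sampled_signal((m[, i] - baselines[i]) / gains[i], fs))
  names(signals) <- make.unique(names_)
  record(signals, metadata = list(source = hea, format = fmt))
}

# WFDB format 212: two 12-bit two's complement samples packed in 3 bytes
decode_212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1, n3, by = 3)]
  b1 <- b[seq(2, n3, by = 3)]
  b2 <- b[seq(3, n3, by = 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8)
  s2 <- b2 + bitwShiftL(bitwAnd(bitwShiftR(b1, 4), 0x0FL), 8)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

#' Write a record in WFDB format 16
#'
#' @param rec A [record()].
#' @param path Output path prefix (writes `path.hea` and `path.dat`). The
#'   per-channel gain is chosen to use the 16-bit range; quantization error
#'   is bounded by half an ADC step.
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(rec, path) {
  stopifnot(inherits(rec, "record"))
  nsig <- length(rec$signals)
  n <- length(rec$signals[[1]]$values)
  gains <- vapply(rec$signals, function(s) {
    mx <- max(abs(s$values))
    if (mx == 0) 200 else 30000 / mx
  }, numeric(1))
  adc <- mapply(function(s, g) as.integer(round(s$values * g)),
                rec$signals, gains, SIMPLIFY = FALSE)
  inter <- as.integer(t(do.call(cbind, adc)))
  base <- basename(path)
  hea <- paste0(path, ".hea")
  dat <- paste0(path, ".dat")
  sig_lines <- vapply(seq_len(nsig), function(i)
    sprintf("%s.dat 16 %.6g(0)/au 16 0 %d 0 0 %s", base, gains[i],
            adc[[i]][1], names(rec$signals)[i]),
    character(1))
  ok <- tryCatch({
    writeLines(c(sprintf("%s %d %g %d", base, nsig, rec$fs, n), sig_lines),
               hea)
    writeBin(inter, dat, size = 2L, endian = "little")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write WFDB record to %s", path)
  invisible(hea)
}

#' Read beat/breath annotations
#'
#' Reads event annotations either from a CSV of times in seconds (header
#' `time_s` optional) or from a binary WFDB (MIT-format) annotation file.
#' Unsorted input is sorted and duplicate timestamps are collapsed, each
#' with a warning.
#'
#' @param path Annotation file path.
#' @param format `"csv"` or `"wfdb_ann"`.
#' @param fs Sampling rate in Hz, required for `wfdb_ann` (annotation times
#'   are stored in samples).
#' @param label Event kind for the returned series.
#' @return An [event_series()] with `source = "reference"`.
#' @export
read_annotations <- function(path, format = c("csv", "wfdb_ann"), fs = NULL,
                             label = "beat") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("annotation file not found: %s", path)
  times <- if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) numeric(0)
    else {
      fields <- strsplit(lines, ",", fixed = TRUE)
      header <- fields[[1]]
      col <- 1L
      start <- 1L
      if (anyNA(suppressWarnings(as.numeric(header)))) {
        start <- 2L
        # named header: prefer a time_s column, else the last column
        col <- if ("time_s" %in% trimws(header))
          match("time_s", trimws(header)) else length(header)
      } else {
        col <- length(header)
      }
      if (start > length(lines)) numeric(0)
      else {
        vals <- suppressWarnings(vapply(
          fields[start:length(lines)],
          function(f) as.numeric(f[min(col, length(f))]), numeric(1)))
        if (anyNA(vals))
          stop_format("unparseable annotation at %s line %d", path,
                      start + which(is.na(vals))[1] - 1L)
        vals
      }
    }
  } else {
    if (is.null(fs)) stop_invalid("'fs' is required for wfdb_ann input")
    read_mit_annotations(path) / fs
  }
  if (is.unsorted(times)) {
    warning("annotation times were unsorted: sorting")
    times <- sort(times)
  }
  if (anyDuplicated(times)) {
    warning(sprintf("%d duplicate annotation timestamps collapsed",
                    sum(duplicated(times))))
    times <- unique(times)
  }
  event_series(times, label = label, source = "reference")
}

# MIT annotation format: 16-bit little-endian words; code = high 6 bits,
# time increment = low 10 bits. Beat codes 1..49 advance time and emit an
# event; SKIP(59) carries a 32-bit interval in the next two words (high word
# first); NUM/SUB/CHN(60-62) carry state only; AUX(63) is followed by its
# byte count of data (padded to even). Code 0 with zero interval ends the
# stream.
read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nw <- length(raw) %/% 2L
  words <- readBin(raw[seq_len(2L * nw)], "integer", n = nw, size = 2L,
                   signed = FALSE, endian = "little")
  t_cur <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= nw) {
    w <- words[i]
    code <- bitwShiftR(w, 10)
    interval <- bitwAnd(w, 1023L)
    if (code == 0L && interval == 0L) break
    if (code == 59L) {
      if (i + 2L > nw) stop_format("truncated SKIP in %s", path)
      interval32 <- words[i + 1L] * 65536 + words[i + 2L]
      if (interval32 > 2^31) interval32 <- interval32 - 2^32
      t_cur <- t_cur + interval32
      i <- i + 3L
      next
    }
    if (code %in% 60:62) { i <- i + 1L; next }
    if (code == 63L) {
      i <- i + 1L + ((interval + 1L) %/% 2L)
      next
    }
    t_cur <- t_cur + interval
    if (code >= 1L && code <= 49L) out <- c(out, t_cur)
    i <- i + 1L
  }
  out
}

#' Write pipeline outputs
#'
#' Deterministic writers for the three artifact kinds: detected beats
#' (`beat_index,time_s`), the composite respiration waveform
#' (`time_s,amplitude`), and a JSON report with stable keys. Floats are
#' written with six decimals.
#'
#' @param result For `beats_csv` an [event_series()]; for `composite_csv` a
#'   [sampled_signal()]; for `report_json` a named list or a
#'   `beat_report`/`breath_report`/`rate_metrics` object.
#' @param path Output file path.
#' @param kind One of `"beats_csv"`, `"composite_csv"`, `"report_json"`.
#' @return Invisibly, `path`.
#' @export
write_outputs <- function(result, path,
                          kind = c("beats_csv", "composite_csv",
                                   "report_json")) {
  kind <- match.arg(kind)
  ok <- tryCatch({
    if (kind == "beats_csv") {
      stopifnot(inherits(result, "event_series"))
      df <- data.frame(beat_index = seq_along(result$times),
                       time_s = sprintf("%.6f", result$times))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else if (kind == "composite_csv") {
      result <- as_sampled_signal(result)
      df <- data.frame(time_s = sprintf("%.6f", signal_times(result)),
                       amplitude = sprintf("%.6f", result$values))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      rep <- report_as_list(result)
      jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 6,
                           pretty = TRUE, na = "null")
    }
    TRUE
  }, error = function(e) {
    if (inherits(e, "cardioresp_error")) stop(e)
    FALSE
  })
  if (!isTRUE(ok)) stop_io("cannot write %s output to %s", kind, path)
  invisible(path)
}

report_as_list <- function(result) {
  if (inherits(result, "beat_report")) {
    list(true_positive_pct = 100 * result$tp / max(result$n_reference, 1),
         false_positive_pct = 100 * result$fp / max(result$n_reference, 1),
         t_wave_pct = 100 * result$t_wave / max(result$n_reference, 1),
         precision_pct = 100 * result$precision,
         sensitivity_pct = 100 * result$sensitivity,
         annotations_pct = result$annotations_pct,
         tp = result$tp, fp = result$fp, fn = result$fn,
         t_wave = result$t_wave)
  } else if (inherits(result, "breath_report")) {
    list(true_positive_pct = 100 * result$tp / max(result$n_reference, 1),
         false_positive_pct = 100 * result$fp / max(result$n_reference, 1),
         inaccurate_pct = 100 * result$inaccurate /
           max(result$n_reference, 1),
         precision_pct = 100 * result$precision,
         sensitivity_pct = 100 * result$sensitivity,
         annotations_pct = result$annotations_pct,
         phase_shift_s = result$phase_shift,
         tp = result$tp, fp = result$fp, fn = result$fn,
         inaccurate = result$inaccurate)
  } else if (inherits(result, "rate_metrics")) {
    list(mae = result$mae, pe = result$pe, nrmse = result$nrmse,
         rho_p = result$rho_p, p_value = result$p_value,
         rho_c = result$rho_c, n = result$n)
  } else if (is.list(result)) {
    result
  } else {
    stop_invalid("cannot serialize object of class '%s' as a report",
                 class(result)[1])
  }
}

#' Validate a JSON report against the shipped key schema
#'
#' Checks that every key required by the schema for the given report kind is
#' present in the JSON file.
#'
#' @param path Path to a report JSON.
#' @param kind `"beat"`, `"breath"` or `"metrics"`.
#' @return `TRUE` invisibly; errors if a required key is missing.
#' @export
validate_report <- function(path, kind = c("beat", "breath", "metrics")) {
  kind <- match.arg(kind)
  schema <- jsonlite::read_json(system.file("schemas", "report-schema.json",
                                            package = "cardioresp"))
  required <- unlist(schema[[kind]])
  got <- names(jsonlite::read_json(path))
  missing <- setdiff(required, got)
  if (length(missing))
    stop_format("report %s missing keys: %s", path,
                paste(missing, collapse = ", "))
  invisible(TRUE)
}
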