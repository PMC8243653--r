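# WFDB-style record and annotation I/O, plus a plain-text CSV fallback.
#
# The binary support covers what ambulatory ECG databases actually use:
# header (.hea) parsing, signal formats 16 (int16 LE) and 212 (packed
# 12-bit), and the MIT annotation codec (.atr). Everything is also
# readable/writable as plain CSV so tests need no binary fixtures.

# MIT annotation type codes <-> PhysioNet symbols. Beat symbols first;
# the remainder are non-beat annotations that are dropped on read.
.WFDB_BEAT_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "B" = 25L, "e" = 34L, "n" = 35L, "f" = 38L
)
.WFDB_NONBEAT_CODES <- c(
  "~" = 14L, "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L,
  "\"" = 22L, "=" = 23L, "p" = 24L, "?" = 26L, "t" = 27L, "+" = 28L,
  "u" = 29L, "!" = 31L, "[" = 32L, "]" = 33L, "@" = 36L, "x" = 37L,
  "(" = 39L, ")" = 40L, "r" = 41L
)

#' Construct an ECG record
#'
#' @param signal numeric matrix, one column per lead, in millivolts.
#' @param fs sampling rate in Hz (> 0).
#' @param patient_id opaque identifier string.
#' @return an object of class `ecg_record` with fields `signal`, `fs`,
#'   `patient_id`, `n_samples`, `n_leads`.
#' @export
ecg_record <- function(signal, fs, patient_id = "anonymous") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || nrow(signal) < 1L) {
    stop("ecg_record: signal must be a non-empty numeric matrix")
  }
  if (ncol(signal) < 1L) stop("ecg_record: at least one lead required")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("ecg_record: fs must be a positive scalar")
  }
  structure(
    list(signal = unname(signal), fs = as.numeric(fs),
         patient_id = as.character(patient_id),
         n_samples = nrow(signal), n_leads = ncol(signal)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> patient=%s  %d leads x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$n_leads, x$n_samples, x$fs,
              x$n_samples / x$fs))
  invisible(x)
}

#' Map a PhysioNet beat symbol to a simplified class
#'
#' Atrial premature beats (`A`, `a`, `S`) map to `S`; ventricular,
#' fusion and ventricular-escape beats (`V`, `F`, `E`) map to `V`;
#' normal, bundle-branch-block and atrial-escape beats (`N`, `B`, `e`)
#' map to `N`. Junctional and unclassifiable beats (`J`, `j`, `Q`) are
#' `EXCLUDED`, as is any beat symbol outside this 12-symbol scheme
#' (with a warning), so foreign databases degrade gracefully. The
#' mapping is total and vectorized.
#'
#' @param symbol character vector of one-character beat symbols.
#' @return character vector over `N`, `S`, `V`, `EXCLUDED`.
#' @export
simplify_label <- function(symbol) {
  out <- rep(PAC_EXCLUDED, length(symbol))
  out[symbol %in% c("N", "B", "e")] <- "N"
  out[symbol %in% c("A", "a", "S")] <- "S"
  out[symbol %in% c("V", "F", "E")] <- "V"
  known <- c("N", "B", "e", "A", "a", "S", "V", "F", "E", "J", "j", "Q")
  unknown <- setdiff(unique(symbol), known)
  if (length(unknown) > 0L) {
    warning(sprintf("unknown beat symbol(s) %s mapped to EXCLUDED",
                    paste(sQuote(unknown), collapse = ", ")))
  }
  out
}

# ---------------------------------------------------------------------
# Header + signal reading

.parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(sprintf("corrupt WFDB header: %s", hea_path))
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  name <- sub("/.*$", "", rec[[1L]])
  nsig <- as.integer(rec[[2L]])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[[3L]])) else 250
  nsamp <- if (length(rec) >= 4L) as.numeric(rec[[4L]]) else NA_real_
  if (is.na(nsig) || nsig < 1L) {
    stop(sprintf("WFDB header %s declares no signals", hea_path))
  }
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", f[[2L]]))
    gainfield <- if (length(f) >= 3L) f[[3L]] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gainfield))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gainfield)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield))
    } else NA_real_
    adczero <- if (length(f) >= 5L) as.numeric(f[[5L]]) else 0
    if (is.na(baseline)) baseline <- adczero
    list(file = f[[1L]], format = fmt, gain = gain, baseline = baseline)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

.read_dat <- function(dat_path, nsig, fmt, nsamp) {
  raw <- readBin(dat_path, what = "raw", n = file.size(dat_path))
  if (fmt == 16L) {
    vals <- readBin(raw, what = "integer", size = 2L, signed = TRUE,
                    endian = "little", n = length(raw) %/% 2L)
  } else if (fmt == 212L) {
    ints <- as.integer(raw)
    ntrip <- length(ints) %/% 3L
    b0 <- ints[seq(1L, by = 3L, length.out = ntrip)]
    b1 <- ints[seq(2L, by = 3L, length.out = ntrip)]
    b2 <- ints[seq(3L, by = 3L, length.out = ntrip)]
    s1 <- b0 + 256L * (b1 %% 16L)       # low 12 bits
    s2 <- b2 + 256L * (b1 %/% 16L)      # high nibble of b1 + third byte
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    vals <- as.vector(rbind(s1, s2))
  } else {
    stop(sprintf("unsupported WFDB signal format %d", fmt))
  }
  nfr <- length(vals) %/% nsig
  if (!is.na(nsamp) && nfr > nsamp) nfr <- nsamp
  matrix(vals[seq_len(nfr * nsig)], nrow = nfr, ncol = nsig, byrow = TRUE)
}

#' Read an ECG record (WFDB or CSV)
#'
#' `path` may be a WFDB header (`.hea`), a CSV signal file (`.csv`,
#' with a JSON sidecar `<base>.json` holding `fs` and `patient_id`), or
#' an extension-less record base name, in which case `.hea` is tried
#' first and `.csv` second. WFDB samples are converted to physical
#' millivolt units via `(adc - baseline) / gain`; lead order is as
#' stored. All leads are returned; the feature extractor uses the first
#' two.
#'
#' @param path record path as described above.
#' @return an [ecg_record].
#' @export
read_record <- function(path) {
  if (grepl("\\.hea$", path)) return(.read_record_wfdb(path))
  if (grepl("\\.csv$", path)) return(.read_record_csv(path))
  if (file.exists(paste0(path, ".hea"))) {
    return(.read_record_wfdb(paste0(path, ".hea")))
  }
  if (file.exists(paste0(path, ".csv"))) {
    return(.read_record_csv(paste0(path, ".csv")))
  }
  stop(sprintf("no record found at %s (.hea/.csv tried)", path))
}

.read_record_wfdb <- function(hea_path) {
  if (!file.exists(hea_path)) stop(sprintf("missing header file: %s", hea_path))
  hdr <- .parse_hea(hea_path)
  dat_files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(dat_files) != 1L) {
    stop("multi-file WFDB records are not supported")
  }
  fmts <- unique(vapply(hdr$signals, function(s) s$format, 0L))
  if (length(fmts) != 1L) stop("mixed signal formats are not supported")
  dat_path <- file.path(dirname(hea_path), dat_files)
  if (!file.exists(dat_path)) stop(sprintf("missing signal file: %s", dat_path))
  adc <- .read_dat(dat_path, hdr$nsig, fmts, hdr$nsamp)
  phys <- sapply(seq_len(hdr$nsig), function(j) {
    (adc[, j] - hdr$signals[[j]]$baseline) / hdr$signals[[j]]$gain
  })
  ecg_record(phys, fs = hdr$fs, patient_id = hdr$name)
}

.read_record_csv <- function(csv_path) {
  if (!file.exists(csv_path)) stop(sprintf("missing signal file: %s", csv_path))
  meta_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(meta_path)) {
    stop(sprintf("missing JSON sidecar for %s", csv_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sig <- as.matrix(read.csv(csv_path, check.names = FALSE))
  pid <- if (!is.null(meta$patient_id)) meta$patient_id else
    sub("\\.csv$", "", basename(csv_path))
  ecg_record(sig, fs = meta$fs, patient_id = pid)
}

# ---------------------------------------------------------------------
# Annotations

#' Read beat annotations (MIT .atr or CSV)
#'
#' Non-beat annotations (rhythm changes, noise marks, waveform
#' boundaries) are silently dropped; beat symbols become rows with a
#' simplified class label. Output is sorted by sample; annotations past
#' the end of the record are dropped with a warning.
#'
#' @param path `.atr` file or CSV with columns `sample,symbol`.
#' @param record the [ecg_record] the annotations refer to.
#' @return data.frame with columns `sample` (0-based), `symbol`,
#'   `label`.
#' @export
read_annotations <- function(path, record) {
  ann <- if (grepl("\\.csv$", path)) {
    df <- read.csv(path, colClasses = c("numeric", "character"))
    names(df) <- c("sample", "symbol")
    df
  } else {
    .read_atr(path)
  }
  if (nrow(ann) == 0L) {
    return(data.frame(sample = numeric(0), symbol = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ann <- ann[ann$symbol %in% names(.WFDB_BEAT_CODES) |
               ann$symbol %in% c("N", "B", "e", "A", "a", "S", "V", "F",
                                 "E", "J", "j", "Q"), , drop = FALSE]
  bad <- ann$sample < 0 | ann$sample >= record$n_samples
  if (any(bad)) {
    warning(sprintf("%d annotation(s) outside the record were dropped",
                    sum(bad)))
    ann <- ann[!bad, , drop = FALSE]
  }
  ann <- ann[order(ann$sample), , drop = FALSE]
  ann$label <- simplify_label(ann$symbol)
  rownames(ann) <- NULL
  ann
}

.read_atr <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing annotation file: %s", path))
  raw <- readBin(path, what = "raw", n = file.size(path))
  nw <- length(raw) %/% 2L
  w <- as.integer(raw[seq(1L, by = 2L, length.out = nw)]) +
    256L * as.integer(raw[seq(2L, by = 2L, length.out = nw)])
  samples <- numeric(0)
  symbols <- character(0)
  t <- 0
  i <- 1L
  code2sym <- c(.WFDB_BEAT_CODES, .WFDB_NONBEAT_CODES)
  sym_of <- names(code2sym)[order(code2sym)]  # not dense; use match below
  while (i <= nw) {
    code <- w[i] %/% 1024L
    delta <- w[i] %% 1024L
    if (code == 0L && delta == 0L) break
    if (code == 59L) {            # SKIP: 32-bit interval, MSW first
      if (i + 2L > nw) break
      t <- t + w[i + 1L] * 65536 + w[i + 2L]
      i <- i + 3L
      next
    }
    if (code == 63L) {            # AUX: delta = byte count (even-padded)
      i <- i + 1L + as.integer(ceiling(delta / 2))
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM/SUB/CHN modifiers
      i <- i + 1L
      next
    }
    t <- t + delta
    m <- match(code, code2sym)
    if (!is.na(m)) {
      samples <- c(samples, t)
      symbols <- c(symbols, names(code2sym)[m])
    }
    i <- i + 1L
  }
  keep <- symbols %in% names(.WFDB_BEAT_CODES)
  data.frame(sample = samples[keep], symbol = symbols[keep],
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------
# Writers (used by the synthetic generator and tests)

#' Write an ECG record
#'
#' `format = "wfdb"` writes a `.hea`/`.dat` pair in signal format 16
#' with gain 1000 adu/mV (1 microvolt resolution); `format = "csv"`
#' writes the signal matrix as CSV plus a JSON sidecar with `fs` and
#' `patient_id`.
#'
#' @param record an [ecg_record].
#' @param base output path without extension.
#' @param format `"wfdb"` or `"csv"`.
#' @return `base`, invisibly.
#' @export
write_record <- function(record, base, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    sig <- as.data.frame(record$signal)
    names(sig) <- paste0("lead", seq_len(record$n_leads))
    write.csv(sig, paste0(base, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fs = record$fs, patient_id = record$patient_id,
           n_samples = record$n_samples, units = "mV"),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(base))
  }
  gain <- 1000
  adc <- round(record$signal * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  name <- basename(base)
  chks <- vapply(seq_len(ncol(adc)), function(j) {
    s <- sum(adc[, j]) %% 65536
    if (s > 32767) s - 65536 else s
  }, 0)
  hdr <- c(
    sprintf("%s %d %g %d", name, ncol(adc), record$fs, nrow(adc)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d %d 0 ECG%d",
            name, gain, as.integer(adc[1, ]), as.integer(chks),
            seq_len(ncol(adc)))
  )
  writeLines(hdr, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(base)
}

#' Write beat annotations
#'
#' `format = "wfdb"` emits the MIT annotation codec (`.atr`);
#' `format = "csv"` a `sample,symbol` table.
#'
#' @param ann data.frame with columns `sample` (0-based) and `symbol`.
#' @param base output path without extension.
#' @param format `"wfdb"` or `"csv"`.
#' @export
write_annotations <- function(ann, base, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  ann <- ann[order(ann$sample), , drop = FALSE]
  if (format == "csv") {
    write.csv(ann[, c("sample", "symbol")], paste0(base, ".atr.csv"),
              row.names = FALSE, quote = FALSE)
    return(invisible(base))
  }
  words <- integer(0)
  t <- 0
  for (r in seq_len(nrow(ann))) {
    code <- .WFDB_BEAT_CODES[[ann$symbol[[r]]]]
    if (is.null(code)) stop(sprintf("cannot encode symbol %s", ann$symbol[[r]]))
    delta <- ann$sample[[r]] - t
    if (delta > 1023) {
      words <- c(words, 59L * 1024L, delta %/% 65536, delta %% 65536)
      delta <- 0
    }
    words <- c(words, code * 1024L + delta)
    t <- ann$sample[[r]]
  }
  words <- c(words, 0L)  # EOF
  con <- file(paste0(base, ".atr"), "wb")
  on.exit(close(con))
  writeBin(as.raw(as.vector(rbind(words %% 256L, words %/% 256L))), con)
  invisible(base)
}
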