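## Waveform and annotation I/O: columnar CSV, WFDB (format 16), EDF.
## A channel map assigns file channels to the roles
## {ecg_x, ecg_y, ecg_z, bp, resp}; ecg_x, bp and resp are mandatory.

#' Default channel-to-role map
#'
#' Identity mapping of the waveform roles `ecg_x`, `ecg_y`, `ecg_z`, `bp`,
#' `resp` onto file channel names; override entries to match the channel
#' names actually used in a file (see [load_recording()]).
#'
#' @return named list, role to channel name.
#' @export
default_channel_map <- function() {
  list(ecg_x = "ecg_x", ecg_y = "ecg_y", ecg_z = "ecg_z", bp = "bp",
       resp = "resp")
}

resolve_roles <- function(available, channel_map) {
  cm <- utils::modifyList(default_channel_map(), as.list(channel_map))
  pick <- function(role, required) {
    nm <- cm[[role]]
    if (!is.null(nm) && nm %in% available) {
      return(nm)
    }
    if (required) stop("missing role: ", role)
    NULL
  }
  list(
    ecg_x = pick("ecg_x", TRUE),
    ecg_y = pick("ecg_y", FALSE),
    ecg_z = pick("ecg_z", FALSE),
    bp = pick("bp", TRUE),
    resp = pick("resp", TRUE)
  )
}

build_recording_from_channels <- function(chans, fs, channel_map, subject_id) {
  roles <- resolve_roles(names(chans), channel_map)
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("inconsistent channel lengths: ", paste(lens, collapse = ", "))
  }
  ecg <- cbind(X = chans[[roles$ecg_x]])
  if (!is.null(roles$ecg_y)) ecg <- cbind(ecg, Y = chans[[roles$ecg_y]])
  if (!is.null(roles$ecg_z)) ecg <- cbind(ecg, Z = chans[[roles$ecg_z]])
  recording(
    ecg = ecg, bp = chans[[roles$bp]], resp = chans[[roles$resp]],
    fs = fs, subject_id = subject_id
  )
}

#' Load a multichannel recording from CSV, WFDB or EDF
#'
#' The format is taken from `format_hint` if given, else from the file
#' extension (`.csv`, `.hea`/`.dat`, `.edf`). Samples are stored at the
#' native sampling rate; nothing is resampled. Channels are assigned to the
#' roles `ecg_x`, `ecg_y`, `ecg_z`, `bp`, `resp` through `channel_map`, a
#' named list mapping role to the channel name used in the file (CSV column
#' header, WFDB signal description, EDF label). `ecg_x`, `bp` and `resp` are
#' mandatory; a missing mandatory role raises an error naming the role.
#'
#' @param path file path (for WFDB, either the `.hea` header or the record
#'   name without extension).
#' @param format_hint optional, one of `"csv"`, `"wfdb"`, `"edf"`.
#' @param channel_map named list mapping roles to file channel names;
#'   defaults to identity names `ecg_x`, `ecg_y`, `ecg_z`, `bp`, `resp`.
#' @param subject_id subject identifier recorded in the result; defaults to
#'   the file base name.
#' @return A [recording()] object.
#' @export
load_recording <- function(path, format_hint = NULL,
                           channel_map = default_channel_map(),
                           subject_id = NULL) {
  fmt <- if (!is.null(format_hint)) {
    match.arg(tolower(format_hint), c("csv", "wfdb", "edf"))
  } else {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
      csv = "csv", hea = "wfdb", dat = "wfdb", edf = "edf",
      stop("cannot infer format from extension '", ext,
        "'; pass format_hint")
    )
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.(csv|hea|dat|edf)$", "", basename(path),
      ignore.case = TRUE
    )
  }
  switch(fmt,
    csv = load_recording_csv(path, channel_map, subject_id),
    wfdb = load_recording_wfdb(path, channel_map, subject_id),
    edf = load_recording_edf(path, channel_map, subject_id)
  )
}

#' Write a recording to CSV, WFDB or EDF
#'
#' Written files round-trip through [load_recording()] to within the
#' format's sample resolution (exactly for CSV; within one quantization step
#' for the 16-bit WFDB and EDF encodings). Channels are written under their
#' role names `ecg_x`, `ecg_y`, `ecg_z`, `bp`, `resp`.
#'
#' @param rec a [recording()].
#' @param path destination path. For WFDB, the record name; `.hea` and
#'   `.dat` are derived from it.
#' @param format one of `"csv"`, `"wfdb"`, `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "wfdb", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "polyscore_recording"))
  switch(format,
    csv = write_recording_csv(rec, path),
    wfdb = write_recording_wfdb(rec, path),
    edf = write_recording_edf(rec, path)
  )
  invisible(path)
}

recording_role_channels <- function(rec) {
  chans <- list(ecg_x = rec$ecg[, 1])
  if (ncol(rec$ecg) >= 2) chans$ecg_y <- rec$ecg[, 2]
  if (ncol(rec$ecg) >= 3) chans$ecg_z <- rec$ecg[, 3]
  chans$bp <- rec$bp
  chans$resp <- rec$resp
  chans
}

## ---- CSV ----

load_recording_csv <- function(path, channel_map, subject_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("CSV waveform table needs a 'time' column")
  n <- nrow(df)
  if (n < 2) stop("CSV waveform table needs at least 2 samples")
  fs <- signif((n - 1) / (df$time[n] - df$time[1]), 12)
  chans <- as.list(df[setdiff(names(df), "time")])
  build_recording_from_channels(chans, fs, channel_map, subject_id)
}

write_recording_csv <- function(rec, path) {
  chans <- recording_role_channels(rec)
  df <- data.frame(time = (seq_len(rec$n) - 1) / rec$fs)
  for (nm in names(chans)) df[[nm]] <- chans[[nm]]
  ok <- tryCatch(
    {
      write.csv(df, path, row.names = FALSE)
      TRUE
    },
    error = function(e) stop("cannot write recording to ", path, ": ",
      conditionMessage(e))
  )
  invisible(ok)
}

## ---- WFDB (format 16: interleaved little-endian int16) ----

wfdb_paths <- function(path) {
  base <- sub("\\.(hea|dat)$", "", path, ignore.case = TRUE)
  list(base = base, hea = paste0(base, ".hea"), dat = paste0(base, ".dat"),
       record = basename(base))
}

write_recording_wfdb <- function(rec, path) {
  p <- wfdb_paths(path)
  chans <- recording_role_channels(rec)
  units <- c(ecg_x = "mV", ecg_y = "mV", ecg_z = "mV", bp = "mmHg",
             resp = "au")
  ns <- length(chans)
  gains <- vapply(chans, function(x) {
    signif(30000 / max(1, max(abs(x), na.rm = TRUE)), 6)
  }, numeric(1))
  adc <- mapply(function(x, g) {
    v <- as.integer(round(x * g))
    pmin(pmax(v, -32768L), 32767L)
  }, chans, gains, SIMPLIFY = FALSE)
  hdr <- c(
    sprintf("%s %d %s %d", p$record, ns, format(rec$fs), rec$n),
    vapply(seq_len(ns), function(i) {
      sprintf(
        "%s.dat 16 %s(0)/%s 16 0 %d 0 0 %s",
        p$record, format(gains[i]), units[[names(chans)[i]]],
        adc[[i]][1], names(chans)[i]
      )
    }, character(1))
  )
  writeLines(hdr, p$hea)
  mat <- do.call(rbind, adc) # ns x n; column-major write interleaves samples
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(as.integer(mat), con, size = 2L, endian = "little")
  invisible(p$base)
}

parse_wfdb_gain <- function(token) {
  # token like "200(0)/mV" or "200/mV" or "200"
  units <- if (grepl("/", token)) sub("^[^/]*/", "", token) else "adu"
  lead <- sub("/.*$", "", token)
  baseline <- 0
  if (grepl("\\(", lead)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", lead))
    lead <- sub("\\(.*$", "", lead)
  }
  gain <- as.numeric(lead)
  if (!is.finite(gain) || gain == 0) gain <- 200
  list(gain = gain, baseline = baseline, units = units)
}

load_recording_wfdb <- function(path, channel_map, subject_id) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea)) stop("WFDB header not found: ", p$hea)
  lines <- readLines(p$hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rl <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ns <- as.integer(rl[2])
  fs <- as.numeric(rl[3])
  nsamp <- as.integer(rl[4])
  if (length(lines) < 1 + ns) stop("WFDB header truncated: ", p$hea)
  sig <- lapply(lines[1 + seq_len(ns)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (!grepl("^16", tok[2])) {
      stop("unsupported WFDB sample format '", tok[2], "' (only 16)")
    }
    g <- parse_wfdb_gain(tok[3])
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(gain = g$gain, baseline = g$baseline, desc = desc)
  })
  raw <- readBin(p$dat, integer(), n = ns * nsamp, size = 2L,
    endian = "little", signed = TRUE)
  if (length(raw) < ns * nsamp) stop("WFDB .dat shorter than header declares")
  mat <- matrix(raw, nrow = ns)
  chans <- lapply(seq_len(ns), function(i) {
    (mat[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  })
  names(chans) <- vapply(seq_len(ns), function(i) {
    if (nzchar(sig[[i]]$desc)) sig[[i]]$desc else paste0("sig", i)
  }, character(1))
  build_recording_from_channels(chans, fs, channel_map, subject_id)
}

## ---- EDF (16-bit, single continuous data record) ----

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  chans <- recording_role_channels(rec)
  ns <- length(chans)
  con <- file(path, "wb")
  on.exit(close(con))
  phys_min <- vapply(chans, function(x) min(x, na.rm = TRUE), numeric(1))
  phys_max <- vapply(chans, function(x) max(x, na.rm = TRUE), numeric(1))
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  # header uses 8-char ascii fields; round-trip uses the printed values
  pmin_s <- vapply(phys_min, function(v) edf_pad(signif(v, 7), 8), character(1))
  pmax_s <- vapply(phys_max, function(v) edf_pad(signif(v, 7), 8), character(1))
  phys_min <- as.numeric(pmin_s)
  phys_max <- as.numeric(pmax_s)
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(rec$recorded_state, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad("1", 8),                      # one data record
    edf_pad(format(rec$duration_s), 8),   # of the full duration
    edf_pad(ns, 4)
  )
  units <- c(ecg_x = "mV", ecg_y = "mV", ecg_z = "mV", bp = "mmHg",
             resp = "au")
  field <- function(f, width) {
    paste(vapply(f, edf_pad, character(1), width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(names(chans), 16),
    field(rep("", ns), 80),
    field(units[names(chans)], 8),
    paste(pmin_s, collapse = ""),
    paste(pmax_s, collapse = ""),
    field(rep("-32768", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),
    field(rep(rec$n, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  for (i in seq_len(ns)) {
    x <- chans[[i]]
    dig <- as.integer(round(
      (x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768
    ))
    dig <- pmin(pmax(dig, -32768L), 32767L)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

load_recording_edf <- function(path, channel_map, subject_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  invisible(rd(8)) # version
  subj <- rd(80)
  invisible(rd(80))
  invisible(rd(8)); invisible(rd(8))
  invisible(rd(8)) # header bytes
  invisible(rd(44))
  ndr <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- rdv(16)
  invisible(rdv(80))
  invisible(rdv(8))
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  invisible(rdv(80))
  spr <- as.integer(rdv(8))
  invisible(rdv(32))
  chans <- lapply(seq_len(ns), function(i) numeric(ndr * spr[i]))
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L,
        endian = "little", signed = TRUE)
      phys <- pmin[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
      chans[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  names(chans) <- labels
  fs <- spr[1] / (dur / 1) # samples per record / record duration
  if (is.na(subject_id) || subject_id == basename(path)) {
    if (nzchar(subj)) subject_id <- subj
  }
  build_recording_from_channels(chans, fs, channel_map, subject_id)
}

## ---- Beat annotations (CSV dialect, WFDB symbols) ----

#' Load beat annotations from a CSV sidecar
#'
#' Expects a two-column CSV `time_s,label` with one beat per line, using
#' WFDB-style symbols (`N`, `V`, `S`; `|` and any unknown symbol map to `X`,
#' unknown ones with a warning). Times must be strictly increasing.
#'
#' @param path annotation CSV path.
#' @return A [beat_series()].
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(df))) {
    stop("annotation CSV needs columns time_s,label")
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("annotation times must be strictly increasing (duplicate or ",
      "non-monotone timestamp)")
  }
  lab <- df$label
  lab[lab == "|"] <- "X"
  beat_series(df$time_s, lab)
}

#' Write beat annotations to a CSV sidecar
#'
#' Artifact beats (`X`) are written with the WFDB symbol `|`.
#'
#' @param bs a [beat_series()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(bs, path) {
  lab <- bs$labels
  lab[lab == "X"] <- "|"
  write.csv(
    data.frame(time_s = bs$beat_times_s, label = lab),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
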