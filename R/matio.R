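#' @title Minimal MAT-file (v5) reader and writer
#' @description Just enough of the Level-5 MAT format to speak the public
#'   simulated benchmark's dialect: real numeric arrays (int8..uint32, single,
#'   double), character arrays and cell arrays, with zlib-compressed elements
#'   handled on read. Writing emits uncompressed little-endian files readable
#'   by MATLAB, Octave and scipy.
#' @name matio
NULL

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L

MX_CELL <- 1L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

mat_numeric_classes <- c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                         MX_UINT16, MX_INT32, MX_UINT32)

# --- reading -----------------------------------------------------------------

mat_read_payload <- function(raw, pos, type, nbytes, endian) {
  dat <- raw[pos:(pos + nbytes - 1)]
  switch(as.character(type),
    "1" = readBin(dat, "integer", n = nbytes, size = 1, signed = TRUE, endian = endian),
    "2" = readBin(dat, "integer", n = nbytes, size = 1, signed = FALSE, endian = endian),
    "3" = readBin(dat, "integer", n = nbytes / 2, size = 2, signed = TRUE, endian = endian),
    "4" = readBin(dat, "integer", n = nbytes / 2, size = 2, signed = FALSE, endian = endian),
    "5" = readBin(dat, "integer", n = nbytes / 4, size = 4, endian = endian),
    "6" = {
      v <- as.numeric(readBin(dat, "integer", n = nbytes / 4, size = 4, endian = endian))
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    "7" = readBin(dat, "numeric", n = nbytes / 4, size = 4, endian = endian),
    "9" = readBin(dat, "numeric", n = nbytes / 8, size = 8, endian = endian),
    "16" = rawToChar(dat),
    stop_invalid("unsupported MAT data type %d", type))
}

# Read one sub/element tag at pos; returns list(type, nbytes, data_pos, next_pos)
mat_read_tag <- function(raw, pos, endian) {
  w1 <- readBin(raw[pos:(pos + 3)], "integer", size = 4, endian = endian)
  small_len <- bitwAnd(bitwShiftR(w1, 16), 0xFFFFL)
  if (small_len > 0L) {                 # small data element: data in bytes 5-8
    list(type = bitwAnd(w1, 0xFFFFL), nbytes = small_len,
         data_pos = pos + 4L, next_pos = pos + 8L)
  } else {
    nbytes <- readBin(raw[(pos + 4):(pos + 7)], "integer", size = 4, endian = endian)
    padded <- 8L * ((nbytes + 7L) %/% 8L)
    list(type = w1, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + 8L + padded)
  }
}

mat_parse_matrix <- function(raw, pos, endian) {
  tg <- mat_read_tag(raw, pos, endian)          # array flags
  flags <- mat_read_payload(raw, tg$data_pos, tg$type, tg$nbytes, endian)
  klass <- bitwAnd(as.integer(flags[1]), 0xFFL)
  pos <- tg$next_pos
  tg <- mat_read_tag(raw, pos, endian)          # dimensions
  dims <- mat_read_payload(raw, tg$data_pos, tg$type, tg$nbytes, endian)
  pos <- tg$next_pos
  tg <- mat_read_tag(raw, pos, endian)          # name
  nm <- if (tg$nbytes > 0)
    rawToChar(raw[tg$data_pos:(tg$data_pos + tg$nbytes - 1)]) else ""
  pos <- tg$next_pos

  if (klass == MX_CELL) {
    ncells <- prod(dims)
    cells <- vector("list", ncells)
    for (i in seq_len(ncells)) {
      tg <- mat_read_tag(raw, pos, endian)
      if (tg$type != MI_MATRIX) stop_invalid("malformed cell array")
      el <- mat_parse_matrix(raw, tg$data_pos, endian)
      cells[[i]] <- el$value
      pos <- tg$next_pos
    }
    return(list(name = nm, value = cells, next_pos = pos))
  }
  if (klass == MX_CHAR) {
    tg <- mat_read_tag(raw, pos, endian)
    v <- if (tg$type == MI_UTF8)
      mat_read_payload(raw, tg$data_pos, tg$type, tg$nbytes, endian)
    else intToUtf8(mat_read_payload(raw, tg$data_pos, tg$type, tg$nbytes, endian))
    return(list(name = nm, value = v, next_pos = tg$next_pos))
  }
  if (!(klass %in% mat_numeric_classes))
    stop_invalid("unsupported MAT array class %d (variable '%s')", klass, nm)
  tg <- mat_read_tag(raw, pos, endian)          # real part
  v <- as.numeric(mat_read_payload(raw, tg$data_pos, tg$type, tg$nbytes, endian))
  if (length(dims) == 2 && all(dims > 1)) dim(v) <- dims
  list(name = nm, value = v, next_pos = tg$next_pos)
}

#' Read a MAT v5 file
#'
#' @param path file path.
#' @return Named list of variables: numeric vectors/matrices, strings, or
#'   lists (cell arrays).
#' @export
read_mat <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128) stop_invalid("'%s' is not a MAT v5 file", path)
  endian <- if (rawToChar(raw[127:128]) == "IM") "little" else "big"
  out <- list()
  pos <- 129L
  while (pos + 8 <= length(raw)) {
    tg <- mat_read_tag(raw, pos, endian)
    if (tg$type == MI_COMPRESSED) {
      payload <- raw[tg$data_pos:(tg$data_pos + tg$nbytes - 1)]
      inflated <- memDecompress(payload, type = "gzip")
      itg <- mat_read_tag(inflated, 1L, endian)
      if (itg$type == MI_MATRIX) {
        el <- tryCatch(mat_parse_matrix(inflated, itg$data_pos, endian),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         NULL
                       })
        if (!is.null(el)) out[[el$name]] <- el$value
      }
    } else if (tg$type == MI_MATRIX) {
      el <- tryCatch(mat_parse_matrix(raw, tg$data_pos, endian),
                     error = function(e) {
                       warning(conditionMessage(e), call. = FALSE)
                       NULL
                     })
      if (!is.null(el)) out[[el$name]] <- el$value
    }
    pos <- tg$next_pos
  }
  out
}

# --- writing -----------------------------------------------------------------

mat_pad8 <- function(x) {
  rem <- length(x) %% 8L
  if (rem) c(x, raw(8L - rem)) else x
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_sub_double <- function(x)
  c(mat_tag(MI_DOUBLE, 8L * length(x)),
    mat_pad8(writeBin(as.numeric(x), raw(), size = 8, endian = "little")))

mat_sub_int32 <- function(x)
  c(mat_tag(MI_INT32, 4L * length(x)),
    mat_pad8(writeBin(as.integer(x), raw(), size = 4, endian = "little")))

mat_sub_name <- function(nm) {
  b <- charToRaw(nm)
  c(mat_tag(MI_INT8, length(b)), mat_pad8(b))
}

mat_element <- function(name, value) {
  if (is.list(value)) {
    body <- c(
      mat_tag(MI_UINT32, 8L),
      writeBin(c(MX_CELL, 0L), raw(), size = 4, endian = "little"),
      mat_sub_int32(c(1L, length(value))),
      mat_sub_name(name),
      unlist(lapply(value, function(el) mat_element("", el))))
  } else if (is.character(value)) {
    b <- charToRaw(paste(value, collapse = "")) # ASCII, stored as UTF8 subelement
    body <- c(
      mat_tag(MI_UINT32, 8L),
      writeBin(c(MX_CHAR, 0L), raw(), size = 4, endian = "little"),
      mat_sub_int32(c(1L, length(b))),
      mat_sub_name(name),
      mat_tag(MI_UTF8, length(b)), mat_pad8(b))
  } else {
    v <- as.numeric(value)
    dims <- if (is.matrix(value)) dim(value) else c(1L, length(v))
    body <- c(
      mat_tag(MI_UINT32, 8L),
      writeBin(c(MX_DOUBLE, 0L), raw(), size = 4, endian = "little"),
      mat_sub_int32(dims),
      mat_sub_name(name),
      mat_sub_double(v))
  }
  c(mat_tag(MI_MATRIX, length(body)), body)
}

#' Write variables to a MAT v5 file
#'
#' @param path output file path.
#' @param vars named list; numeric vectors/matrices become double arrays,
#'   character scalars char arrays, lists cell arrays.
#' @export
write_mat <- function(path, vars) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, Platform: selsort, Created on: %s",
                  format(Sys.time(), "%a %b %d %H:%M:%S %Y"))
  hdr <- charToRaw(desc)
  if (length(hdr) > 116) hdr <- hdr[1:116]
  hdr <- c(hdr, rep(charToRaw(" "), 116 - length(hdr)))
  hdr <- c(hdr, raw(8),
           writeBin(256L, raw(), size = 2, endian = "little"),
           charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (nm in names(vars)) writeBin(mat_element(nm, vars[[nm]]), con)
  invisible(path)
}

# --- benchmark dialect -------------------------------------------------------

#' Read a benchmark-dialect dataset (trace + ground truth)
#'
#' Understands the conventions of the public simulated single-channel
#' benchmark: variable `data` holds the raw trace, `spike_times` and
#' `spike_class` are cell arrays (either one cell with all events plus class
#' labels, or one cell per neuron), and `samplingInterval` (ms) is optional
#' (24 kHz assumed when absent). Spike times are returned as 1-based sample
#' indices.
#'
#' @param path MAT-file path.
#' @return list with elements `recording` (`ss_recording`) and `truth`
#'   (`ss_ground_truth`; templates and noise level unknown, hence `NULL`/`NA`).
#' @export
read_benchmark <- function(path) {
  vars <- read_mat(path)
  for (need in c("data", "spike_times")) {
    if (is.null(vars[[need]]))
      stop_invalid("benchmark file '%s' is missing variable '%s'", path, need)
  }
  rate <- if (!is.null(vars$samplingInterval))
    1000 / as.numeric(vars$samplingInterval)[1] else 24000
  rec <- recording(as.numeric(vars$data), sampling_rate = rate,
                   id = basename(path))
  st <- vars$spike_times
  if (!is.list(st)) st <- list(st)
  if (length(st) == 1L) {
    times <- as.numeric(st[[1]])
    if (is.null(vars$spike_class))
      stop_invalid("benchmark file '%s' is missing variable 'spike_class'", path)
    cls <- vars$spike_class
    cls <- as.numeric(if (is.list(cls)) cls[[1]] else cls)
    if (length(cls) != length(times))
      stop_invalid("spike_times/spike_class length mismatch in '%s'", path)
    ids <- sort(unique(cls))
    trains <- lapply(ids, function(k) sort(times[cls == k]))
  } else {
    trains <- lapply(st, function(s) sort(as.numeric(s)))
  }
  truth <- ground_truth(trains, templates = NULL, noise_sigma = NA_real_,
                        refractory = 1)
  list(recording = rec, truth = truth)
}

#' Write a recording plus ground truth in the benchmark dialect
#'
#' Lossless round-trip with [read_benchmark()] for the trace, spike times and
#' class labels (templates and the noise level are not part of the dialect).
#'
#' @param rec an `ss_recording`.
#' @param truth an `ss_ground_truth`.
#' @param path output MAT-file path.
#' @export
write_dataset <- function(rec, truth, path) {
  stopifnot(inherits(rec, "ss_recording"), inherits(truth, "ss_ground_truth"))
  times <- unlist(truth$spike_times, use.names = FALSE)
  cls <- rep(seq_len(truth$n_neurons), lengths(truth$spike_times))
  if (length(times)) {
    o <- order(times, cls)
    times <- times[o]
    cls <- cls[o]
  }
  write_mat(path, list(
    data = rec$samples,
    spike_times = list(times),
    spike_class = list(cls),
    samplingInterval = 1000 / rec$sampling_rate))
}

# --- plain-text trace I/O ----------------------------------------------------

#' Write a trace as two-column CSV (sample index, voltage)
#' @param rec an `ss_recording`.
#' @param path output path.
#' @export
write_trace_csv <- function(rec, path) {
  write.csv(data.frame(sample = seq_along(rec$samples), voltage = rec$samples),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV trace written by [write_trace_csv()] (or any file with a
#' `voltage` column)
#' @param path input path.
#' @param sampling_rate Hz.
#' @export
read_trace_csv <- function(path, sampling_rate = 24000) {
  df <- read.csv(path)
  col <- if ("voltage" %in% names(df)) df$voltage else df[[ncol(df)]]
  recording(col, sampling_rate = sampling_rate, id = basename(path))
}

#' Serialise ground truth to JSON (lossless, including templates)
#' @param truth an `ss_ground_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(spike_times = truth$spike_times,
              templates = truth$templates,
              peak_index = attr(truth$templates, "peak_index"),
              noise_sigma = truth$noise_sigma,
              refractory = truth$refractory)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read ground truth from JSON written by [write_truth_json()]
#' @param path input path.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  templates <- obj$templates
  if (!is.null(templates)) {
    templates <- rbind(templates)
    attr(templates, "peak_index") <- obj$peak_index
  }
  st <- obj$spike_times
  if (is.matrix(st)) st <- lapply(seq_len(nrow(st)), function(i) st[i, ])
  if (!is.list(st)) st <- as.list(st)
  ground_truth(lapply(st, as.numeric), templates = templates,
               noise_sigma = if (is.null(obj$noise_sigma)) NA_real_ else obj$noise_sigma,
               refractory = obj$refractory)
}
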