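#' Waveform record I/O and the screening ledger
#'
#' A `waveform_record` holds one subject's synchronized ECG, PPG, and ABP
#' sample arrays at a single sampling rate. The native on-disk format is a
#' plain-text header (`#key=value` lines for subject id, sampling rate, and
#' channel list) followed by one CSV row per sample -- inspectable and
#' diff-able. A minimal WFDB-compatible adapter reads single-segment
#' records stored in 16-bit format. The screening ledger maps each of the
#' seven quality categories to its record IDs.
#'
#' @name io_records
NULL

#' Construct a waveform record
#'
#' @param subject_id character scalar identifier.
#' @param fs sampling rate in Hz (> 0), common to all channels.
#' @param ecg,ppg,abp numeric sample vectors (ECG/PPG in arbitrary units,
#'   ABP in mmHg). A channel may be `NULL` to mark it absent (distinct from
#'   a flat line of samples).
#' @return Object of class `waveform_record` with a `duration` field in
#'   seconds.
#' @export
waveform_record <- function(subject_id, fs, ecg = NULL, ppg = NULL,
                            abp = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop("subject_id must be a single string")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive number")
  }
  chans <- Filter(Negate(is.null), list(ecg = ecg, ppg = ppg, abp = abp))
  if (length(chans) == 0L) stop("at least one channel must be present")
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("channel length mismatch: ",
         paste(names(lens), lens, sep = "=", collapse = ", "))
  }
  structure(list(subject_id = subject_id, fs = fs, ecg = ecg, ppg = ppg,
                 abp = abp, duration = lens[[1]] / fs),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  present <- names(Filter(Negate(is.null), x[c("ecg", "ppg", "abp")]))
  cat("<waveform_record> ", x$subject_id, ": ",
      paste(present, collapse = "+"), ", ", x$fs, " Hz, ",
      signif(x$duration, 4), " s\n", sep = "")
  invisible(x)
}

record_channels <- function(record) {
  names(Filter(Negate(is.null), record[c("ecg", "ppg", "abp")]))
}

#' Write a record in the native delimited format
#'
#' @param record a [waveform_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  chans <- record_channels(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#subject_id=", record$subject_id),
               paste0("#fs=", format(record$fs, digits = 15)),
               paste0("#channels=", paste(chans, collapse = ","))), con)
  df <- as.data.frame(lapply(record[chans], function(v) {
    formatC(v, digits = 9, format = "g")
  }))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_native_record <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  need <- c("subject_id", "fs", "channels")
  if (!all(need %in% keys)) {
    stop("malformed record header in ", path, ": need #subject_id, #fs, ",
         "#channels lines")
  }
  fs <- suppressWarnings(as.numeric(vals[keys == "fs"]))
  if (is.na(fs) || fs <= 0) stop("non-positive or unparseable fs in ", path)
  chans <- strsplit(vals[keys == "channels"], ",", fixed = TRUE)[[1]]
  df <- tryCatch(
    read.csv(path, comment.char = "#", colClasses = "numeric"),
    error = function(e) stop("cannot parse samples in ", path, ": ",
                             conditionMessage(e)),
    warning = function(w) stop("cannot parse samples in ", path, ": ",
                               conditionMessage(w))
  )
  if (!setequal(names(df), chans)) {
    stop("channel columns ", paste(names(df), collapse = ","),
         " do not match header declaration ", paste(chans, collapse = ","),
         " in ", path)
  }
  if (anyNA(df)) stop("truncated or non-numeric samples in ", path)
  args <- c(list(subject_id = vals[keys == "subject_id"], fs = fs),
            as.list(df[chans]))
  do.call(waveform_record, args)
}

# Minimal WFDB-compatible reader: single-segment header plus a format-16
# (16-bit little-endian) signal file. Channel roles are inferred from the
# signal description/units (ECG leads, PLETH, ABP/ART).
read_wfdb_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- grep("^#|^\\s*$", readLines(hea), value = TRUE, invert = TRUE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3L) stop("malformed WFDB record line in ", hea)
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3])
  if (is.na(fs) || fs <= 0) stop("non-positive fs in WFDB header ", hea)
  sig <- lines[1 + seq_len(nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*", "", f[2])
    gain_spec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    } else 0
    desc <- paste(f[-seq_len(min(8, length(f)))], collapse = " ")
    if (desc == "") desc <- f[length(f)]
    list(file = f[1], fmt = fmt, gain = ifelse(is.na(gain) || gain == 0,
                                               200, gain),
         baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, character(1), "fmt"))
  if (!identical(fmts, "16")) {
    stop("WFDB adapter supports format 16 only (got ",
         paste(fmts, collapse = ","), ")")
  }
  datf <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(datf)) stop("WFDB signal file not found: ", datf)
  raw <- readBin(datf, "integer", n = file.size(datf) / 2L, size = 2L,
                 endian = "little", signed = TRUE)
  nsamp <- length(raw) %/% nsig
  mat <- matrix(raw[seq_len(nsamp * nsig)], nrow = nsig)
  role_of <- function(desc) {
    d <- toupper(desc)
    if (grepl("PLETH|PPG", d)) "ppg"
    else if (grepl("ABP|ART", d)) "abp"
    else if (grepl("ECG|\\bI+\\b|MCL|V\\d?|AVR|AVL|AVF", d)) "ecg"
    else NA_character_
  }
  args <- list(subject_id = sub("\\.hea$", "", basename(hea)), fs = fs)
  for (k in seq_len(nsig)) {
    role <- role_of(sigs[[k]]$desc)
    if (is.na(role) || !is.null(args[[role]])) next
    args[[role]] <- (mat[k, ] - sigs[[k]]$baseline) / sigs[[k]]$gain
  }
  do.call(waveform_record, args)
}

#' Read a waveform record
#'
#' @param path path to a native-format file, or to a WFDB header (`.hea`)
#'   or record stem for `format = "wfdb"`.
#' @param format `"native"` (default) or `"wfdb"`. No resampling is
#'   performed; channels must share one sampling rate.
#' @return A validated [waveform_record()].
#' @export
read_record <- function(path, format = c("native", "wfdb")) {
  format <- match.arg(format)
  if (format == "native" && !file.exists(path)) {
    stop("record file not found: ", path)
  }
  switch(format, native = read_native_record(path),
         wfdb = read_wfdb_record(path))
}

#' Construct a screening ledger
#'
#' @param x named list mapping each of the seven quality categories to a
#'   character vector of record IDs (empty vectors allowed), or a data
#'   frame with columns `category`, `record_id`.
#' @return Object of class `screening_ledger`.
#' @export
screening_ledger <- function(x) {
  if (is.data.frame(x)) {
    x <- split(as.character(x$record_id),
               factor(x$category, levels = QUALITY_CATEGORIES))
    x <- lapply(x, as.character)
  }
  missing_cats <- setdiff(QUALITY_CATEGORIES, names(x))
  x[missing_cats] <- list(character(0))
  extra <- setdiff(names(x), QUALITY_CATEGORIES)
  if (length(extra) > 0) {
    stop("unknown screening categories: ", paste(extra, collapse = ", "))
  }
  x <- x[QUALITY_CATEGORIES]
  all_ids <- unlist(x, use.names = FALSE)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0) {
    cats <- vapply(dup[1], function(id) {
      paste(names(x)[vapply(x, function(v) id %in% v, logical(1))],
            collapse = " and ")
    }, character(1))
    stop("record ", dup[1], " appears in two categories (", cats, ")")
  }
  structure(x, class = "screening_ledger")
}

#' Read a screening ledger from a two-column CSV
#'
#' @param path CSV with columns `category`, `record_id`.
#' @return A [screening_ledger()].
#' @export
read_ledger <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("screening ledger file not found")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "record_id") %in% names(df))) {
    stop("screening ledger corrupted: need columns category, record_id")
  }
  bad <- setdiff(unique(df$category), QUALITY_CATEGORIES)
  if (length(bad) > 0) {
    stop("screening ledger corrupted: unknown category ", bad[1])
  }
  screening_ledger(df)
}

#' Load the packaged screening-bookkeeping fixture
#'
#' The fixture transcribes the published seven-category screening of the
#' 578 downloaded ICU records (see
#' `system.file("extdata", "screening_fixture_provenance.md", package = "patcor")` for
#' the transcription notes).
#'
#' @param path fixture CSV; defaults to the packaged copy.
#' @return A [screening_ledger()].
#' @export
load_screening_fixture <- function(path = system.file("extdata",
                                                   "screening_fixture.csv",
                                                   package = "patcor")) {
  read_ledger(path)
}

#' Tabulate a screening ledger
#'
#' @param ledger a [screening_ledger()].
#' @return List with `counts` (named integer vector over the seven
#'   categories) and `total` (their sum).
#' @export
tabulate_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "screening_ledger"))
  counts <- vapply(ledger, length, integer(1))
  list(counts = counts, total = sum(counts))
}

#' Write a screening ledger in the fixture format
#'
#' @param ledger a [screening_ledger()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "screening_ledger"))
  df <- data.frame(
    category = rep(names(ledger), vapply(ledger, length, integer(1))),
    record_id = unlist(ledger, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
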