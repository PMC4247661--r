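#' Read a minute-epoch count file
#'
#' Reads the package's canonical epoch CSV dialect, or (permissively) an
#' ActiGraph-export-style file with a `"---"`-delimited preamble.
#'
#' The canonical dialect is three header lines followed by a column header
#' and one row per epoch:
#' \preformatted{
#' subject,S001
#' start,2012-03-01T00:00:00
#' epoch_seconds,60
#' axis1,axis2,axis3
#' 0,0,0
#' ...
#' }
#'
#' The permissive `"actigraph"` dialect tolerates a preamble of up to ~10
#' lines between dashed delimiter rows, from which the start date/time and
#' epoch period are extracted (`Start Time HH:MM:SS`, `Start Date M/D/YYYY`,
#' `Epoch Period (hh:mm:ss) 00:01:00`, `Serial Number ...` used as subject
#' id), followed by `axis1,axis2,axis3` rows.
#'
#' Input series must be contiguous whole-minute epochs; only a 60-s epoch
#' length is accepted, and negative or non-integer counts are a validation
#' error naming the offending row.
#'
#' @param path Path to the file.
#' @param dialect `"canonical"` (default) or `"actigraph"`.
#' @return An [epoch_series()].
#' @seealso [write_epochs()]
#' @export
read_epochs <- function(path, dialect = c("canonical", "actigraph")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "canonical") read_epochs_canonical(lines, path)
  else read_epochs_actigraph(lines, path)
}

read_epochs_canonical <- function(lines, path) {
  if (length(lines) < 4L)
    stop(sprintf("%s: not a canonical epoch file (needs 3 header lines + column header)", path))
  hdr <- function(i, key) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L || parts[1L] != key)
      stop(sprintf("%s: line %d must be '%s,<value>'", path, i, key))
    paste(parts[-1L], collapse = ",")
  }
  subject <- hdr(1L, "subject")
  start <- hdr(2L, "start")
  epoch_s <- suppressWarnings(as.numeric(hdr(3L, "epoch_seconds")))
  if (is.na(epoch_s) || epoch_s != 60)
    stop(sprintf("%s: unsupported epoch resolution '%s' (only 60-s epochs supported)",
                 path, hdr(3L, "epoch_seconds")))
  if (lines[4L] != "axis1,axis2,axis3")
    stop(sprintf("%s: line 4 must be the column header 'axis1,axis2,axis3'", path))
  start_time <- tryCatch(parse_epoch_time(start),
                         error = function(e)
                           stop(sprintf("%s: line 2: %s", path, conditionMessage(e))))
  data_lines <- lines[-(1:4)]
  data_lines <- data_lines[nzchar(data_lines)]
  parse_axis_rows(data_lines, first_row_line = 5L, path = path,
                  subject = subject, start_time = start_time)
}

read_epochs_actigraph <- function(lines, path) {
  delim <- grep("^-{5,}", lines)
  if (length(delim) < 2L)
    stop(sprintf("%s: no ActiGraph-style preamble delimiters found", path))
  pre <- lines[(delim[1L] + 1L):(delim[2L] - 1L)]
  grab <- function(pattern) {
    m <- grep(pattern, pre, ignore.case = TRUE, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    trimws(sub(pattern, "", m[1L], ignore.case = TRUE))
  }
  start_time_s <- grab("^Start Time")
  start_date_s <- grab("^Start Date")
  epoch_s <- grab("^Epoch Period \\(hh:mm:ss\\)")
  serial <- grab("^Serial Number:?")
  if (is.na(start_time_s) || is.na(start_date_s))
    stop(sprintf("%s: preamble lacks Start Date / Start Time", path))
  if (is.na(epoch_s) || !grepl("^00:01:00$", trimws(epoch_s)))
    stop(sprintf("%s: unsupported epoch period '%s' (only 00:01:00 supported)",
                 path, epoch_s))
  d <- as.Date(trimws(start_date_s), tryFormats = c("%m/%d/%Y", "%Y-%m-%d"))
  if (is.na(d)) stop(sprintf("%s: malformed Start Date '%s'", path, start_date_s))
  start_time <- parse_epoch_time(paste(format(d, "%Y-%m-%d"), trimws(start_time_s)))
  if (is.na(serial) || !nzchar(serial)) serial <- "unknown"
  body <- lines[(delim[2L] + 1L):length(lines)]
  # optional column-header row
  if (length(body) && grepl("axis", body[1L], ignore.case = TRUE))
    body <- body[-1L]
  body <- body[nzchar(body)]
  parse_axis_rows(body, first_row_line = delim[2L] + 1L, path = path,
                  subject = serial, start_time = start_time)
}

parse_axis_rows <- function(data_lines, first_row_line, path, subject, start_time) {
  if (length(data_lines) == 0L)
    return(epoch_series(subject, start_time, integer(), integer(), integer()))
  mat <- tryCatch(
    utils::read.csv(text = data_lines, header = FALSE,
                    colClasses = "numeric", col.names = c("a1", "a2", "a3")),
    error = function(e) stop(sprintf("%s: malformed count rows: %s",
                                     path, conditionMessage(e))))
  for (j in 1:3)
    check_counts(mat[[j]], sprintf("%s axis%d", path, j),
                 rows = seq_len(nrow(mat)))
  epoch_series(subject, start_time, mat$a1, mat$a2, mat$a3)
}

#' Write a minute-epoch count file
#'
#' Writes the canonical CSV dialect described in [read_epochs()]. The output
#' round-trips losslessly: `read_epochs(write_epochs(x, f))` reproduces `x`,
#' and re-writing a file read in canonical dialect is byte-identical.
#'
#' @param series An [epoch_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  header <- c(
    paste0("subject,", series$subject_id),
    paste0("start,", format(series$start_time, "%Y-%m-%dT%H:%M:%S")),
    "epoch_seconds,60",
    "axis1,axis2,axis3"
  )
  rows <- if (n_epochs(series) > 0)
    paste(series$axis1, series$axis2, series$axis3, sep = ",") else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
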