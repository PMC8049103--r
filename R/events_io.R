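# Event-table container and CSV / FCS 3.0 input-output.

#' Construct an event table
#'
#' The unit of all cytometry stages: one row per cell with `cell_id`,
#' `sample`, `arm`, `day` metadata followed by one intensity column per
#' channel.
#'
#' @param data Data frame with the four metadata columns plus channels.
#' @param channels Channel column names, in panel order.
#' @param transformed Logical; `TRUE` once arcsinh-transformed.
#' @param cofactor Arcsinh cofactor used (`NA` while raw).
#' @return An object of class `event_table`.
#' @export
event_table <- function(data, channels, transformed = FALSE, cofactor = NA_real_) {
  required <- c("cell_id", "sample", "arm", "day")
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop("event table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(channels)) stop("channel names must be unique")
  absent <- setdiff(channels, names(data))
  if (length(absent))
    stop("channel column(s) absent from data: ", paste(absent, collapse = ", "))
  if (any(is.na(data$day))) stop("day must be present for every cell")
  if (!transformed) {
    ch <- as.matrix(data[channels])
    if (any(ch < 0, na.rm = TRUE))
      stop("negative raw intensity found; raw intensities must be >= 0")
  }
  structure(list(data = data[c(required, channels)], channels = channels,
                 transformed = transformed, cofactor = cofactor),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d cells x %d channels (%s scale)\n",
              nrow(x$data), length(x$channels),
              if (x$transformed) sprintf("arcsinh, cofactor %g", x$cofactor)
              else "raw"))
  cat("arms:", paste(unique(x$data$arm), collapse = ", "),
      "| days:", paste(sort(unique(x$data$day)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the channel intensity matrix of an event table
#' @param x An `event_table`.
#' @param channels Optional subset of channels.
#' @return Numeric matrix, cells x channels.
#' @export
channel_matrix <- function(x, channels = NULL) {
  stopifnot(inherits(x, "event_table"))
  if (is.null(channels)) channels <- x$channels
  absent <- setdiff(channels, x$channels)
  if (length(absent))
    stop("unknown channel(s): ", paste(absent, collapse = ", "))
  as.matrix(x$data[channels])
}

#' Write an event table to CSV
#'
#' One row per cell; columns `cell_id`, `sample`, `arm`, `day`, then one
#' column per channel.
#'
#' @param x An `event_table`.
#' @param path Output file.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  utils::write.csv(x$data, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV or FCS
#'
#' CSV files must carry the metadata columns `cell_id`, `sample`, `arm`,
#' `day`; FCS files store channels only, so metadata is supplied through a
#' one-row `sample_sheet` (`sample`, `arm`, `day`) applied to all events.
#' The returned table is on the raw scale (untransformed); channel order is
#' preserved from the source.
#'
#' @param path File to read.
#' @param format `"csv"` or `"fcs"`.
#' @param sample_sheet Data frame with columns `sample`, `arm`, `day`
#'   (FCS only). May also have a `channels` character column naming a subset
#'   of channels to keep; unknown names are an error.
#' @return An `event_table`.
#' @export
read_events <- function(path, format = c("csv", "fcs"), sample_sheet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    required <- c("cell_id", "sample", "arm", "day")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("CSV is missing required column(s): ",
           paste(missing, collapse = ", "))
    channels <- setdiff(names(df), required)
    return(event_table(df, channels = channels))
  }
  if (is.null(sample_sheet))
    stop("reading FCS requires a sample_sheet with sample, arm, day")
  fcs <- read_fcs(path)
  channels <- colnames(fcs)
  if (!is.null(sample_sheet$channels)) {
    keep <- sample_sheet$channels[[1]]
    absent <- setdiff(keep, channels)
    if (length(absent))
      stop("sample sheet references unknown channel(s): ",
           paste(absent, collapse = ", "))
    fcs <- fcs[, keep, drop = FALSE]
    channels <- keep
  }
  df <- data.frame(cell_id = sprintf("%s_%06d", sample_sheet$sample[1],
                                     seq_len(nrow(fcs))),
                   sample = sample_sheet$sample[1],
                   arm = sample_sheet$arm[1],
                   day = sample_sheet$day[1], stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(fcs, check.names = FALSE))
  event_table(df, channels = channels)
}

# --- minimal FCS 3.0 (list mode, 32-bit float, little-endian) -------------

#' Write channel intensities as a minimal FCS 3.0 file
#'
#' List-mode, `$DATATYPE F` (32-bit float, little-endian). Only channel data
#' is stored; cell metadata travels in a sample sheet. Values round-trip at
#' single precision.
#'
#' @param x An `event_table` (typically one sample).
#' @param path Output file.
#' @export
write_fcs <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  mat <- channel_matrix(x)
  n_par <- ncol(mat); n_tot <- nrow(mat)
  delim <- "/"
  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
          "$NEXTDATA" = "0")
  for (j in seq_len(n_par)) {
    kw[sprintf("$P%dN", j)] <- colnames(mat)[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- as.character(ceiling(max(mat[, j], 1)))
  }
  text_seg <- paste0(delim, paste0(names(kw), delim, unname(kw), delim,
                                   collapse = ""))
  # pad so segment offsets are stable regardless of value widths
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(text_seg, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_seg, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a minimal FCS 3.0 file written by [write_fcs()]
#'
#' Accepts any FCS 3.0/3.1 file with `$DATATYPE F`, `$MODE L` and a uniform
#' 32-bit word size.
#'
#' @param path File to read.
#' @return Numeric matrix events x channels with channel names.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!startsWith(header, "FCS3"))
    stop("not an FCS 3.x file: ", path)
  off <- as.integer(trimws(substring(header,
                                     c(11, 19, 27, 35), c(18, 26, 34, 42))))
  seek(con, off[1])
  text_seg <- readChar(con, off[2] - off[1] + 1L, useBytes = TRUE)
  delim <- substr(text_seg, 1, 1)
  parts <- strsplit(substring(text_seg, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  if (toupper(trimws(kw[["$DATATYPE"]])) != "F")
    stop("only $DATATYPE F is supported")
  n_par <- as.integer(kw[["$PAR"]]); n_tot <- as.integer(kw[["$TOT"]])
  endian <- if (trimws(kw[["$BYTEORD"]]) == "4,3,2,1") "big" else "little"
  seek(con, off[3])
  vals <- readBin(con, numeric(), n = n_par * n_tot, size = 4,
                  endian = endian)
  ch <- vapply(seq_len(n_par),
               function(j) trimws(kw[[sprintf("$P%dN", j)]]), character(1))
  matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE,
         dimnames = list(NULL, ch))
}
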