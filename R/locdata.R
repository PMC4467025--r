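#' Construct a localization table
#'
#' The universal input of the package: time-stamped 2-D point localizations
#' with a channel label.  Coordinates are continuous nanometres in a y-up
#' Cartesian frame; frame indices are 0-based integers; exactly two channel
#' labels (1 and 2) are supported, matching the two-colour scope of the
#' cross-correlation method.
#'
#' @param x,y Numeric coordinates in nm.  Must be finite.
#' @param frame Integer frame index, 0-based.
#' @param channel Channel label, coerced to integer; only values 1 and 2 are
#'   accepted.
#' @param precision Optional localization precision in nm (may contain `NA`).
#' @param frame_interval Acquisition time per frame in seconds (default
#'   0.03 s, a typical sCMOS/EMCCD super-resolution frame rate).  Time lags
#'   are handled internally in frames and converted to seconds with this
#'   value only for presentation and fitting.
#' @return A `loc_table`: a data frame with columns `x`, `y`, `frame`,
#'   `channel` (and `precision` when supplied) and a `frame_interval`
#'   attribute.
#' @examples
#' tab <- loc_table(x = c(0, 100), y = c(0, 50), frame = c(0, 0),
#'                  channel = c(1, 2))
#' channel_counts(tab)
#' @export
loc_table <- function(x, y, frame, channel, precision = NULL,
                      frame_interval = 0.03) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || length(frame) != n || length(channel) != n)
    stop("x, y, frame and channel must have equal length")
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("x and y must be finite")
  frame <- as.integer(round(frame))
  if (n > 0 && any(frame < 0)) stop("frame indices must be >= 0")
  channel <- as.integer(channel)
  if (n > 0 && !all(channel %in% c(1L, 2L)))
    stop("channel labels must be 1 or 2 (two-colour data only)")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number of seconds")
  df <- data.frame(x = x, y = y, frame = frame, channel = channel)
  if (!is.null(precision)) {
    if (length(precision) != n) stop("precision must match the record count")
    df$precision <- as.numeric(precision)
  }
  structure(df, frame_interval = frame_interval,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cnt <- channel_counts(x)
  fr <- if (nrow(x)) range(x$frame) else c(NA, NA)
  cat(sprintf(
    "<loc_table> %d localizations (ch1: %d, ch2: %d), frames %s..%s, %g s/frame\n",
    nrow(x), cnt[1], cnt[2], fr[1], fr[2], frame_interval(x)))
  invisible(x)
}

#' Frame interval of a localization table
#' @param table A `loc_table`.
#' @return Seconds per frame.
#' @export
frame_interval <- function(table) {
  fi <- attr(table, "frame_interval")
  if (is.null(fi)) 0.03 else fi
}

#' Per-channel localization counts
#' @param table A `loc_table`.
#' @return Integer vector `c(n1, n2)`.
#' @export
channel_counts <- function(table) {
  c(sum(table$channel == 1L), sum(table$channel == 2L))
}

#' Per-frame, per-channel localization counts
#'
#' @param table A `loc_table`.
#' @param frames Optional integer vector of frames to tabulate (defaults to
#'   the full observed range).
#' @return A data frame with columns `frame`, `n1`, `n2`; `sum(n1)` and
#'   `sum(n2)` equal the totals from [channel_counts()] when `frames` covers
#'   the table.
#' @export
frame_counts <- function(table, frames = NULL) {
  if (is.null(frames)) {
    frames <- if (nrow(table)) seq(min(table$frame), max(table$frame)) else integer()
  }
  idx <- match(table$frame, frames)
  keep <- !is.na(idx)
  n1 <- tabulate(idx[keep & table$channel == 1L], nbins = length(frames))
  n2 <- tabulate(idx[keep & table$channel == 2L], nbins = length(frames))
  data.frame(frame = frames, n1 = n1, n2 = n2)
}

# canonical column names used on disk
.loc_cols <- c(x = "x_nm", y = "y_nm", frame = "frame", channel = "channel",
               precision = "precision_nm")

#' Read a localization table from delimited text
#'
#' Reads comma- or tab-delimited text with a header row.  There is no single
#' table standard across localization software, so `column_map` translates
#' foreign headers (for example ThunderSTORM's `"x [nm]"`) to the fields the
#' package needs.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector mapping the fields `x`, `y`,
#'   `frame`, `channel` (and optionally `precision`) to column names in the
#'   file.  Defaults to the package's own `x_nm`, `y_nm`, `frame`,
#'   `channel`, `precision_nm`.
#' @param frame_interval Seconds per frame (see [loc_table()]).
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, column_map = NULL, frame_interval = 0.03,
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cmap <- .loc_cols
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("x", "y", "frame", "channel")
  miss <- need[!cmap[need] %in% names(df)]
  if (length(miss))
    stop("missing required column(s): ",
         paste(sprintf("%s (mapped to '%s')", miss, cmap[miss]), collapse = ", "))
  num <- function(field) {
    v <- df[[cmap[[field]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & v != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   cmap[[field]], bad[1], v[bad[1]]))
    out
  }
  prec <- if (cmap[["precision"]] %in% names(df)) num("precision") else NULL
  loc_table(num("x"), num("y"), num("frame"), num("channel"),
            precision = prec, frame_interval = frame_interval)
}

#' Write a localization table to delimited text
#'
#' Writes canonical headers (`x_nm`, `y_nm`, `frame`, `channel`,
#' `precision_nm`) so that [read_localizations()] round-trips the table:
#' integers exactly, reals to 15 significant digits.
#'
#' @param table A [loc_table()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "loc_table"))
  out <- data.frame(x_nm = format(table$x, digits = 15, trim = TRUE,
                                  scientific = FALSE),
                    y_nm = format(table$y, digits = 15, trim = TRUE,
                                  scientific = FALSE),
                    frame = table$frame, channel = table$channel,
                    check.names = FALSE)
  if (!is.null(table$precision))
    out$precision_nm <- format(table$precision, digits = 15, trim = TRUE,
                               scientific = FALSE)
  if (nrow(out) == 0L) {
    # header-only file for an empty table
    writeLines(paste(names(out), collapse = sep), path)
    return(invisible(path))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subset a loc_table, keeping attributes
.loc_subset <- function(table, keep) {
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- frame_interval(table)
  class(out) <- c("loc_table", "data.frame")
  out
}
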