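#' Streamline tractograms
#'
#' A tractogram is an ordered collection of streamlines, each an n x 3 matrix
#' of vertex coordinates in world millimetres (n >= 2), together with a header
#' of key/value text pairs. Streamlines are the counting unit of all
#' downstream density measures: one streamline, one count.
#'
#' @param streamlines list of numeric matrices, each with 3 columns (x, y, z
#'   in mm) and at least 2 rows.
#' @param header named character vector or list of header key/value pairs.
#'   `count` and `datatype` are filled in automatically on write.
#' @return An object of class `tractogram`: a list with elements
#'   `streamlines` and `header`.
#' @examples
#' t <- tractogram(list(cbind(c(0, 1), c(0, 0), c(0, 0))))
#' n_streamlines(t)
#' @export
tractogram <- function(streamlines, header = list()) {
  stopifnot(is.list(streamlines))
  streamlines <- lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    if (!is.matrix(s)) s <- matrix(as.numeric(s), ncol = 3)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L)
      stop("streamline ", i, " does not have 3 coordinate columns")
    if (nrow(s) < 2L)
      stop("streamline ", i, " has fewer than 2 vertices")
    if (!all(is.finite(s)))
      stop("streamline ", i, " contains non-finite coordinates")
    step <- sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
    if (any(step == 0))
      stop("streamline ", i, " has repeated consecutive vertices")
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines,
                 header = as.list(header)),
            class = "tractogram")
}

#' @rdname tractogram
#' @param x a `tractogram`.
#' @export
n_streamlines <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  nv <- vapply(x$streamlines, nrow, integer(1))
  cat("tractogram:", length(nv), "streamlines,",
      sum(nv), "vertices\n")
  invisible(x)
}

.tck_magic <- "mrtrix tracks"

tck_error <- function(msg, class) {
  stop(structure(class = c(class, "tck_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write a tractogram to a TCK file
#'
#' Emits the MRtrix TCK tractogram format: a text header (magic line,
#' `key: value` pairs, `file: . <offset>`, `END`) followed by a binary stream
#' of little-endian 32-bit float vertex triplets, with a NaN triplet between
#' streamlines and an Inf triplet as end-of-stream sentinel. Coordinates are
#' therefore stored at single precision.
#'
#' @param x a `tractogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tck()]
#' @export
write_tck <- function(x, path) {
  stopifnot(inherits(x, "tractogram"))
  hdr <- x$header
  hdr$count <- NULL; hdr$datatype <- NULL; hdr$file <- NULL
  lines <- c(.tck_magic,
             paste0("count: ", length(x$streamlines)),
             "datatype: Float32LE",
             if (length(hdr)) paste0(names(hdr), ": ",
                                     vapply(hdr, as.character, character(1))))
  # the offset field changes the header length; iterate until stable
  offset <- 0L
  repeat {
    full <- c(lines, paste0("file: . ", offset), "END")
    len <- sum(nchar(full, type = "bytes")) + length(full)  # newlines
    if (len == offset) break
    offset <- len
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) tck_error(
                    paste0("cannot open '", path, "' for writing: ",
                           conditionMessage(e)), "tck_io_error"))
  on.exit(close(con))
  writeChar(paste0(paste(full, collapse = "\n"), "\n"), con, eos = NULL)
  for (s in x$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram file
#'
#' Parses the text header, then decodes the binary vertex stream, splitting
#' streamlines at NaN-triplet separators and consuming the Inf-triplet
#' end-of-stream sentinel. `Float32LE` and `Float32BE` vertex encodings are
#' supported; unknown header keys are retained but otherwise ignored.
#'
#' @param path path to a TCK file.
#' @return a [tractogram()].
#' @section Errors:
#' A malformed header raises a `tck_format_error` naming the offending key; a
#' vertex stream shorter than the header promises raises a
#' `tck_truncation_error` reporting the byte offset reached.
#' @export
read_tck <- function(path) {
  if (!file.exists(path))
    tck_error(paste0("file not found: ", path), "tck_io_error")
  con <- file(path, open = "rb")
  on.exit(close(con))

  read_line <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L)
        tck_error("unexpected end of file in header (no END line)",
                  "tck_format_error")
      if (ch == "\n") break
      chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }

  magic <- read_line()
  if (!identical(magic, .tck_magic))
    tck_error("not a TCK file: missing 'mrtrix tracks' magic line",
              "tck_format_error")
  header <- list()
  repeat {
    line <- read_line()
    if (identical(line, "END")) break
    m <- regmatches(line, regexec("^([^:]+):[ ]?(.*)$", line))[[1]]
    if (length(m) != 3L)
      tck_error(paste0("malformed header line: '", line, "'"),
                "tck_format_error")
    header[[m[2]]] <- m[3]
  }
  for (key in c("count", "datatype", "file"))
    if (is.null(header[[key]]))
      tck_error(paste0("missing mandatory header key: '", key, "'"),
                "tck_format_error")
  count <- suppressWarnings(as.integer(header$count))
  if (is.na(count) || count < 0L)
    tck_error("malformed header key: 'count' is not a nonnegative integer",
              "tck_format_error")
  endian <- switch(header$datatype,
                   Float32LE = "little", Float32BE = "big",
                   tck_error(paste0("unsupported header key: 'datatype' = '",
                                    header$datatype,
                                    "' (need Float32LE or Float32BE)"),
                             "tck_format_error"))
  m <- regmatches(header$file, regexec("^\\.[ ]+([0-9]+)$", header$file))[[1]]
  if (length(m) != 2L)
    tck_error("malformed header key: 'file' (expected '. <offset>')",
              "tck_format_error")
  offset <- as.integer(m[2])

  fsize <- file.size(path)
  nbytes <- fsize - offset
  if (nbytes < 0 || nbytes %% 4L != 0L)
    tck_error(paste0("truncated vertex stream: ", nbytes,
                     " bytes after header offset ", offset),
              "tck_truncation_error")
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "numeric", n = nbytes / 4L, size = 4L, endian = endian)
  if (length(vals) %% 3L != 0L)
    tck_error(paste0("truncated vertex stream: stream ends mid-triplet at ",
                     "byte offset ", offset + length(vals) * 4L),
              "tck_truncation_error")
  trip <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_sep <- rowSums(is.nan(trip)) == 3L
  is_end <- rowSums(is.infinite(trip) & trip > 0) == 3L
  endpos <- which(is_end)
  if (length(endpos) == 0L)
    tck_error(paste0("truncated vertex stream: no end-of-stream sentinel ",
                     "before byte offset ", fsize),
              "tck_truncation_error")
  endpos <- endpos[1L]
  trip <- trip[seq_len(endpos - 1L), , drop = FALSE]
  is_sep <- is_sep[seq_len(endpos - 1L)]

  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)])) # group id per triplet row
  keep <- !is_sep
  streamlines <- if (any(keep)) {
    unname(lapply(split.data.frame(trip[keep, , drop = FALSE], grp[keep]),
                  function(m) { dimnames(m) <- NULL; m }))
  } else list()
  if (length(streamlines) != count)
    tck_error(paste0("truncated vertex stream: header declares ", count,
                     " streamlines but ", length(streamlines),
                     " found (stream ends at byte offset ", fsize, ")"),
              "tck_truncation_error")
  out <- structure(list(streamlines = streamlines, header = header),
                   class = "tractogram")
  out
}
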