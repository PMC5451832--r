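# File I/O. Image stacks are directories of NetPBM PGM frames (P2 ASCII
# or P5 binary, 8- or 16-bit) ordered by file name, with acquisition
# metadata in an accompanying JSON file; tables are CSV, lineage and
# evaluation reports JSON. Label masks use 16-bit PGM, pixel value =
# trajectory id, 0 = background. All coordinates written to disk are
# 0-based pixels, origin top-left.

#' Write a PGM image
#'
#' @param img numeric/integer matrix (values clamped to `[0, maxval]`).
#' @param path output file.
#' @param maxval maximum gray value (255 or 65535).
#' @param ascii write P2 (ASCII, default) or P5 (binary).
#' @export
write_pgm <- function(img, path, maxval = 255L, ascii = TRUE) {
  v <- round(pmin(pmax(img, 0), maxval))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)),
                 as.character(maxval)), con)
    # row-major pixel order
    write(t(v), con, ncolumns = ncol(img))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval),
              con, eos = NULL)
    sz <- if (maxval > 255) 2L else 1L
    writeBin(as.integer(t(v)), con, size = sz, endian = "big")
  }
  invisible(path)
}

#' Read a PGM image
#'
#' Supports P2 (ASCII) and P5 (binary), 8- and 16-bit.
#'
#' @param path input file.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval (comments allowed)
  while (length(tokens) < 4L) {
    line <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header: ", path)
      if (ch == "\n") break
      line <- c(line, ch)
    }
    line <- paste(line, collapse = "")
    line <- sub("#.*$", "", line)
    tk <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    tokens <- c(tokens, tk[nzchar(tk)])
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  n <- w * h
  if (magic == "P5") {
    sz <- if (maxval > 255L) 2L else 1L
    v <- readBin(con, "integer", n = n, size = sz, signed = FALSE,
                 endian = "big")
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    v <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(v) < n) stop("truncated PGM data: ", path)
    v <- v[seq_len(n)]
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Load an image stack
#'
#' @param path directory containing PGM frames (all files matching
#'   `*.pgm`, ordered by name), or a single PGM file.
#' @param calibration micrometres per pixel (overrides any metadata).
#' @param frame_interval seconds between frames.
#' @return an object of class `frame_stack`: `frames` (list of
#'   matrices), `calibration`, `frame_interval`, `source`.
#' @export
load_stack <- function(path, calibration = 0.15, frame_interval = 69) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pgm$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no PGM frames in ", path)
    meta <- file.path(path, "stack.json")
    if (file.exists(meta)) {
      md <- jsonlite::read_json(meta)
      if (missing(calibration) && !is.null(md$calibration))
        calibration <- md$calibration
      if (missing(frame_interval) && !is.null(md$frame_interval))
        frame_interval <- md$frame_interval
    }
  } else if (file.exists(path)) {
    files <- path
  } else stop("no such stack: ", path)
  frames <- lapply(files, read_pgm)
  dims <- dim(frames[[1]])
  for (k in seq_along(frames))
    if (!identical(dim(frames[[k]]), dims))
      stop("frame shape mismatch at ", basename(files[k]), ": ",
           paste(dim(frames[[k]]), collapse = "x"), " vs ",
           paste(dims, collapse = "x"))
  frame_stack(frames, calibration, frame_interval, source = path)
}

#' Construct a frame stack
#'
#' @param frames list of image matrices (same shape).
#' @param calibration micrometres per pixel, > 0.
#' @param frame_interval seconds between frames.
#' @param source origin path (optional).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, calibration = 0.15, frame_interval = 69,
                        source = NA_character_) {
  stopifnot(length(frames) >= 1L, calibration > 0)
  dims <- dim(frames[[1]])
  for (k in seq_along(frames))
    if (!identical(dim(frames[[k]]), dims))
      stop("frame shape mismatch at frame ", k)
  structure(list(frames = frames, calibration = calibration,
                 frame_interval = frame_interval, source = source),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %dx%d px, %.3f um/px, %gs\n",
              length(x$frames), d[1], d[2], x$calibration,
              x$frame_interval))
  invisible(x)
}

#' Save an image stack or label stack as PGM frames
#'
#' @param frames list of matrices.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param maxval 255 for images, 65535 for label masks.
#' @param calibration,frame_interval metadata written to `stack.json`.
#' @return the directory, invisibly.
#' @export
save_stack <- function(frames, dir, prefix = "frame",
                       maxval = 255L, calibration = 0.15,
                       frame_interval = 69) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(frames))
    write_pgm(frames[[t]],
              file.path(dir, sprintf("%s_%04d.pgm", prefix, t)),
              maxval = maxval)
  jsonlite::write_json(
    list(calibration = calibration, frame_interval = frame_interval,
         n_frames = length(frames)),
    file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a lineage table as JSON
#'
#' @param lineage data.frame with id, parent, b, d (and optionally
#'   generation).
#' @param path output file.
#' @export
write_lineage_json <- function(lineage, path) {
  jsonlite::write_json(lineage, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}
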