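#' Read a tractogram file
#'
#' Two dialects are supported, each a documented subset of the common
#' streamline formats:
#'
#' * `"tck"`: a text header starting `mrtrix tracks`, `key: value` lines
#'   (`datatype: Float32LE`, `file: . <offset>`, optional `count`),
#'   terminated by `END`; the body is little-endian float32 triplets in
#'   world mm, with a `(NaN,NaN,NaN)` triplet separating streamlines and an
#'   `(Inf,Inf,Inf)` triplet marking end of file.
#' * `"trk"`: a 1000-byte binary header (`TRACK` magic, dims, voxel size,
#'   4x4 voxel-to-world, streamline count, version, header size) followed by
#'   records of `int32 n_points` then `n_points` float32 triplets. In this
#'   subset coordinates are stored directly in world mm and scalars /
#'   per-track properties are not supported.
#'
#' @param path File path.
#' @param dialect `"tck"` or `"trk"`.
#' @param space Space identifier to attach to the result.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, dialect = c("tck", "trk"),
                            space = "template") {
  dialect <- match.arg(dialect)
  switch(dialect,
         tck = read_tck(path, space),
         trk = read_trk(path, space))
}

#' Write a tractogram file
#'
#' @param t A [tractogram()].
#' @param path Output path.
#' @param dialect `"tck"` or `"trk"`.
#' @param grid For `"trk"`, the [template_grid()] whose dims/affine fill the
#'   header (defaults to a unit grid; the coordinates themselves are world
#'   mm either way).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, dialect = c("tck", "trk"),
                             grid = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tck = write_tck(t, path),
         trk = write_trk(t, path, grid))
  invisible(path)
}

parse_error <- function(path, offset, msg) {
  stop(sprintf("parse error in '%s' at byte %d: %s", path, offset, msg),
       call. = FALSE)
}

# ---- TCK-style ----

write_tck <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", n_streamlines(t)))
  # reserve room for the 'file: . <offset>' line, then compute the offset
  head_txt <- paste0(paste(header, collapse = "\n"), "\n")
  offset_line_max <- "file: . 000000\n"
  offset <- nchar(head_txt, "bytes") + nchar(offset_line_max, "bytes") +
    nchar("END\n", "bytes")
  writeChar(head_txt, con, eos = NULL)
  writeChar(sprintf("file: . %06d\n", offset), con, eos = NULL)
  writeChar("END\n", con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(unclass(s))), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
}

read_tck <- function(path, space) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    parse_error(path, 0L, "missing 'mrtrix tracks' magic line")
  offset <- NA_integer_
  datatype <- NA_character_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      parse_error(path, seek(con), "header not terminated by END")
    if (line == "END") break
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) != 3L)
      parse_error(path, seek(con), sprintf("malformed header line '%s'", line))
    if (kv[2] == "file") {
      offset <- as.integer(sub("^\\. *", "", kv[3]))
    } else if (kv[2] == "datatype") {
      datatype <- kv[3]
    }
  }
  if (is.na(offset)) parse_error(path, seek(con), "missing 'file' offset")
  if (!identical(datatype, "Float32LE"))
    parse_error(path, seek(con), "unsupported datatype (need Float32LE)")
  seek(con, offset)
  raw_n <- file.size(path) - offset
  vals <- readBin(con, "numeric", n = raw_n %/% 4L, size = 4L,
                  endian = "little")
  if (length(vals) %% 3L != 0L)
    parse_error(path, file.size(path), "truncated triplet stream")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  streams <- list()
  cur <- NULL
  done <- FALSE
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    if (all(is.infinite(row))) { done <- TRUE; break }
    if (all(is.nan(row))) {
      if (!is.null(cur)) streams[[length(streams) + 1L]] <- do.call(rbind, cur)
      cur <- NULL
    } else {
      cur <- c(cur, list(row))
    }
  }
  if (!done)
    parse_error(path, file.size(path),
                "missing end-of-file (Inf) triplet: truncated record")
  tractogram(streams, space = space)
}

# ---- TRK-style ----

write_trk <- function(t, path, grid = NULL) {
  if (is.null(grid)) grid <- template_grid(c(1L, 1L, 1L), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(as.raw(0L), con)
  writeBin(as.integer(grid$shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(grid$voxel_size), con, size = 4L, endian = "little")
  writeBin(rep(0, 3), con, size = 4L, endian = "little")      # origin
  writeBin(0L, con, size = 2L, endian = "little")             # n_scalars
  writeBin(raw(200L), con)                                    # scalar names
  writeBin(0L, con, size = 2L, endian = "little")             # n_properties
  writeBin(raw(200L), con)                                    # property names
  writeBin(as.numeric(t(grid$affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                    # reserved
  writeBin(charToRaw("RAS"), con); writeBin(as.raw(0L), con)  # voxel_order
  writeBin(raw(4L), con)                                      # pad2
  writeBin(rep(0, 6), con, size = 4L, endian = "little")      # orientation
  writeBin(raw(2L), con)                                      # pad1
  writeBin(raw(6L), con)                                      # invert/swap
  writeBin(n_streamlines(t), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")             # version
  writeBin(1000L, con, size = 4L, endian = "little")          # hdr_size
  for (s in t$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(unclass(s))), con, size = 4L, endian = "little")
  }
}

read_trk <- function(path, space) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    parse_error(path, 0L, "missing TRACK magic")
  invisible(readBin(con, "integer", 3L, size = 2L, endian = "little"))
  invisible(readBin(con, "numeric", 6L, size = 4L, endian = "little"))
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  if (n_scalars != 0L || n_props != 0L)
    parse_error(path, 24L, "scalars/properties unsupported in this subset")
  invisible(readBin(con, "numeric", 16L, size = 4L, endian = "little"))
  invisible(readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L))
    parse_error(path, 996L, sprintf("bad header size %d", hdr_size))
  if (version > 2L)
    parse_error(path, 992L, sprintf("unsupported version %d", version))
  streams <- vector("list", max(0L, n_count))
  for (i in seq_len(n_count)) {
    at <- seek(con)
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L)
      parse_error(path, at, "truncated streamline record")
    if (np < 2L)
      parse_error(path, at, sprintf("invalid point count %d", np))
    vals <- readBin(con, "numeric", 3L * np, size = 4L, endian = "little")
    if (length(vals) < 3L * np)
      parse_error(path, at, "truncated streamline record")
    streams[[i]] <- matrix(vals, ncol = 3L, byrow = TRUE)
  }
  tractogram(streams, space = space)
}
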