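#' Read a gameplay session log
#'
#' Parses one session-log JSON document (optionally gzip-compressed, as the
#' acquisition pipeline ships them) into a validated [game_session()].
#' Accepts a file path or a raw vector; gzip input is detected by its magic
#' bytes. Timestamps recorded as epoch milliseconds are normalised to float
#' seconds from session start. Unknown top-level keys are ignored with a
#' warning; schema violations, unsorted timestamps and unbalanced pointer
#' phases raise descriptive errors naming the offending record.
#'
#' @param x path to a `.json` / `.json.gz` file, or a raw vector of bytes.
#' @return a validated `game_session`.
#' @export
read_session <- function(x) {
  if (is.raw(x)) {
    bytes <- x
  } else if (is.character(x) && length(x) == 1L) {
    bytes <- readBin(x, "raw", n = file.size(x))
  } else {
    abort_parse("read_session() expects a file path or a raw vector")
  }
  if (length(bytes) >= 2 && bytes[1] == as.raw(0x1f) && bytes[2] == as.raw(0x8b)) {
    bytes <- gunzip_raw(bytes)
  }
  doc <- jsonlite::fromJSON(rawToChar(bytes), simplifyVector = TRUE)

  known <- c("child_id", "game", "phase", "duration_s", "screen_pts",
             "label", "age_months", "gender", "touch", "inertial")
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown session key(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (k in c("child_id", "game", "phase", "duration_s", "screen_pts")) {
    if (is.null(doc[[k]])) abort_parse("session JSON lacks required key '%s'", k)
  }

  touch <- parse_touch(doc$touch)
  inertial <- parse_inertial(doc$inertial)

  # Normalise epoch-millisecond clocks to seconds from session start.
  ts <- c(touch$t, inertial$t)
  if (length(ts) && min(ts) > 1e10) {
    t0 <- min(ts)
    touch$t <- (touch$t - t0) / 1000
    inertial$t <- (inertial$t - t0) / 1000
  }

  game_session(
    child_id = doc$child_id, game = doc$game, phase = doc$phase,
    duration = doc$duration_s, screen_pts = doc$screen_pts,
    label = null_if_na(doc$label), age_months = null_if_na(doc$age_months),
    gender = null_if_na(doc$gender),
    touch = touch, inertial = inertial
  )
}

null_if_na <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x
}

parse_touch <- function(tt) {
  if (is.null(tt) || (is.data.frame(tt) && !nrow(tt)) || !length(tt)) {
    return(empty_touch())
  }
  if (!is.data.frame(tt)) abort_parse("'touch' is not an array of event records")
  need <- c("t", "id", "phase", "x", "y")
  miss <- setdiff(need, names(tt))
  if (length(miss)) {
    abort_parse("touch records lack field(s): %s", paste(miss, collapse = ", "))
  }
  data.frame(t = as.numeric(tt$t), id = as.integer(tt$id),
             phase = as.character(tt$phase),
             x = as.numeric(tt$x), y = as.numeric(tt$y))
}

parse_inertial <- function(it) {
  if (is.null(it) || (is.data.frame(it) && !nrow(it)) || !length(it)) {
    return(empty_inertial())
  }
  if (!is.data.frame(it)) abort_parse("'inertial' is not an array of sample records")
  miss <- setdiff(c("t", "accel", "rotation", "attitude"), names(it))
  if (length(miss)) {
    abort_parse("inertial records lack field(s): %s", paste(miss, collapse = ", "))
  }
  tri <- function(m, what) {
    if (is.list(m) && !is.data.frame(m)) {
      bad <- which(lengths(m) != 3)
      if (length(bad)) {
        abort_parse("inertial record %d: '%s' is not a 3-vector", bad[1], what)
      }
      m <- do.call(rbind, m)
    }
    m <- as.matrix(m)
    if (ncol(m) != 3) abort_parse("inertial '%s' is not a 3-vector per sample", what)
    m
  }
  a <- tri(it$accel, "accel")
  g <- tri(it$rotation, "rotation")
  o <- tri(it$attitude, "attitude")
  data.frame(t = as.numeric(it$t),
             ax = a[, 1], ay = a[, 2], az = a[, 3],
             gx = g[, 1], gy = g[, 2], gz = g[, 3],
             ox = o[, 1], oy = o[, 2], oz = o[, 3])
}

#' Serialise a gameplay session to JSON bytes
#'
#' Inverse of [read_session()]: emits the session-log JSON schema, optionally
#' gzip-wrapped (the format the acquisition pipeline uploads).
#'
#' @param session a `game_session`.
#' @param compress gzip-wrap the output (default `FALSE`).
#' @return a raw vector; with `compress = TRUE` it starts with the gzip magic
#'   bytes `0x1f 0x8b`.
#' @export
write_session <- function(session, compress = FALSE) {
  stopifnot(inherits(session, "game_session"), is_flag(compress))
  it <- session$inertial
  inertial <- lapply(seq_len(nrow(it)), function(i) {
    list(t = jsonlite::unbox(it$t[i]),
         accel = c(it$ax[i], it$ay[i], it$az[i]),
         rotation = c(it$gx[i], it$gy[i], it$gz[i]),
         attitude = c(it$ox[i], it$oy[i], it$oz[i]))
  })
  doc <- list(
    child_id = jsonlite::unbox(session$child_id),
    game = jsonlite::unbox(session$game),
    phase = jsonlite::unbox(session$phase),
    duration_s = jsonlite::unbox(session$duration),
    screen_pts = session$screen_pts,
    label = jsonlite::unbox(session$label %||% NA),
    age_months = jsonlite::unbox(session$age_months %||% NA),
    gender = jsonlite::unbox(session$gender %||% NA),
    touch = session$touch,
    inertial = inertial
  )
  bytes <- charToRaw(as.character(
    jsonlite::toJSON(doc, dataframe = "rows", digits = NA, na = "null",
                     null = "null")))
  if (compress) gzip_raw(bytes) else bytes
}

#' Write a session log file
#'
#' @param session a `game_session`.
#' @param path output path; a `.gz` suffix selects gzip framing.
#' @return `path`, invisibly.
#' @export
write_session_file <- function(session, path) {
  bytes <- write_session(session, compress = grepl("\\.gz$", path))
  writeBin(bytes, path)
  invisible(path)
}

# gzip framing via a file connection: memCompress(type = "gzip") produces a
# bare zlib stream without the 0x1f 0x8b header, which downstream tools
# reject.
gzip_raw <- function(bytes) {
  tmp <- tempfile(fileext = ".gz")
  on.exit(unlink(tmp))
  con <- gzfile(tmp, "wb")
  writeBin(bytes, con)
  close(con)
  readBin(tmp, "raw", n = file.size(tmp))
}

gunzip_raw <- function(bytes) {
  tmp <- tempfile(fileext = ".gz")
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  con <- gzfile(tmp, "rb")
  on.exit(close(con), add = TRUE, after = FALSE)
  out <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (!length(chunk)) break
    out <- c(out, chunk)
  }
  out
}
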