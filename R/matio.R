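# Minimal MATLAB Level-5 (.mat, uncompressed) codec.
#
# Supports exactly what the Oufti-style cell-list dialect needs: double
# arrays, character arrays, cell arrays and struct arrays, little-endian,
# uncompressed elements. Struct arrays map to/from an R list of named
# lists carrying class "mat_struct". This is intentionally a small,
# self-contained codec, not a general MAT-file library.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L

## ---- writer ------------------------------------------------------------

pad8 <- function(r) {
  need <- (8L - length(r) %% 8L) %% 8L
  if (need) c(r, raw(need)) else r
}

w_i32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

mat_element <- function(type, data_raw) {
  c(w_i32(c(type, length(data_raw))), pad8(data_raw))
}

mat_name_field <- function(nm) mat_element(MI_INT8, charToRaw(nm))

mat_array_raw <- function(name, x) {
  if (inherits(x, "mat_struct")) {
    fields <- if (length(x)) names(x[[1]]) else character()
    fn_raw <- raw(0)
    for (f in fields) {
      b <- charToRaw(substr(f, 1L, 31L))
      fn_raw <- c(fn_raw, b, raw(32L - length(b)))
    }
    body <- c(
      mat_element(MI_UINT32, w_i32(c(MX_STRUCT, 0L))),
      mat_element(MI_INT32, w_i32(c(1L, length(x)))),
      mat_name_field(name),
      mat_element(MI_INT32, w_i32(32L)),
      mat_element(MI_INT8, fn_raw)
    )
    for (el in x) {
      for (f in fields) body <- c(body, mat_array_raw("", el[[f]]))
    }
  } else if (is.character(x)) {
    s <- paste(x, collapse = "\n")
    u <- utf8ToInt(s)
    body <- c(
      mat_element(MI_UINT32, w_i32(c(MX_CHAR, 0L))),
      mat_element(MI_INT32, w_i32(c(1L, length(u)))),
      mat_name_field(name),
      mat_element(MI_UINT16, writeBin(as.integer(u), raw(), size = 2L, endian = "little"))
    )
  } else if (is.list(x)) {
    body <- c(
      mat_element(MI_UINT32, w_i32(c(MX_CELL, 0L))),
      mat_element(MI_INT32, w_i32(c(1L, length(x)))),
      mat_name_field(name)
    )
    for (el in x) body <- c(body, mat_array_raw("", el))
  } else {
    d <- if (!is.null(dim(x))) dim(x) else c(1L, length(x))
    x <- as.numeric(x)
    body <- c(
      mat_element(MI_UINT32, w_i32(c(MX_DOUBLE, 0L))),
      mat_element(MI_INT32, w_i32(d)),
      mat_name_field(name),
      mat_element(MI_DOUBLE, writeBin(as.vector(x), raw(), size = 8L, endian = "little"))
    )
  }
  mat_element(MI_MATRIX, body)
}

#' Write variables to a MATLAB Level-5 file
#'
#' Writes a named list of variables as an uncompressed little-endian MAT
#' v5 file. Numeric vectors/matrices become double arrays, single strings
#' char arrays, unnamed lists cell arrays, and lists of named lists with
#' class `"mat_struct"` become 1-by-n struct arrays.
#'
#' @param vars named list of variables.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(length(names(vars)) == length(vars))
  txt <- "MATLAB 5.0 MAT-file, written by cellmapr"
  hdr <- charToRaw(txt)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  hdr <- c(hdr, raw(8L))                                  # subsys offset
  hdr <- c(hdr, writeBin(c(0x00L, 0x01L), raw(), size = 1L))  # version 0x0100 LE
  hdr <- c(hdr, charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) body <- c(body, mat_array_raw(nm, vars[[nm]]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, body), con)
  invisible(path)
}

## ---- reader ------------------------------------------------------------

r_u32 <- function(r, at) {
  v <- readBin(r[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

# Reads one sub-element tag at offset `at`; returns list(type, data, nxt).
read_subelement <- function(r, at) {
  first <- r[at:(at + 3L)]
  hi <- readBin(first[3:4], "integer", size = 2L, endian = "little", signed = FALSE)
  if (hi != 0L) {  # small data element: size in upper 16 bits, data in next 4
    type <- readBin(first[1:2], "integer", size = 2L, endian = "little", signed = FALSE)
    size <- hi
    data <- if (size) r[(at + 4L):(at + 3L + size)] else raw(0)
    list(type = type, data = data, nxt = at + 8L)
  } else {
    type <- readBin(first, "integer", size = 4L, endian = "little")
    size <- as.integer(r_u32(r, at + 4L))
    data <- if (size) r[(at + 8L):(at + 7L + size)] else raw(0)
    pad <- (8L - size %% 8L) %% 8L
    list(type = type, data = data, nxt = at + 8L + size + pad)
  }
}

decode_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = as.numeric(readBin(data, "integer", n = length(data), size = 1L,
                             endian = "little", signed = TRUE)),
    "2" = as.numeric(readBin(data, "integer", n = length(data), size = 1L,
                             endian = "little", signed = FALSE)),
    "3" = as.numeric(readBin(data, "integer", n = length(data) / 2L, size = 2L,
                             endian = "little", signed = TRUE)),
    "4" = as.numeric(readBin(data, "integer", n = length(data) / 2L, size = 2L,
                             endian = "little", signed = FALSE)),
    "5" = as.numeric(readBin(data, "integer", n = length(data) / 4L, size = 4L,
                             endian = "little")),
    "6" = {
      v <- readBin(data, "integer", n = length(data) / 4L, size = 4L, endian = "little")
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(data, "double", n = length(data) / 4L, size = 4L, endian = "little"),
    "9" = readBin(data, "double", n = length(data) / 8L, size = 8L, endian = "little"),
    cm_stop("schema_error", sprintf("unsupported MAT numeric type %d", type))
  )
}

parse_matrix <- function(r, at, end) {
  flags <- read_subelement(r, at)
  cls <- as.integer(r_u32(flags$data, 1L) %% 256)
  dims_el <- read_subelement(r, flags$nxt)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4L,
                  size = 4L, endian = "little")
  name_el <- read_subelement(r, dims_el$nxt)
  name <- rawToChar(name_el$data)
  at <- name_el$nxt
  value <- NULL
  if (cls == MX_DOUBLE || (cls >= 6L && cls <= 15L)) {
    pr <- read_subelement(r, at)
    v <- decode_numeric(pr$type, pr$data)
    if (length(dims) == 2L && all(dims > 0L)) {
      value <- matrix(v, nrow = dims[1], ncol = dims[2])
    } else {
      value <- v
    }
    if (length(v) == 0L) value <- matrix(numeric(0), nrow = dims[1], ncol = dims[2])
    at <- pr$nxt
  } else if (cls == MX_CHAR) {
    ch <- read_subelement(r, at)
    value <- switch(as.character(ch$type),
      "16" = rawToChar(ch$data),
      "2" = rawToChar(ch$data),
      "1" = rawToChar(ch$data),
      "4" = intToUtf8(readBin(ch$data, "integer", n = length(ch$data) / 2L,
                              size = 2L, endian = "little", signed = FALSE)),
      cm_stop("schema_error", sprintf("unsupported MAT char type %d", ch$type)))
    at <- ch$nxt
  } else if (cls == MX_CELL) {
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- read_subelement(r, at)
      pm <- parse_matrix(r, at + element_header_size(r, at), sub$nxt)
      value[[i]] <- pm$value
      at <- sub$nxt
    }
  } else if (cls == MX_STRUCT) {
    fnl <- read_subelement(r, at)
    fn <- read_subelement(r, fnl$nxt)
    width <- readBin(fnl$data, "integer", size = 4L, endian = "little")
    nfields <- length(fn$data) %/% width
    fields <- vapply(seq_len(nfields), function(i) {
      b <- fn$data[((i - 1L) * width + 1L):(i * width)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    at <- fn$nxt
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      el <- stats::setNames(vector("list", nfields), fields)
      for (f in fields) {
        sub <- read_subelement(r, at)
        pm <- parse_matrix(r, at + element_header_size(r, at), sub$nxt)
        el[[f]] <- pm$value
        at <- sub$nxt
      }
      value[[i]] <- el
    }
    class(value) <- "mat_struct"
  } else {
    cm_stop("schema_error", sprintf("unsupported MAT array class %d", cls))
  }
  list(name = name, value = value, nxt = at)
}

element_header_size <- function(r, at) {
  hi <- readBin(r[(at + 2L):(at + 3L)], "integer", size = 2L,
                endian = "little", signed = FALSE)
  if (hi != 0L) 4L else 8L
}

#' Read a MATLAB Level-5 file
#'
#' Reads uncompressed little-endian MAT v5 files containing double, char,
#' cell and struct arrays. Compressed elements (as written by recent
#' MATLAB defaults) are not supported and raise a `schema_error`.
#'
#' @param path .mat file.
#' @return named list of variables; struct arrays become lists of named
#'   lists with class `"mat_struct"`.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) cm_stop("io_error", sprintf("no such file: %s", path))
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 128L) cm_stop("schema_error", "not a MAT v5 file (truncated header)")
  endian <- rawToChar(r[127:128])
  if (endian != "IM")
    cm_stop("schema_error", "only little-endian MAT v5 files are supported")
  out <- list()
  at <- 129L
  n <- length(r)
  while (at + 7L <= n) {
    tag <- read_subelement(r, at)
    if (tag$type == MI_COMPRESSED)
      cm_stop("schema_error", "compressed MAT elements are not supported")
    if (tag$type == MI_MATRIX) {
      pm <- parse_matrix(r, at + element_header_size(r, at), tag$nxt)
      out[[pm$name]] <- pm$value
    }
    at <- tag$nxt
  }
  out
}
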